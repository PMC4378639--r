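#' Generate a synthetic epidermal cell lattice
#'
#' Cells are modelled as a jittered hexagonal tessellation: a regular
#' hexagonal grid whose hexagon area equals `target_cell_area_um2`, with
#' every lattice vertex (shared by three cells) displaced once by a
#' seeded uniform jitter. Because shared vertices move together the
#' cells remain a space-filling tessellation with non-degenerate,
#' simple polygons, and the mean cell area stays within a few percent of
#' the target. Cells whose centroid falls inside the
#' `width_mm` x `height_mm` rectangle are retained.
#'
#' The x axis is the medio-lateral axis (midrib at `x = 0`, margin at
#' `x = width`); the y axis is proximo-distal (base at `y = 0`).
#'
#' @param width_mm,height_mm extent of the sampled tissue rectangle, mm.
#' @param target_cell_area_um2 mean cell area to aim for, square microns.
#' @param seed integer seed for the vertex jitter.
#' @param jitter fraction of the hexagon circumradius used as the
#'   half-width of the uniform vertex displacement (default 0.25).
#' @return An object of class `cell_map`: list with `cells` (data frame
#'   `cell_id`, `x_um`, `y_um`, `area_um2`, `gus`), `polygons` (list of
#'   vertex matrices, microns), `width_um`, `height_um`, and the
#'   generation parameters. `gus` is `NA` until [assign_gus()] is run.
#' @examples
#' cm <- gen_cell_map(1, 1, 10000, seed = 1)
#' nrow(cm$cells) # ~ 100
#' @export
gen_cell_map <- function(width_mm, height_mm, target_cell_area_um2,
                         seed = NULL, jitter = 0.25) {
  stopifnot_positive(width_mm = width_mm, height_mm = height_mm,
                     target_cell_area_um2 = target_cell_area_um2)
  if (jitter < 0 || jitter > 0.4) stop("`jitter` must be in [0, 0.4]")
  W <- width_mm * 1000; H <- height_mm * 1000
  s <- sqrt(2 * target_cell_area_um2 / (3 * sqrt(3)))  # hexagon circumradius
  # flat-top hexagon centres; cover the rectangle with margin
  dx <- 1.5 * s; dy <- sqrt(3) * s
  qs <- seq(floor(-2 * s / dx) - 1L, ceiling((W + 2 * s) / dx) + 1L)
  rs <- seq(floor(-2 * s / dy) - 1L, ceiling((H + 2 * s) / dy) + 1L)
  centres <- expand.grid(q = qs, r = rs)
  cx <- centres$q * dx
  cy <- (centres$r + 0.5 * (centres$q %% 2)) * dy
  # hexagon corners, keyed so shared corners jitter identically
  ang <- pi / 3 * (0:5)
  corner_x <- outer(cx, s * cos(ang), `+`)
  corner_y <- outer(cy, s * sin(ang), `+`)
  key <- matrix(paste(round(corner_x, 3), round(corner_y, 3)),
                nrow = length(cx))
  uk <- unique(as.vector(key))
  jx <- jy <- setNames(numeric(length(uk)), uk)
  if (jitter > 0) {
    j <- with_seed(seed, matrix(runif(2 * length(uk), -jitter * s, jitter * s), ncol = 2))
    jx[] <- j[, 1]; jy[] <- j[, 2]
  }
  polys <- vector("list", length(cx))
  keep <- logical(length(cx))
  cent <- matrix(0, length(cx), 2)
  area <- numeric(length(cx))
  for (i in seq_along(cx)) {
    k <- key[i, ]
    p <- cbind(corner_x[i, ] + jx[k], corner_y[i, ] + jy[k])
    colnames(p) <- c("x", "y")
    cc <- polygon_centroid(p)
    if (cc[1] >= 0 && cc[1] <= W && cc[2] >= 0 && cc[2] <= H) {
      keep[i] <- TRUE
      polys[[i]] <- p
      cent[i, ] <- cc
      area[i] <- polygon_area(p)
    }
  }
  polys <- polys[keep]
  cells <- data.frame(cell_id = seq_len(sum(keep)),
                      x_um = cent[keep, 1], y_um = cent[keep, 2],
                      area_um2 = area[keep], gus = NA)
  if (!nrow(cells)) stop("tessellation produced no cells inside the rectangle")
  structure(list(cells = cells, polygons = polys, width_um = W, height_um = H,
                 target_cell_area_um2 = target_cell_area_um2,
                 seed = seed, jitter = jitter, front = NULL),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> %d cells over %.0f x %.0f um, mean cell area %.0f um2%s\n",
              nrow(x$cells), x$width_um, x$height_um, mean(x$cells$area_um2),
              if (!all(is.na(x$cells$gus)))
                sprintf(", %.1f%% GUS+", 100 * mean(x$cells$gus)) else ""))
  invisible(x)
}

#' Assign reporter status to cells from a front model
#'
#' Each cell's GUS status is an independent Bernoulli draw with success
#' probability `model$p(x)` evaluated at the cell centroid's normalised
#' midrib-to-margin coordinate `x = x_um / width_um`.
#'
#' @param map a [gen_cell_map()] result.
#' @param model a [front_model()].
#' @param seed integer seed for the Bernoulli draws.
#' @return The cell map with the `gus` column filled in.
#' @export
assign_gus <- function(map, model, seed = NULL) {
  stopifnot(inherits(map, "cell_map"), inherits(model, "front_model"))
  x <- pmin(pmax(map$cells$x_um / map$width_um, 0), 1)
  p <- model$p(x)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("front model produced probabilities outside [0, 1]")
  map$cells$gus <- with_seed(seed, runif(length(p)) < p)
  map$front <- model$name
  map
}
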