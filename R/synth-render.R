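#' Render a cell map to a synthetic stained-tissue image
#'
#' Rasterises the tessellation: reporter-positive cells are filled with
#' the stain colour, other tissue with a pale background, and cell walls
#' are drawn as dark lines two pixels wide (so that adjacent stained
#' cells remain separated under 8-connectivity). Optional Gaussian pixel
#' noise emulates acquisition noise. A ground-truth mask marking the
#' exact stained-interior pixels accompanies the image.
#'
#' @param map a [gen_cell_map()] result with GUS status assigned (a map
#'   with no assignment renders with zero positive cells).
#' @param pixel_size_um microns per pixel.
#' @param stain_color length-3 RGB in \[0, 1\] for stained cells.
#' @param noise_sd standard deviation of additive Gaussian noise, in
#'   units of the \[0, 1\] intensity range.
#' @param seed seed for the noise draw.
#' @return An object of class `gus_image`: list with `pixels`
#'   (H x W x 3 array in \[0, 1\]), `pixel_size_um`, `truth_mask`
#'   (H x W logical: stained interior pixels), `cell_labels` (H x W
#'   integer: owning cell id, 0 between cells), `n_gus_cells`, and the
#'   render parameters. Row 1 of the arrays is `y = 0` (lamina base);
#'   columns index x from the midrib.
#' @export
render_gus_image <- function(map, pixel_size_um = 2,
                             stain_color = c(0.20, 0.25, 0.65),
                             noise_sd = 0, seed = NULL) {
  stopifnot(inherits(map, "cell_map"))
  stopifnot_positive(pixel_size_um = pixel_size_um)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  W <- as.integer(ceiling(map$width_um / pixel_size_um))
  H <- as.integer(ceiling(map$height_um / pixel_size_um))
  px <- (seq_len(W) - 0.5) * pixel_size_um
  py <- (seq_len(H) - 0.5) * pixel_size_um
  labels <- matrix(0L, H, W)
  for (i in seq_along(map$polygons)) {
    p <- map$polygons[[i]]
    ix <- which(px >= min(p[, 1]) & px <= max(p[, 1]))
    iy <- which(py >= min(p[, 2]) & py <= max(p[, 2]))
    if (!length(ix) || !length(iy)) next
    g <- expand.grid(y = iy, x = ix)
    ins <- points_in_polygon(px[g$x], py[g$y], p)
    sel <- cbind(g$y[ins], g$x[ins])
    labels[sel] <- map$cells$cell_id[i]
  }
  # wall pixels: label changes against the 4-neighbourhood, thickened to
  # 2 px by also marking the neighbour on the far side of each change
  wall <- matrix(FALSE, H, W)
  dh <- labels[, -1, drop = FALSE] != labels[, -W, drop = FALSE]
  wall[, -W][dh] <- TRUE; wall[, -1][dh] <- TRUE
  dv <- labels[-1, , drop = FALSE] != labels[-H, , drop = FALSE]
  wall[-H, ][dv] <- TRUE; wall[-1, ][dv] <- TRUE
  gus <- map$cells$gus
  gus[is.na(gus)] <- FALSE
  gus_ids <- map$cells$cell_id[gus]
  stained <- matrix(labels %in% gus_ids, H, W) & !wall & labels > 0L
  bg <- c(0.92, 0.95, 0.90)
  wall_col <- c(0.25, 0.25, 0.25)
  pixels <- array(rep(bg, each = H * W), dim = c(H, W, 3))
  for (ch in 1:3) {
    pl <- pixels[, , ch]
    pl[stained] <- stain_color[ch]
    pl[wall] <- wall_col[ch]
    pixels[, , ch] <- pl
  }
  if (noise_sd > 0) {
    pixels <- with_seed(seed,
      pixels + array(rnorm(length(pixels), 0, noise_sd), dim = dim(pixels)))
    pixels[pixels < 0] <- 0
    pixels[pixels > 1] <- 1
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 truth_mask = stained, cell_labels = labels,
                 n_gus_cells = length(gus_ids),
                 stain_color = stain_color, noise_sd = noise_sd, seed = seed),
            class = "gus_image")
}

#' @export
print.gus_image <- function(x, ...) {
  cat(sprintf("<gus_image> %d x %d px (%.1f um/px), %d stained cells, noise sd %.3f\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size_um,
              x$n_gus_cells, x$noise_sd))
  invisible(x)
}
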