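#' Specification for a synthetic leaf outline
#'
#' Describes an elliptical lamina outline with optional low-frequency
#' radial perturbation. The base shape is the parametric ellipse with
#' semi-axes `length/2` and `width/2`; `roughness` scales random
#' low-order Fourier modulation of the radius (serrations are not
#' modelled: the mature leaves this emulates are unserrated).
#'
#' @param length,width full extents along the major/minor axes, mm.
#' @param n_vertices number of outline vertices (minimum 16; rounded up
#'   to a multiple of 4 so the axis extremes are sampled exactly).
#' @param roughness unitless amplitude of the radial noise (>= 0).
#' @param seed integer seed for the roughness draw.
#' @return An object of class `outline_spec`.
#' @export
outline_spec <- function(length, width, n_vertices = 256L, roughness = 0,
                         seed = NULL) {
  stopifnot_positive(length = length, width = width)
  if (n_vertices < 16) stop("`n_vertices` must be at least 16")
  if (roughness < 0) stop("`roughness` must be non-negative")
  n_vertices <- as.integer(4 * ceiling(n_vertices / 4))
  structure(list(length = length, width = width, n_vertices = n_vertices,
                 roughness = roughness, seed = seed),
            class = "outline_spec")
}

#' Generate a synthetic leaf outline
#'
#' Produces a closed, simple polygon. With `roughness = 0` the outline is
#' the exact sampled ellipse, so the extents along the two principal axes
#' equal `length` and `width` and the shoelace area converges to
#' `pi * length * width / 4` as `n_vertices` grows. With positive
#' roughness the radius is modulated by low-frequency cosine modes with
#' seeded random coefficients; the modulation is damped automatically if
#' it would drive the radius non-positive, so the polygon stays
#' star-shaped (hence simple).
#'
#' @param spec an [outline_spec()].
#' @param genotype,node optional metadata carried on the outline.
#' @return An object of class `leaf_outline`: list with `vertices`
#'   (n x 2 matrix, mm), `genotype`, `node`, `flattening_cuts`, and the
#'   per-edge cut flag `is_cut` (edge i joins vertex i to i + 1).
#' @examples
#' ol <- gen_outline(outline_spec(12.8, 9.0, 512))
#' polygon_area(ol$vertices) # ~ pi * 6.4 * 4.5
#' @export
gen_outline <- function(spec, genotype = NULL, node = NULL) {
  stopifnot(inherits(spec, "outline_spec"))
  n <- spec$n_vertices
  a <- spec$length / 2
  b <- spec$width / 2
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  f <- rep(1, n)
  if (spec$roughness > 0) {
    harmonics <- 2:5
    co <- with_seed(spec$seed, {
      amp <- spec$roughness * rnorm(length(harmonics)) / harmonics
      ph <- runif(length(harmonics), 0, 2 * pi)
      list(amp = amp, ph = ph)
    })
    mod <- rowSums(vapply(seq_along(harmonics), function(k)
      co$amp[k] * cos(harmonics[k] * theta + co$ph[k]), numeric(n)))
    tries <- 0L
    while (min(1 + mod) <= 0.2 && tries < 30L) {
      mod <- mod / 2
      tries <- tries + 1L
    }
    if (min(1 + mod) <= 0.2)
      stop("could not damp roughness to a valid outline")
    f <- 1 + mod
  }
  xy <- cbind(x = a * cos(theta) * f, y = b * sin(theta) * f)
  new_leaf_outline(xy, genotype = genotype, node = node)
}

#' Construct a leaf outline from vertices
#'
#' @param vertices n x 2 matrix (or data frame) of ordered boundary
#'   vertices in mm; the polygon is closed implicitly.
#' @param genotype,node optional metadata.
#' @param flattening_cuts was the physical leaf cut to flatten it?
#' @param is_cut logical per-edge flag marking cut (artificial) edges;
#'   edge `i` joins vertex `i` to vertex `i + 1` (last edge closes).
#' @param check verify the polygon is simple (non-self-intersecting).
#' @export
new_leaf_outline <- function(vertices, genotype = NULL, node = NULL,
                             flattening_cuts = FALSE, is_cut = NULL,
                             check = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2) stop("`vertices` must have two columns")
  if (nrow(vertices) < 3) stop("an outline needs at least 3 vertices")
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  if (is.null(is_cut)) is_cut <- rep(FALSE, nrow(vertices))
  if (length(is_cut) != nrow(vertices))
    stop("`is_cut` must have one flag per edge (= per vertex)")
  if (check && !polygon_is_simple(vertices))
    stop("outline polygon is self-intersecting")
  structure(list(vertices = vertices, genotype = genotype, node = node,
                 flattening_cuts = isTRUE(flattening_cuts),
                 is_cut = as.logical(is_cut)),
            class = "leaf_outline")
}

#' @export
print.leaf_outline <- function(x, ...) {
  cat(sprintf("<leaf_outline> %d vertices%s%s\n", nrow(x$vertices),
              if (!is.null(x$genotype)) paste0(", genotype ", x$genotype) else "",
              if (any(x$is_cut)) sprintf(", %d cut edges", sum(x$is_cut)) else ""))
  invisible(x)
}

#' @export
plot.leaf_outline <- function(x, ..., asp = 1) {
  v <- rbind(x$vertices, x$vertices[1, ])
  plot(v, type = "l", asp = asp, xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}
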