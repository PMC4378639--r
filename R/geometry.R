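#' Elliptical leaf null model
#'
#' Treats a flattened lamina as a planar ellipse with semi-major axis
#' `a = length / 2` and semi-minor axis `b = width / 2`. Used to predict
#' what the curvature proxy P/sqrt(A) of a leaf *would* be from its
#' length and width alone, i.e. with planar-ellipse geometry and no
#' surface curvature.
#'
#' @param a,b semi-axes in mm (`a` need not exceed `b`; round-leaved
#'   genotypes have length:width below 1).
#' @return An object of class `ellipse_model`.
#' @export
ellipse_model <- function(a, b) {
  stopifnot_positive(a = a, b = b)
  structure(list(a = a, b = b), class = "ellipse_model")
}

#' Ellipse perimeter, quadratic-mean approximation
#'
#' Evaluates `P = 2 * pi * sqrt((a^2 + b^2) / 2)`, the quadratic-mean
#' approximation conventionally used for leaf-shape work. It is exact
#' for the circle and overestimates the true perimeter by under 1% for
#' the mild eccentricities of real laminae (compare
#' [ellipse_perimeter_ramanujan()]).
#'
#' @param model an [ellipse_model()].
#' @return Perimeter, mm.
#' @examples
#' ellipse_predicted_perimeter(ellipse_model(6.4, 4.5)) # 34.76
#' @export
ellipse_predicted_perimeter <- function(model) {
  stopifnot(inherits(model, "ellipse_model"))
  2 * pi * sqrt((model$a^2 + model$b^2) / 2)
}

#' Ellipse area
#' @param model an [ellipse_model()].
#' @return `pi * a * b`, square mm.
#' @export
ellipse_area <- function(model) {
  stopifnot(inherits(model, "ellipse_model"))
  pi * model$a * model$b
}

#' Ellipse perimeter, Ramanujan's second approximation
#'
#' High-accuracy closed form (relative error below 1e-9 for the
#' eccentricities arising here); provided so the error of the
#' quadratic-mean approximation can be quantified.
#'
#' @param model an [ellipse_model()].
#' @export
ellipse_perimeter_ramanujan <- function(model) {
  stopifnot(inherits(model, "ellipse_model"))
  a <- model$a; b <- model$b
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Surface-curvature proxy P/sqrt(A)
#'
#' The perimeter divided by the square root of the area: a scale-free
#' shape statistic. For planar shapes it is bounded below by the
#' flat-disc (isoperimetric) value `2 * sqrt(pi)`; for curved laminae
#' measured intrinsically, values below the planar-ellipse prediction
#' indicate net positive (cup-like) Gaussian curvature and values above
#' it indicate net negative (ruffled-margin) curvature. No rounding is
#' applied; round only when reporting.
#'
#' @param perimeter boundary length, mm.
#' @param area surface area, square mm.
#' @return Unitless proxy value.
#' @examples
#' curvature_proxy(36.3, 90.3)  # 3.82, reported as 3.8
#' curvature_proxy(42.7, 179.5) # 3.19, reported as 3.2
#' @export
curvature_proxy <- function(perimeter, area) {
  stopifnot_positive(perimeter = perimeter, area = area)
  perimeter / sqrt(area)
}

#' Predicted P/sqrt(A) of a planar elliptical leaf
#'
#' Combines the quadratic-mean perimeter approximation with the exact
#' ellipse area, using `a = length / 2`, `b = width / 2`. The result
#' depends only on the length:width ratio (it is invariant to uniform
#' scaling), so a genotype's predicted proxy can be computed from its
#' leaf index alone.
#'
#' @param length,width lamina extents, mm (or any common unit).
#' @return Unitless predicted proxy.
#' @examples
#' predicted_proxy_from_length_width(1.4, 1) # ~3.64, i.e. ~3.6
#' predicted_proxy_from_length_width(0.9, 1) # ~3.55, i.e. ~3.6
#' @export
predicted_proxy_from_length_width <- function(length, width) {
  m <- ellipse_model(length / 2, width / 2)
  ellipse_predicted_perimeter(m) / sqrt(ellipse_area(m))
}

#' Intrinsic surface metrics of a lamina mesh
#'
#' Computes surface area (sum of triangle areas), boundary perimeter
#' (sum of rim edge lengths), and their proxy P/sqrt(A) directly on the
#' 3-D mesh. Because both quantities are intrinsic, this equals the
#' value that would be measured after cutting and flattening the
#' surface, provided cut edges are excluded from the perimeter -- the
#' flattening convention used for physical cup-shaped leaves -- without
#' performing any flattening.
#'
#' The curvature class compares the proxy with the flat-disc reference
#' `2 * sqrt(pi)`: within `tol` (relative) is `flat`; below is
#' `positive` (cup/dome); above is `negative` (saddle/ruffle). The
#' default band of 2% exceeds the discretisation error of
#' default-resolution meshes. The classification is meaningful for
#' disc-like rims; elongated planar outlines also raise the proxy.
#'
#' @param mesh a `leaf_mesh`.
#' @param tol relative half-width of the `flat` band (default 0.02).
#' @return An object of class `surface_metrics`: list with
#'   `surface_area`, `boundary_perimeter`, `proxy`, `curvature_class`.
#' @examples
#' mesh_metrics(gen_surface(surface_spec("flat_disc", radius = 1)))
#' @export
mesh_metrics <- function(mesh, tol = 0.02) {
  stopifnot(inherits(mesh, "leaf_mesh"))
  ta <- triangle_areas(mesh)
  if (any(ta <= 0)) stop("mesh contains degenerate triangles")
  loops <- boundary_loops(mesh)
  if (length(loops) == 0L)
    stop("mesh is closed (no boundary); lamina meshes must have a rim")
  if (length(loops) > 1L)
    stop("mesh has multiple boundary loops; re-join cut pieces or measure ",
         "each piece excluding cut edges")
  loop <- loops[[1]]
  v <- mesh$vertices
  d <- v[c(loop[-1], loop[1]), , drop = FALSE] - v[loop, , drop = FALSE]
  perim <- sum(sqrt(rowSums(d^2)))
  area <- sum(ta)
  proxy <- perim / sqrt(area)
  cls <- if (abs(proxy - FLAT_DISC_PROXY) <= tol * FLAT_DISC_PROXY) "flat"
         else if (proxy < FLAT_DISC_PROXY) "positive" else "negative"
  structure(list(surface_area = area, boundary_perimeter = perim,
                 proxy = proxy, curvature_class = cls),
            class = "surface_metrics")
}

#' @export
print.surface_metrics <- function(x, ...) {
  cat(sprintf("<surface_metrics> A = %.4f mm2, P = %.4f mm, P/sqrt(A) = %.3f [%s curvature]\n",
              x$surface_area, x$boundary_perimeter, x$proxy, x$curvature_class))
  invisible(x)
}
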