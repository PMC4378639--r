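#' Specification for a synthetic lamina surface mesh
#'
#' Three canonical shapes carry the three signs of Gaussian curvature:
#' a flat disc (zero), a spherical cap (positive, cup-like), and a
#' saddle `z = k * x * y` over a disc (negative, margin-excess).
#'
#' @param kind `"flat_disc"`, `"spherical_cap"`, or `"saddle"`.
#' @param radius disc radius, or sphere radius for the cap, mm.
#' @param curvature_param for `spherical_cap`, the half-angle of the cap
#'   in radians (0, pi\]); for `saddle`, the coefficient `k` of the
#'   height field `z = k * x * y` (1/mm); ignored for `flat_disc`.
#' @param mesh_resolution target edge length, mm.
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(kind = c("flat_disc", "spherical_cap", "saddle"),
                         radius = 1, curvature_param = NULL,
                         mesh_resolution = radius / 20) {
  kind <- match.arg(kind)
  stopifnot_positive(radius = radius, mesh_resolution = mesh_resolution)
  if (kind == "spherical_cap") {
    if (is.null(curvature_param) || curvature_param <= 0 || curvature_param > pi)
      stop("spherical_cap needs a half-angle in (0, pi]")
  }
  if (kind == "saddle" && is.null(curvature_param))
    stop("saddle needs the height-field coefficient k")
  structure(list(kind = kind, radius = radius,
                 curvature_param = curvature_param,
                 mesh_resolution = mesh_resolution),
            class = "surface_spec")
}

# Triangulated disc in polar layout: a centre vertex plus rings i = 1..nr
# with 6*i vertices each; annuli are triangulated by merging the two ring
# sequences in angular order. Returns list(vertices = (r, angle) pairs as
# polar coords, faces).
disc_triangulation <- function(nr) {
  stopifnot(nr >= 2)
  ring_n <- 6L * seq_len(nr)
  ring_start <- cumsum(c(2L, ring_n[-nr]))  # first vertex index of each ring
  n_v <- 1L + sum(ring_n)
  r <- numeric(n_v); ang <- numeric(n_v)
  r[1] <- 0; ang[1] <- 0
  for (i in seq_len(nr)) {
    idx <- ring_start[i] + seq_len(ring_n[i]) - 1L
    r[idx] <- i / nr
    ang[idx] <- 2 * pi * (seq_len(ring_n[i]) - 1L) / ring_n[i]
  }
  faces <- vector("list", nr)
  # fan around the centre
  first <- ring_start[1] + seq_len(ring_n[1]) - 1L
  faces[[1]] <- cbind(1L, first, c(first[-1], first[1]))
  for (i in 2:nr) {
    inner <- ring_start[i - 1L] + seq_len(ring_n[i - 1L]) - 1L
    outer <- ring_start[i] + seq_len(ring_n[i]) - 1L
    fi <- merge_rings(inner, ang[inner], outer, ang[outer])
    faces[[i]] <- fi
  }
  list(r = r, angle = ang, faces = do.call(rbind, faces),
       boundary = ring_start[nr] + seq_len(ring_n[nr]) - 1L)
}

# Triangulate the annulus between two concentric vertex rings by a
# two-pointer sweep: at each step advance along the ring whose next
# vertex comes first in angle, consuming each ring's edges exactly once.
merge_rings <- function(inner, a_in, outer, a_out) {
  ni <- length(inner); no <- length(outer)
  faces <- matrix(0L, ni + no, 3L)
  ci <- 1L; co <- 1L          # current vertex index on each ring
  used_in <- 0L; used_out <- 0L
  adv_in <- function(k) if (k == ni) 1L else k + 1L
  adv_out <- function(k) if (k == no) 1L else k + 1L
  for (f in seq_len(ni + no)) {
    ai_next <- if (used_in < ni)
      a_in[adv_in(ci)] + if (adv_in(ci) == 1L) 2 * pi else 0 else Inf
    ao_next <- if (used_out < no)
      a_out[adv_out(co)] + if (adv_out(co) == 1L) 2 * pi else 0 else Inf
    if (ai_next <= ao_next) {
      faces[f, ] <- c(outer[co], inner[ci], inner[adv_in(ci)])
      ci <- adv_in(ci); used_in <- used_in + 1L
    } else {
      faces[f, ] <- c(outer[co], outer[adv_out(co)], inner[ci])
      co <- adv_out(co); used_out <- used_out + 1L
    }
  }
  faces
}

#' Generate a triangulated lamina surface
#'
#' @param spec a [surface_spec()].
#' @return An object of class `leaf_mesh`: list with `vertices` (n x 3
#'   matrix, mm), `faces` (m x 3 integer matrix, 1-based), and the spec.
#'   The mesh has exactly one boundary loop (the rim).
#' @examples
#' hemi <- gen_surface(surface_spec("spherical_cap", radius = 1,
#'                                  curvature_param = pi / 2))
#' mesh_metrics(hemi)
#' @export
gen_surface <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  R <- spec$radius
  arc <- switch(spec$kind,
    flat_disc = R,
    saddle = R,
    spherical_cap = R * spec$curvature_param)
  nr <- max(3L, as.integer(ceiling(arc / spec$mesh_resolution)))
  tri <- disc_triangulation(nr)
  v <- switch(spec$kind,
    flat_disc = cbind(R * tri$r * cos(tri$angle), R * tri$r * sin(tri$angle), 0),
    saddle = {
      x <- R * tri$r * cos(tri$angle); y <- R * tri$r * sin(tri$angle)
      cbind(x, y, spec$curvature_param * x * y)
    },
    spherical_cap = {
      phi <- tri$r * spec$curvature_param  # polar angle from the pole
      cbind(R * sin(phi) * cos(tri$angle), R * sin(phi) * sin(tri$angle),
            R * cos(phi))
    })
  colnames(v) <- c("x", "y", "z")
  mesh <- structure(list(vertices = v, faces = tri$faces, spec = spec),
                    class = "leaf_mesh")
  ta <- triangle_areas(mesh)
  if (any(ta <= 0)) stop("mesh resolution produced degenerate triangles")
  bl <- boundary_loops(mesh)
  if (length(bl) != 1L)
    stop("mesh does not have exactly one boundary loop; refine the resolution")
  mesh
}

#' Construct a mesh from vertex and face tables
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @export
new_leaf_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop("`vertices` must be n x 3 and `faces` m x 3")
  if (max(faces) > nrow(vertices) || min(faces) < 1L)
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, spec = NULL),
            class = "leaf_mesh")
}

#' @export
print.leaf_mesh <- function(x, ...) {
  cat(sprintf("<leaf_mesh> %d vertices, %d faces%s\n", nrow(x$vertices),
              nrow(x$faces),
              if (!is.null(x$spec)) paste0(" (", x$spec$kind, ")") else ""))
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Edges used by exactly one face, assembled into closed loops.
# Returns a list of integer vertex cycles.
boundary_loops <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  once <- names(which(table(key) == 1L))
  bnd <- ed[key %in% once, , drop = FALSE]
  if (!nrow(bnd)) return(list())
  loops <- list()
  used <- logical(nrow(bnd))
  for (s in seq_len(nrow(bnd))) {
    if (used[s]) next
    loop <- integer(0)
    cur <- bnd[s, 1]
    repeat {
      loop <- c(loop, cur)
      row <- which(!used & bnd[, 1] == cur)
      if (!length(row)) break
      used[row[1]] <- TRUE
      cur <- bnd[row[1], 2]
      if (cur == loop[1]) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}
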