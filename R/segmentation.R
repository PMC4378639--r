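#' Two-class pixel classification of a stained-tissue image
#'
#' Separates stain-positive pixels from background. The default uses a
#' stain-discriminant channel -- blue minus the mean of red and green,
#' appropriate for the indigo histochemical stain -- thresholded by
#' Otsu's bimodal-histogram criterion. Alternatively, labelled training
#' strokes drive a nearest-mean RGB classifier. Both routes are fully
#' deterministic given the image and configuration.
#'
#' @param image a `gus_image`, or an H x W x 3 array in \[0, 1\] (in
#'   which case `pixel_size_um` must be given).
#' @param training optional list with `positive` and `background`, each
#'   an n x 2 matrix of (row, col) pixel coordinates of a labelled
#'   stroke -- or a list of such matrices, one per stroke; switches to
#'   the nearest-stroke-mean classifier. Multi-modal classes (e.g. pale
#'   background plus dark cell walls) need one stroke per mode.
#' @param threshold optional fixed threshold on the discriminant
#'   channel, overriding Otsu.
#' @param pixel_size_um microns per pixel when `image` is a bare array.
#' @param median_radius radius of the edge-preserving median filter
#'   applied to the discriminant channel before thresholding (the
#'   "local intensity" feature; default 1, i.e. a 3 x 3 window). Set 0
#'   to disable. Median filtering leaves noise-free piecewise-constant
#'   images essentially unchanged while suppressing pixel noise.
#' @return An object of class `gus_mask`: list with `mask` (H x W
#'   logical), `pixel_size_um`, and the threshold used (`NA` for the
#'   nearest-mean route).
#' @export
classify_pixels <- function(image, training = NULL, threshold = NULL,
                            pixel_size_um = NULL, median_radius = 1) {
  if (inherits(image, "gus_image")) {
    px <- image$pixels
    pixel_size_um <- image$pixel_size_um
  } else {
    px <- image
    if (is.null(pixel_size_um))
      stop("`pixel_size_um` is required for a bare pixel array")
  }
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("`image` must be an H x W x 3 RGB array")
  if (!is.null(training)) {
    stroke_means <- function(strokes) {
      if (is.matrix(strokes)) strokes <- list(strokes)
      t(vapply(strokes, function(rc)
        colMeans(t(apply(rc, 1, function(p) px[p[1], p[2], ]))), numeric(3)))
    }
    mu_pos <- stroke_means(training$positive)
    mu_bg <- stroke_means(training$background)
    dist_to <- function(mu) {
      d <- matrix(Inf, dim(px)[1], dim(px)[2])
      for (i in seq_len(nrow(mu)))
        d <- pmin(d, (px[, , 1] - mu[i, 1])^2 + (px[, , 2] - mu[i, 2])^2 +
                    (px[, , 3] - mu[i, 3])^2)
      d
    }
    mask <- dist_to(mu_pos) < dist_to(mu_bg)
    thr <- NA_real_
  } else {
    disc <- px[, , 3] - (px[, , 1] + px[, , 2]) / 2   # stain discriminant
    disc01 <- (disc + 1) / 2                           # map [-1, 1] -> [0, 1]
    if (median_radius > 0)
      disc01 <- EBImage::imageData(
        EBImage::medianFilter(EBImage::Image(disc01), as.integer(median_radius)))
    if (diff(range(disc01)) < 1e-6) {
      warning("image has a constant discriminant channel; no stain detected")
      mask <- matrix(FALSE, nrow(disc01), ncol(disc01))
      thr <- NA_real_
    } else {
      thr <- if (!is.null(threshold)) (threshold + 1) / 2
             else EBImage::otsu(EBImage::Image(disc01), range = c(0, 1))
      mask <- disc01 > thr
      thr <- 2 * thr - 1
    }
  }
  structure(list(mask = mask, pixel_size_um = pixel_size_um,
                 threshold = thr),
            class = "gus_mask")
}

#' @export
print.gus_mask <- function(x, ...) {
  cat(sprintf("<gus_mask> %d x %d px, %.1f%% positive%s\n",
              ncol(x$mask), nrow(x$mask), 100 * mean(x$mask),
              if (is.finite(x$threshold))
                sprintf(" (threshold %.3f)", x$threshold) else ""))
  invisible(x)
}

# 8-connected labelling: 4-connected components from EBImage::bwlabel,
# then components touching diagonally are merged through a label graph.
label_components_8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  mx <- max(lab)
  if (mx <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1])))  # up-right
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (!nrow(pairs)) return(lab)
  g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(as.character(seq_len(mx)),
                                              igraph::V(g)$name)),
                            name = setdiff(as.character(seq_len(mx)),
                                           igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  remap <- integer(mx)
  remap[as.integer(names(comp))] <- comp
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Count stained objects in a classified mask
#'
#' Labels 8-connected components, discards objects below a minimum
#' area, and reports counts, centroids (microns), and areas. Optionally
#' splits merged touching objects with one round of watershed on the
#' distance transform.
#'
#' @param mask a `gus_mask` (or a logical matrix plus `pixel_size_um`).
#' @param min_area_um2 minimum object area retained; the renderer's
#'   counterpart default is a quarter of the target cell area.
#' @param pixel_size_um microns per pixel for a bare matrix.
#' @param split_touching split merged touching objects with one round
#'   of watershed on the distance transform before filtering (default
#'   TRUE: stained neighbours separated only by thin cell walls
#'   otherwise fuse under pixel noise).
#' @param watershed_tolerance minimum depth (in distance-transform
#'   pixels) between objects for watershed to split them; small values
#'   split aggressively, large values conservatively.
#' @return An object of class `object_set`: list with `count`,
#'   `objects` (data frame `label`, `x_um`, `y_um`, `area_um2`), and
#'   the label matrix.
#' @export
count_objects <- function(mask, min_area_um2 = 0, pixel_size_um = NULL,
                          split_touching = TRUE, watershed_tolerance = 1) {
  if (inherits(mask, "gus_mask")) {
    m <- mask$mask
    pixel_size_um <- mask$pixel_size_um
  } else {
    m <- mask
    if (is.null(pixel_size_um))
      stop("`pixel_size_um` is required for a bare mask matrix")
  }
  if (min_area_um2 < 0) stop("`min_area_um2` must be non-negative")
  if (!any(m)) {
    return(structure(list(count = 0L,
                          objects = data.frame(label = integer(0),
                                               x_um = numeric(0),
                                               y_um = numeric(0),
                                               area_um2 = numeric(0)),
                          labels = matrix(0L, nrow(m), ncol(m)),
                          pixel_size_um = pixel_size_um),
                     class = "object_set"))
  }
  if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(m * 1))
    lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance))
    lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  } else {
    lab <- label_components_8(m)
  }
  px_area <- pixel_size_um^2
  tab <- tabulate(lab[lab > 0L])
  keep <- which(tab * px_area >= min_area_um2)
  remap <- integer(length(tab))
  remap[keep] <- seq_along(keep)
  out_lab <- lab
  out_lab[lab > 0L] <- remap[lab[lab > 0L]]
  if (!length(keep)) {
    objects <- data.frame(label = integer(0), x_um = numeric(0),
                          y_um = numeric(0), area_um2 = numeric(0))
  } else {
    pos <- which(out_lab > 0L, arr.ind = TRUE)
    l <- out_lab[pos]
    # array row = y (proximo-distal), column = x (medio-lateral)
    x_um <- (tapply(pos[, 2], l, mean) - 0.5) * pixel_size_um
    y_um <- (tapply(pos[, 1], l, mean) - 0.5) * pixel_size_um
    objects <- data.frame(label = seq_along(keep),
                          x_um = as.numeric(x_um),
                          y_um = as.numeric(y_um),
                          area_um2 = tab[keep] * px_area)
  }
  structure(list(count = nrow(objects), objects = objects, labels = out_lab,
                 pixel_size_um = pixel_size_um),
            class = "object_set")
}

#' @export
print.object_set <- function(x, ...) {
  cat(sprintf("<object_set> %d objects", x$count))
  if (x$count > 0)
    cat(sprintf(", median area %.0f um2", stats::median(x$objects$area_um2)))
  cat("\n")
  invisible(x)
}

#' Per-field counts from segmented objects
#'
#' Assigns detected stained objects to the medio-lateral counting
#' fields of a cell map (total cell counts per field come from the
#' map's lattice), yielding the same `cell_fields` table as manual
#' counting so that [fraction_profile()] applies to either route.
#'
#' @param objects an `object_set` from [count_objects()].
#' @param map the `cell_map` the image was rendered from (supplies the
#'   field geometry and total cell counts).
#' @param band,field_w_um,field_h_um as in [bin_fields()].
#' @return A `cell_fields` data frame with `n_gus` replaced by the
#'   automated object counts. Objects falling outside all fields are
#'   dropped with a message.
#' @export
per_field_fractions <- function(objects, map, band = NULL,
                                field_w_um = 200, field_h_um = 100) {
  stopifnot(inherits(objects, "object_set"), inherits(map, "cell_map"))
  fields <- bin_fields(map, band = band, field_w_um = field_w_um,
                       field_h_um = field_h_um)
  if (is.null(band)) band <- c(0, map$height_um)
  if (diff(band) > field_h_um) band <- mean(band) + c(-0.5, 0.5) * field_h_um
  ob <- objects$objects
  inb <- ob$y_um >= band[1] & ob$y_um < band[2] &
    ob$x_um >= 0 & ob$x_um <= map$width_um
  if (any(!inb))
    message(sum(!inb), " object(s) outside the counting fields were ignored")
  ob <- ob[inb, , drop = FALSE]
  edges <- field_edges(map$width_um, field_w_um)
  nf <- length(edges) - 1L
  idx <- findInterval(ob$x_um, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > nf] <- nf
  fields$n_gus <- as.integer(tabulate(idx, nbins = nf))
  fields
}
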