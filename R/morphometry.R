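#' Planar shape metrics of a leaf outline
#'
#' Length is the maximal extent along the outline's principal axis (the
#' major axis of the polygon's area distribution, a proxy for the
#' proximo-distal blade axis that does not depend on how the outline was
#' digitised); width is the maximal orthogonal extent. Perimeter is the
#' boundary arc length, optionally after smoothing the boundary radius
#' with a circular moving average -- the "measure through the middle of
#' the serrations" convention; smoothing is off by default because the
#' mature leaves this targets are unserrated. Area is the shoelace
#' area, and the curvature proxy is `perimeter / sqrt(area)`.
#'
#' For leaves that are wider than long the principal axis is the
#' medio-lateral one, so geometry alone cannot tell which extent is the
#' blade length; pass `axis` explicitly in that case (the physical
#' measurement likewise uses the petiole to orient the blade).
#'
#' @param outline a `leaf_outline`.
#' @param smooth_window odd integer window (in vertices) for the radial
#'   moving average; 0 disables smoothing.
#' @param check test the polygon for self-intersection first.
#' @param axis `"principal"` (default), or the proximo-distal axis as
#'   an angle in radians from the x-axis (e.g. `0` when the outline is
#'   digitised base-to-tip along x).
#' @return An object of class `shape_metrics`: list with `length`,
#'   `width`, `perimeter`, `area`, `length_width_ratio`,
#'   `curvature_proxy`.
#' @examples
#' ol <- gen_outline(outline_spec(12.8, 9.0, 2048))
#' measure_outline(ol)
#' @export
measure_outline <- function(outline, smooth_window = 0, check = TRUE,
                            axis = "principal") {
  stopifnot(inherits(outline, "leaf_outline"))
  xy <- outline$vertices
  if (check && !polygon_is_simple(xy))
    stop("outline polygon is self-intersecting")
  if (smooth_window > 1) xy <- smooth_radius(xy, smooth_window)
  ang <- if (identical(axis, "principal")) polygon_principal_angle(xy)
         else as.numeric(axis)
  len <- diff(range(xy %*% c(cos(ang), sin(ang))))
  wid <- diff(range(xy %*% c(-sin(ang), cos(ang))))
  per <- polygon_perimeter(xy)
  area <- polygon_area(xy)
  if (area <= 0) stop("outline has zero area")
  structure(list(length = len, width = wid, perimeter = per, area = area,
                 length_width_ratio = len / wid,
                 curvature_proxy = per / sqrt(area)),
            class = "shape_metrics")
}

# circular moving average of the boundary radius about the centroid
smooth_radius <- function(xy, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  c0 <- polygon_centroid(xy)
  dx <- xy[, 1] - c0[1]; dy <- xy[, 2] - c0[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  n <- length(r)
  half <- window %/% 2L
  rext <- c(tail(r, half), r, head(r, half))
  rs <- stats::filter(rext, rep(1 / window, window), sides = 2)
  rs <- as.numeric(rs)[half + seq_len(n)]
  cbind(x = c0[1] + rs * cos(th), y = c0[2] + rs * sin(th))
}

#' @export
print.shape_metrics <- function(x, digits = 1, ...) {
  cat(sprintf(
    "<shape_metrics> L %.*f x W %.*f mm, P %.*f mm, A %.*f mm2, L:W %.2f, P/sqrt(A) %.*f\n",
    digits, x$length, digits, x$width, digits, x$perimeter, digits, x$area,
    x$length_width_ratio, digits, x$curvature_proxy))
  invisible(x)
}

#' @export
as.data.frame.shape_metrics <- function(x, ...) {
  data.frame(length_mm = x$length, width_mm = x$width,
             perimeter_mm = x$perimeter, area_mm2 = x$area,
             length_width_ratio = x$length_width_ratio,
             curvature_proxy = x$curvature_proxy)
}

#' Perimeter of a leaf measured in pieces, excluding cut edges
#'
#' Physically flattening a curved or crinkly leaf requires cutting it;
#' the blade margin is then measured piece by piece, the freshly cut
#' edges are excluded, and the pieces are summed. This reproduces that
#' convention on outline polygons whose edges carry a cut flag: the
#' result equals the intact perimeter for any partition.
#'
#' @param pieces list of `leaf_outline` objects with `is_cut` edge flags
#'   (see [split_outline_by_line()]).
#' @return Total margin length, mm.
#' @export
piecewise_perimeter <- function(pieces) {
  if (inherits(pieces, "leaf_outline")) pieces <- list(pieces)
  stopifnot(length(pieces) >= 1, all(vapply(pieces, inherits, TRUE, "leaf_outline")))
  total <- 0
  for (p in pieces) {
    if (all(p$is_cut)) {
      warning("a piece has all edges marked as cuts; it contributes 0")
      next
    }
    xy <- p$vertices
    n <- nrow(xy)
    j <- c(seq_len(n)[-1], 1L)
    el <- sqrt(rowSums((xy[j, , drop = FALSE] - xy)^2))
    total <- total + sum(el[!p$is_cut])
  }
  total
}

#' Split an outline along a straight cut
#'
#' Cuts the polygon with the line through `point` in direction `dir`,
#' returning the pieces on either side with the new edges lying on the
#' cut line flagged as cuts. Non-convex outlines may yield several
#' disconnected fragments per side; each side is still returned as a
#' single vertex cycle whose bridging segments lie on the cut line and
#' are therefore flagged, so cut-excluded perimeter is conserved.
#'
#' @param outline a `leaf_outline`.
#' @param point length-2 numeric, a point on the cut line (mm).
#' @param dir length-2 numeric, direction of the cut line.
#' @param tol absolute tolerance for "vertex lies on the cut line".
#' @return List of `leaf_outline` pieces (one or two entries).
#' @export
split_outline_by_line <- function(outline, point, dir, tol = NULL) {
  stopifnot(inherits(outline, "leaf_outline"))
  nrm <- c(-dir[2], dir[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  xy <- outline$vertices
  if (is.null(tol)) tol <- 1e-9 * max(abs(xy))
  # cut edges already present (from earlier splits) must survive the clip
  old_cuts <- which(outline$is_cut)
  nseg <- nrow(xy)
  pieces <- list()
  for (side in c(1, -1)) {
    cp <- clip_halfplane(xy, point, side * nrm)
    if (nrow(cp) < 3) next
    d <- abs((cp[, 1] - point[1]) * nrm[1] + (cp[, 2] - point[2]) * nrm[2])
    on_line <- d < tol
    n <- nrow(cp)
    nxt <- c(seq_len(n)[-1], 1L)
    is_cut <- on_line & on_line[nxt]
    if (length(old_cuts)) {
      # a surviving sub-edge of a parent cut edge has its midpoint on
      # that parent segment
      mx <- (cp[, 1] + cp[nxt, 1]) / 2
      my <- (cp[, 2] + cp[nxt, 2]) / 2
      for (e in old_cuts) {
        a <- xy[e, ]; b <- xy[if (e == nseg) 1L else e + 1L, ]
        ab <- b - a
        L2 <- sum(ab^2)
        if (L2 == 0) next
        t <- ((mx - a[1]) * ab[1] + (my - a[2]) * ab[2]) / L2
        dist <- abs((mx - a[1]) * ab[2] - (my - a[2]) * ab[1]) / sqrt(L2)
        is_cut <- is_cut | (dist < tol & t > -tol & t < 1 + tol)
      }
    }
    pieces[[length(pieces) + 1L]] <-
      new_leaf_outline(cp, genotype = outline$genotype, node = outline$node,
                       flattening_cuts = TRUE, is_cut = is_cut, check = FALSE)
  }
  pieces
}

#' Width growth rates and peak rate
#'
#' Centred finite-difference rates on the sampling grid (one-sided at
#' the ends), with an optional moving-average pre-smoothing of the
#' widths. No smoothing is applied by default: peak rates are reported
#' from the raw alternate-day samples, as in the measurement protocol
#' this mirrors.
#'
#' @param series a `growth_series` data frame (columns `day`,
#'   `width_mm`), or any data frame with those columns.
#' @param smooth_window odd moving-average window over time points; 0
#'   disables.
#' @return An object of class `growth_rates`: list with `rates` (data
#'   frame `day`, `rate_mm_per_day`) and `peak_rate`.
#' @export
growth_rates <- function(series, smooth_window = 0) {
  if (!all(c("day", "width_mm") %in% names(series)))
    stop("`series` needs columns `day` and `width_mm`")
  day <- series$day; w <- series$width_mm
  if (length(day) < 3) stop("at least 3 time points are required")
  if (any(diff(day) <= 0)) stop("`day` must be strictly increasing")
  if (any(w < 0)) stop("widths must be non-negative")
  if (smooth_window > 1) {
    k <- as.integer(smooth_window); if (k %% 2L == 0L) k <- k + 1L
    w <- as.numeric(stats::filter(w, rep(1 / k, k), sides = 2))
    # shrink one-sided at the ends rather than dropping points
    half <- k %/% 2L
    for (i in seq_len(half)) {
      w[i] <- mean(series$width_mm[seq_len(i + half)])
      j <- length(w) - i + 1L
      w[j] <- mean(series$width_mm[seq(j - half, length(w))])
    }
  }
  n <- length(day)
  rate <- numeric(n)
  rate[1] <- (w[2] - w[1]) / (day[2] - day[1])
  rate[n] <- (w[n] - w[n - 1]) / (day[n] - day[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    rate[i] <- (w[i + 1] - w[i - 1]) / (day[i + 1] - day[i - 1])
  }
  structure(list(rates = data.frame(day = day, rate_mm_per_day = rate),
                 peak_rate = max(rate)),
            class = "growth_rates")
}

#' @export
print.growth_rates <- function(x, ...) {
  cat(sprintf("<growth_rates> %d intervals, peak %.3f mm/day (day %g)\n",
              nrow(x$rates), x$peak_rate,
              x$rates$day[which.max(x$rates$rate_mm_per_day)]))
  invisible(x)
}

#' Mean epidermal cell size from counting fields
#'
#' Per-field cell size is field area divided by the number of cells in
#' the field; the leaf-level estimate is the mean over fields, with its
#' SEM. A warning is issued when fewer than `min_fields` fields are
#' supplied (the measurement convention averages at least eight).
#'
#' @param fields data frame with columns `field_area_um2` and `n_cells`.
#' @param min_fields minimum number of fields before warning.
#' @return List with `mean_um2`, `sem_um2`, `n_fields`, and the
#'   per-field sizes.
#' @export
mean_cell_size <- function(fields, min_fields = 8) {
  if (!NROW(fields)) stop("no counting fields supplied")
  if (!all(c("field_area_um2", "n_cells") %in% names(fields)))
    stop("`fields` needs columns `field_area_um2` and `n_cells`")
  if (any(fields$field_area_um2 <= 0)) stop("field areas must be positive")
  if (any(fields$n_cells < 1)) stop("each field must contain at least one cell")
  if (nrow(fields) < min_fields)
    warning(sprintf("only %d counting fields (minimum recommended is %d)",
                    nrow(fields), min_fields))
  sizes <- fields$field_area_um2 / fields$n_cells
  k <- length(sizes)
  list(mean_um2 = mean(sizes),
       sem_um2 = if (k > 1) sd(sizes) / sqrt(k) else 0,
       n_fields = k, sizes_um2 = sizes)
}

#' Estimate epidermal cell count from leaf area and mean cell size
#'
#' `leaf_area * 1e6 / mean_cell_size`: the number of pavement cells per
#' epidermal surface. Exactly inverse-linear in cell size.
#'
#' @param leaf_area_mm2 lamina area, square mm.
#' @param mean_cell_size_um2 mean pavement-cell area, square microns.
#' @return Estimated cell count (not rounded).
#' @examples
#' estimate_cell_count(90.3, 6000) # ~15000
#' @export
estimate_cell_count <- function(leaf_area_mm2, mean_cell_size_um2) {
  stopifnot_positive(leaf_area_mm2 = leaf_area_mm2,
                     mean_cell_size_um2 = mean_cell_size_um2)
  leaf_area_mm2 * 1e6 / mean_cell_size_um2
}

#' Trichome branch-number frequencies
#'
#' @param table data frame with columns `branches` and `count`, or a
#'   named vector of counts (names = branch numbers).
#' @return Data frame `branches`, `count`, `percent`; percentages sum
#'   to 100.
#' @export
trichome_frequencies <- function(table) {
  if (is.numeric(table) && !is.null(names(table)))
    table <- data.frame(branches = as.integer(names(table)),
                        count = as.numeric(table))
  if (!NROW(table)) stop("empty trichome table")
  if (!all(c("branches", "count") %in% names(table)))
    stop("`table` needs columns `branches` and `count`")
  if (any(table$count < 0)) stop("counts must be non-negative")
  total <- sum(table$count)
  if (total <= 0) stop("total trichome count must be positive")
  out <- table[order(table$branches), c("branches", "count")]
  out$percent <- 100 * out$count / total
  rownames(out) <- NULL
  out
}

#' Cell-size frequency distribution
#'
#' Histogram of per-cell (or per-field mean) areas, kept separate per
#' surface group (adaxial/abaxial) when one is given.
#'
#' @param samples_um2 numeric vector of cell sizes, square microns.
#' @param bin_edges histogram break points (square microns); must span
#'   the samples.
#' @param group optional factor (e.g. adaxial/abaxial) splitting the
#'   samples.
#' @param normalize return relative frequencies instead of counts.
#' @return Data frame with `bin_low`, `bin_high`, one column per group
#'   (or `count`), class `cell_size_histogram`.
#' @export
cell_size_histogram <- function(samples_um2, bin_edges, group = NULL,
                                normalize = FALSE) {
  if (!length(samples_um2)) stop("no cell-size samples")
  if (any(samples_um2 < min(bin_edges)) || any(samples_um2 > max(bin_edges)))
    stop("`bin_edges` must span all samples")
  tab1 <- function(x) {
    ct <- as.numeric(table(cut(x, bin_edges, include.lowest = TRUE)))
    if (normalize) ct / sum(ct) else ct
  }
  nb <- length(bin_edges) - 1L
  out <- data.frame(bin_low = bin_edges[-length(bin_edges)],
                    bin_high = bin_edges[-1])
  if (is.null(group)) {
    out$count <- tab1(samples_um2)
  } else {
    group <- as.factor(group)
    for (g in levels(group)) out[[g]] <- tab1(samples_um2[group == g])
  }
  class(out) <- c("cell_size_histogram", "data.frame")
  out
}
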