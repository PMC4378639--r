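#' Bin cells of the transition zone into counting fields
#'
#' Tiles the medio-lateral (midrib-to-margin) axis with rectangular
#' counting fields of `field_w_um` x `field_h_um` (the measurement
#' convention uses 200 x 100 microns) inside a proximo-distal band, and
#' counts total and reporter-positive cells per field. A cell belongs to
#' exactly one field, decided by its centroid. A trailing partial field
#' is kept when it covers at least half a field width, otherwise its
#' cells are merged into the previous field.
#'
#' @param map a `cell_map` (with GUS status assigned for `n_gus` to be
#'   meaningful).
#' @param band length-2 numeric, proximo-distal extent (microns, from
#'   the base) of the strip to profile; default the whole map. If the
#'   band is taller than `field_h_um`, the central `field_h_um` window
#'   of the band is used.
#' @param field_w_um,field_h_um field dimensions, microns.
#' @return Data frame of class `cell_fields`: `field`, `x_center_um`,
#'   `n_total`, `n_gus`.
#' @export
bin_fields <- function(map, band = NULL, field_w_um = 200, field_h_um = 100) {
  stopifnot(inherits(map, "cell_map"))
  stopifnot_positive(field_w_um = field_w_um, field_h_um = field_h_um)
  if (is.null(band)) band <- c(0, map$height_um)
  if (band[1] < 0 || band[2] > map$height_um || band[1] >= band[2])
    stop("`band` must lie within the map's proximo-distal extent")
  if (diff(band) > field_h_um) {
    mid <- mean(band)
    band <- mid + c(-0.5, 0.5) * field_h_um
  }
  cells <- map$cells
  cells <- cells[cells$y_um >= band[1] & cells$y_um < band[2], , drop = FALSE]
  if (!nrow(cells)) stop("no cells inside the requested band")
  edges <- field_edges(map$width_um, field_w_um)
  nf <- length(edges) - 1L
  idx <- findInterval(cells$x_um, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > nf] <- nf
  gus <- cells$gus
  if (all(is.na(gus))) gus <- rep(FALSE, length(gus))
  out <- data.frame(
    field = seq_len(nf),
    x_center_um = (edges[-length(edges)] + edges[-1]) / 2,
    n_total = as.integer(tabulate(idx, nbins = nf)),
    n_gus = as.integer(tabulate(idx[gus %in% TRUE], nbins = nf)))
  class(out) <- c("cell_fields", "data.frame")
  out
}

# Field boundaries tiling [0, W]: full fields of width fw; a trailing
# remainder of at least fw/2 becomes its own field, a smaller one is
# absorbed into the last full field.
field_edges <- function(W, fw) {
  n_full <- floor(W / fw)
  if (n_full < 1L) return(c(0, W))
  rem <- W - n_full * fw
  edges <- seq(0, n_full * fw, by = fw)
  if (rem >= fw / 2) edges <- c(edges, W)
  else if (rem > 0) edges[length(edges)] <- W
  edges
}

#' Medio-lateral reporter fraction profile
#'
#' Fraction of reporter-positive cells per counting field, ordered from
#' midrib to margin, with the per-field binomial standard error.
#'
#' @param fields a `cell_fields` data frame (from [bin_fields()] or
#'   [per_field_fractions()], or hand-built with columns `x_center_um`,
#'   `n_total`, `n_gus`).
#' @param leaf_length_mm,front_position optional metadata: total leaf
#'   length and the band's position as a fraction of leaf length from
#'   the tip (the convention places it at ~0.30-0.40).
#' @return An object of class `front_profile`: the fields data frame
#'   gains `fraction` and `se`; metadata stored as attributes.
#' @export
fraction_profile <- function(fields, leaf_length_mm = NA,
                             front_position = NA) {
  if (!all(c("x_center_um", "n_total", "n_gus") %in% names(fields)))
    stop("`fields` needs columns `x_center_um`, `n_total`, `n_gus`")
  if (nrow(fields) < 3) stop("at least 3 fields are required for a profile")
  if (any(fields$n_total == 0)) stop("a field contains no cells")
  if (any(fields$n_gus > fields$n_total) || any(fields$n_gus < 0))
    stop("0 <= n_gus <= n_total violated")
  if (!is.na(front_position) && (front_position < 0 || front_position > 1))
    stop("`front_position` must be in [0, 1]")
  out <- fields[order(fields$x_center_um), , drop = FALSE]
  out$fraction <- out$n_gus / out$n_total
  out$se <- sqrt(out$fraction * (1 - out$fraction) / out$n_total)
  attr(out, "leaf_length_mm") <- leaf_length_mm
  attr(out, "front_position") <- front_position
  class(out) <- c("front_profile", "data.frame")
  out
}

#' Average front profiles over leaves
#'
#' Profiles measured on replicate leaves are combined per field index.
#' The default averages the per-leaf fractions (each leaf contributes
#' equally); `method = "pooled"` instead pools the raw counts. The
#' standard error reported is the binomial SE at the combined fraction
#' and pooled cell count.
#'
#' @param profiles list of `front_profile` objects with equal field
#'   counts.
#' @param method `"mean"` or `"pooled"`.
#' @return A `front_profile` whose `n_total`/`n_gus` are pooled counts.
#' @export
average_profiles <- function(profiles, method = c("mean", "pooled")) {
  method <- match.arg(method)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "front_profile")))
  nf <- vapply(profiles, nrow, 1L)
  if (length(unique(nf)) != 1L)
    stop("profiles have differing numbers of fields; re-bin to a common grid")
  n_tot <- Reduce(`+`, lapply(profiles, `[[`, "n_total"))
  n_gus <- Reduce(`+`, lapply(profiles, `[[`, "n_gus"))
  frac <- if (method == "mean")
    rowMeans(vapply(profiles, `[[`, numeric(nf[1]), "fraction"))
  else n_gus / n_tot
  out <- data.frame(field = profiles[[1]]$field,
                    x_center_um = profiles[[1]]$x_center_um,
                    n_total = n_tot, n_gus = n_gus, fraction = frac,
                    se = sqrt(frac * (1 - frac) / n_tot))
  attr(out, "n_leaves") <- length(profiles)
  class(out) <- c("front_profile", "data.frame")
  out
}

#' @export
plot.front_profile <- function(x, ...) {
  plot(x$x_center_um, 100 * x$fraction, type = "b", pch = 19,
       xlab = "distance from midrib (um)", ylab = "GUS-positive cells (%)",
       ylim = c(0, max(100 * (x$fraction + 2 * x$se))), ...)
  segments(x$x_center_um, 100 * (x$fraction - x$se),
           x$x_center_um, 100 * (x$fraction + x$se))
  invisible(x)
}

#' Classify the shape of the mitotic arrest front
#'
#' Summarises a medio-lateral profile into one of four qualitative
#' labels. With the fields split into three contiguous thirds from the
#' midrib, let `c` be the mean fraction of the central (midrib-adjacent)
#' third and `m` the mean of the marginal third:
#'
#' * `concave` if `m - c > delta` (more division at the margin);
#' * convex if `c - m > delta`; reported as
#'   `strong_convex_with_midrib_dip` when the profile peak lies at an
#'   interior field and exceeds the midrib-adjacent field by more than
#'   `delta`, and `mild_convex` otherwise;
#' * `flat` when neither difference exceeds `delta`.
#'
#' The default margin `delta = 0.05` is about twice the binomial SE of
#' a 150-cell field at these fractions, so noiseless preset profiles
#' classify deterministically and pooled multi-leaf profiles classify
#' stably.
#'
#' @param profile a `front_profile` with at least 4 fields.
#' @param delta classification margin on fractions.
#' @return An object of class `front_classification`: list with
#'   `label`, `central_mean`, `marginal_mean`, `peak_field`,
#'   `peak_fraction`.
#' @export
classify_front <- function(profile, delta = 0.05) {
  stopifnot(inherits(profile, "front_profile"))
  f <- profile$fraction
  k <- length(f)
  if (k < 4) stop("classification needs at least 4 fields")
  third <- ceiling(k / 3)
  cen <- mean(f[seq_len(third)])
  mar <- mean(f[seq(k - third + 1L, k)])
  peak <- which.max(f)
  label <- if (mar - cen > delta) "concave"
  else if (cen - mar > delta) {
    if (peak > 1 && peak < k && f[peak] - f[1] > delta)
      "strong_convex_with_midrib_dip" else "mild_convex"
  } else "flat"
  structure(list(label = label, central_mean = cen, marginal_mean = mar,
                 peak_field = peak, peak_fraction = f[peak], delta = delta),
            class = "front_classification")
}

#' @export
print.front_classification <- function(x, ...) {
  cat(sprintf("<front_classification> %s (central %.3f, marginal %.3f, peak field %d at %.3f)\n",
              x$label, x$central_mean, x$marginal_mean, x$peak_field,
              x$peak_fraction))
  invisible(x)
}

#' Proliferation-zone length from a midrib-adjacent cell column
#'
#' The proliferation zone is defined operationally as the distance from
#' the lamina base to the point where the fraction of reporter-positive
#' cells adjacent to the midrib first falls to the threshold (~10% by
#' convention). The fraction is evaluated in a sliding proximo-distal
#' window over the cells whose centroid lies within `column_width_um`
#' of the midrib; the zone ends at the base of the first window (from
#' the base upward) whose fraction is at or below `threshold`. If no
#' window falls to the threshold the full leaf length is returned.
#'
#' @param map a `cell_map` spanning base (y = 0) to tip
#'   (y = height), with GUS status assigned.
#' @param threshold fraction defining mitotic arrest (default 0.10).
#' @param column_width_um width of the midrib-adjacent column.
#' @param window_um sliding window height (default 100, matching the
#'   counting-field height).
#' @param step_um window step.
#' @return Zone length in mm.
#' @export
zone_length <- function(map, threshold = 0.10, column_width_um = 200,
                        window_um = 100, step_um = 25) {
  stopifnot(inherits(map, "cell_map"))
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  cells <- map$cells[map$cells$x_um <= column_width_um, , drop = FALSE]
  if (!nrow(cells)) stop("no cells in the midrib-adjacent column")
  if (all(is.na(cells$gus))) stop("GUS status has not been assigned")
  H <- map$height_um
  starts <- seq(0, max(0, H - window_um), by = step_um)
  for (s in starts) {
    inw <- cells$y_um >= s & cells$y_um < s + window_um
    if (!any(inw)) next
    if (mean(cells$gus[inw]) <= threshold) return(s / 1000)
  }
  H / 1000
}

#' Proliferation-zone dynamics: slope of zone length on leaf length
#'
#' Ordinary least squares of zone length against total leaf length
#' across a developmental series of leaves. The slope (mm of zone per
#' mm of leaf) is negative when the zone shrinks as the leaf grows and
#' positive when it keeps expanding.
#'
#' @param records a `zone_series` data frame, or any data frame with
#'   columns `leaf_length_mm` and `zone_length_mm`.
#' @return An object of class `zone_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `n`, and the underlying `lm` fit.
#' @export
zone_slope <- function(records) {
  if (!all(c("leaf_length_mm", "zone_length_mm") %in% names(records)))
    stop("`records` needs columns `leaf_length_mm` and `zone_length_mm`")
  if (nrow(records) < 2) stop("at least 2 records are required")
  if (length(unique(records$leaf_length_mm)) < 2)
    stop("all leaf lengths are equal; the slope is undefined")
  fit <- lm(zone_length_mm ~ leaf_length_mm, data = records)
  # R^2 computed directly (summary.lm warns on noiseless, exact fits)
  tss <- sum((records$zone_length_mm - mean(records$zone_length_mm))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 n = nrow(records), fit = fit),
            class = "zone_fit")
}

#' @export
print.zone_fit <- function(x, ...) {
  cat(sprintf("<zone_fit> slope %+.3f mm/mm, intercept %.3f mm, R2 %.2f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
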