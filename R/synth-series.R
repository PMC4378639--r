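#' Specification for a logistic leaf-width growth series
#'
#' Width growth is modelled as the logistic
#' `w(t) = w_max / (1 + exp(-4 * r_max * (t - t_mid) / w_max))`,
#' parameterised directly by the peak growth rate `r_max` (the analytic
#' maximum of `dw/dt`, attained at `t = t_mid`). Sampling follows the
#' measurement protocol the series emulates: every other day from
#' emergence over 20 days.
#'
#' @param w_max asymptotic width, mm. Wild-type-like default 9 mm.
#' @param r_max peak widening rate, mm/day (wild-type-like 0.5; a
#'   round-leaf mutant-like series would use twice that).
#' @param t_mid day of inflection (default 8).
#' @param noise_sd additive Gaussian measurement noise, mm.
#' @param days sampling days (default `seq(0, 20, by = 2)`).
#' @param seed integer seed for the noise.
#' @export
growth_spec <- function(w_max = 9, r_max = 0.5, t_mid = 8, noise_sd = 0,
                        days = seq(0, 20, by = 2), seed = NULL) {
  stopifnot_positive(w_max = w_max, r_max = r_max)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (length(days) < 3 || any(diff(days) <= 0))
    stop("`days` must be at least 3 strictly increasing time points")
  structure(list(w_max = w_max, r_max = r_max, t_mid = t_mid,
                 noise_sd = noise_sd, days = days, seed = seed),
            class = "growth_spec")
}

#' Generate a leaf-width growth series
#'
#' @param spec a [growth_spec()].
#' @return A `growth_series` data frame with columns `day` and
#'   `width_mm`; the generating parameters are kept as attributes.
#' @examples
#' gs <- gen_growth_series(growth_spec(w_max = 9, r_max = 0.5))
#' growth_rates(gs)$peak_rate # ~ 0.5 mm/day
#' @export
gen_growth_series <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  w <- logistic_width(spec$days, spec$w_max, spec$r_max, spec$t_mid)
  if (spec$noise_sd > 0)
    w <- pmax(0, w + with_seed(spec$seed, rnorm(length(w), 0, spec$noise_sd)))
  out <- data.frame(day = spec$days, width_mm = w)
  attr(out, "spec") <- spec
  class(out) <- c("growth_series", "data.frame")
  out
}

logistic_width <- function(t, w_max, r_max, t_mid) {
  w_max / (1 + exp(-4 * r_max * (t - t_mid) / w_max))
}

#' Specification for a proliferation-zone length series
#'
#' Zone length is linear in total leaf length with Gaussian scatter:
#' `zone = intercept + slope * length + e`, `e ~ N(0, noise_sd^2)`.
#' Values falling outside the physical range \[0, leaf length\] are
#' clipped and flagged. The presets reproduce the two reported regimes:
#' a wild-type-like shrinking zone (slope -0.37 mm/mm, scatter set so a
#' straight-line fit yields R^2 of about 0.67) and a mutant-like growing
#' zone (slope +0.43 mm/mm, R^2 about 0.76), each over leaves 1-3 mm
#' long with n = 20.
#'
#' @param preset `"col0"`, `"tni"`, or `"custom"`.
#' @param slope mm of zone change per mm of leaf length.
#' @param intercept zone length at zero leaf length, mm.
#' @param n_leaves number of leaves (one record each).
#' @param leaf_length_range range of total leaf lengths, mm; lengths are
#'   evenly spaced across it.
#' @param noise_sd residual SD, mm; if `NULL` it is derived from
#'   `target_r2` via [zone_noise_for_r2()].
#' @param target_r2 population R^2 used to calibrate `noise_sd`.
#' @param seed integer seed.
#' @export
zone_series_spec <- function(preset = c("custom", "col0", "tni"),
                             slope = NULL, intercept = NULL, n_leaves = 20L,
                             leaf_length_range = c(1, 3), noise_sd = NULL,
                             target_r2 = NULL, seed = NULL) {
  preset <- match.arg(preset)
  if (preset == "col0") {
    slope <- slope %||% -0.37; intercept <- intercept %||% 1.24
    target_r2 <- target_r2 %||% 0.67
  } else if (preset == "tni") {
    slope <- slope %||% 0.43; intercept <- intercept %||% 0.2
    target_r2 <- target_r2 %||% 0.76
  }
  if (is.null(slope) || is.null(intercept))
    stop("`slope` and `intercept` are required for a custom zone series")
  if (n_leaves < 2) stop("`n_leaves` must be at least 2")
  lengths <- seq(leaf_length_range[1], leaf_length_range[2],
                 length.out = n_leaves)
  if (is.null(noise_sd))
    noise_sd <- if (is.null(target_r2)) 0 else
      zone_noise_for_r2(slope, target_r2, lengths)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(preset = preset, slope = slope, intercept = intercept,
                 n_leaves = as.integer(n_leaves),
                 leaf_length_range = leaf_length_range,
                 lengths = lengths, noise_sd = noise_sd, seed = seed),
            class = "zone_series_spec")
}

#' Residual SD giving a target population R-squared
#'
#' For a straight-line relation observed at fixed predictor values,
#' `R^2 = slope^2 var(x) / (slope^2 var(x) + sigma^2)`; inverting gives
#' the residual SD that makes the fit scatter match a reported R^2.
#'
#' @param slope line slope.
#' @param r2 target R-squared in (0, 1).
#' @param lengths predictor values (leaf lengths, mm).
#' @return Residual standard deviation, mm.
#' @export
zone_noise_for_r2 <- function(slope, r2, lengths) {
  if (r2 <= 0 || r2 >= 1) stop("`r2` must be in (0, 1)")
  sqrt(slope^2 * var(lengths) * (1 - r2) / r2)
}

#' Generate proliferation-zone records
#'
#' @param spec a [zone_series_spec()].
#' @return A `zone_series` data frame with columns `leaf_length_mm`,
#'   `zone_length_mm`, and `clipped` (TRUE where the draw fell outside
#'   \[0, leaf length\] and was clipped).
#' @examples
#' zs <- gen_zone_series(zone_series_spec("col0", seed = 1))
#' zone_slope(zs)
#' @export
gen_zone_series <- function(spec) {
  stopifnot(inherits(spec, "zone_series_spec"))
  L <- spec$lengths
  z <- spec$intercept + spec$slope * L
  if (spec$noise_sd > 0)
    z <- z + with_seed(spec$seed, rnorm(length(L), 0, spec$noise_sd))
  clipped <- z < 0 | z > L
  z <- pmin(pmax(z, 0), L)
  out <- data.frame(leaf_length_mm = L, zone_length_mm = z, clipped = clipped)
  attr(out, "spec") <- spec
  class(out) <- c("zone_series", "data.frame")
  out
}
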