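#' Group-level shape summaries (mean +/- SEM per genotype)
#'
#' Summarises per-leaf shape metrics by genotype: mean, SEM
#' (`sd / sqrt(n)`), and sample size for length, width, perimeter,
#' area, the length:width ratio, and the curvature proxy. The proxy is
#' reported two ways: `proxy_mean`, the mean of per-leaf P/sqrt(A)
#' ratios, and `proxy_of_means`, the ratio of the mean perimeter to the
#' square root of the mean area -- the form comparable with published
#' group tables, where the group proxy equals mean P over sqrt(mean A).
#'
#' @param measurements data frame with columns `genotype`, `length_mm`,
#'   `width_mm`, `perimeter_mm`, `area_mm2` (e.g. rows of
#'   `as.data.frame(measure_outline(...))` plus a genotype column).
#' @return Data frame of class `group_summary`, one row per genotype.
#'   Groups of size one report `sem` 0 with `single_leaf = TRUE`; empty
#'   groups are dropped with a warning.
#' @export
summarize_groups <- function(measurements) {
  need <- c("genotype", "length_mm", "width_mm", "perimeter_mm", "area_mm2")
  if (!all(need %in% names(measurements)))
    stop("`measurements` needs columns ", paste(need, collapse = ", "))
  gl <- unique(as.character(measurements$genotype))
  rows <- list()
  for (g in gl) {
    d <- measurements[measurements$genotype == g, , drop = FALSE]
    d <- d[stats::complete.cases(d[, need[-1]]), , drop = FALSE]
    if (!nrow(d)) {
      warning("group '", g, "' has no complete measurements; skipped")
      next
    }
    n <- nrow(d)
    sem <- function(x) if (n > 1) sd(x) / sqrt(n) else 0
    ratio <- d$length_mm / d$width_mm
    proxy <- d$perimeter_mm / sqrt(d$area_mm2)
    rows[[g]] <- data.frame(
      genotype = g, n = n,
      length_mean = mean(d$length_mm), length_sem = sem(d$length_mm),
      width_mean = mean(d$width_mm), width_sem = sem(d$width_mm),
      perimeter_mean = mean(d$perimeter_mm), perimeter_sem = sem(d$perimeter_mm),
      area_mean = mean(d$area_mm2), area_sem = sem(d$area_mm2),
      ratio_mean = mean(ratio), ratio_sem = sem(ratio),
      proxy_mean = mean(proxy), proxy_sem = sem(proxy),
      proxy_of_means = mean(d$perimeter_mm) / sqrt(mean(d$area_mm2)),
      single_leaf = n == 1L)
  }
  if (!length(rows)) stop("no non-empty groups to summarise")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Shape and size parameters (mean +/- SEM)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s L %5.1f+/-%.1f  W %5.1f+/-%.1f  P %5.1f+/-%.1f  A %6.1f+/-%.1f  L:W %.1f  P/sqrt(A) %.1f  (n=%d)\n",
                x$genotype[i], x$length_mean[i], x$length_sem[i],
                x$width_mean[i], x$width_sem[i],
                x$perimeter_mean[i], x$perimeter_sem[i],
                x$area_mean[i], x$area_sem[i],
                x$ratio_mean[i], x$proxy_of_means[i], x$n[i]))
  }
  invisible(x)
}

#' Two-sample t test (pooled-variance or Welch)
#'
#' Thin wrapper over [stats::t.test()] exposing the pooled-variance
#' Student test as the default (matching the convention of the group
#' comparisons this reproduces) with Welch as the alternative. A star
#' code follows the usual thresholds (*** p <= 0.001, ** p <= 0.01,
#' * p <= 0.05).
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return An object of class `test_result`: list with `statistic`,
#'   `df`, `p_value`, `stars`, `variant`.
#' @export
students_t <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations")
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate: no variance anywhere; identical means give p = 1
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(structure(list(statistic = 0, df = length(x) + length(y) - 2,
                            p_value = 1, stars = "", variant = variant),
                       class = "test_result"))
    stop("zero variance in both samples with unequal means; t is undefined")
  }
  ht <- t.test(x, y, var.equal = (variant == "student"))
  p <- ht$p.value
  stars <- if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = p, stars = stars, variant = variant),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s t = %.3f, df = %.2f, p = %.4g %s\n",
              x$variant, x$statistic, x$df, x$p_value, x$stars))
  invisible(x)
}

#' Run the full synthetic pipeline
#'
#' Executes generate -> measure -> profile -> summarise for a set of
#' genotype presets and writes tab-separated outputs plus a JSON run
#' log. Every random draw descends from the single `seed` recorded in
#' the log, so a configuration reruns to identical files.
#'
#' @param config a nested list, or the path to a YAML file with the
#'   same structure. See [default_pipeline_config()] for the shape and
#'   defaults.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results bundle
#'   (`summary`, `profiles`, `classifications`, `zone_fits`,
#'   `growth_peaks`, `log`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = "laminametrics-out") {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  seeds <- sample.int(2^31 - 1, 6L)
  genos <- config$genotypes
  if (is.null(genos) || !length(genos)) stop("config lists no genotypes")

  measurements <- stage("measure", {
    rows <- list()
    for (g in names(genos)) {
      gc <- genos[[g]]
      n <- gc$n_leaves %||% 10L
      for (i in seq_len(n)) {
        sp <- outline_spec(gc$length_mm, gc$width_mm,
                           n_vertices = gc$n_vertices %||% 512L,
                           roughness = gc$roughness %||% 0.25,
                           seed = seeds[1] %% 100000L + 1000L * i +
                             match(g, names(genos)) * 97L)
        sm <- measure_outline(gen_outline(sp, genotype = g), axis = 0)
        rows[[length(rows) + 1L]] <-
          cbind(genotype = g, as.data.frame(sm))
      }
    }
    do.call(rbind, rows)
  })
  summary <- stage("summarize", summarize_groups(measurements))

  profiles <- list(); classifications <- list()
  stage("profile", {
    for (g in names(genos)) {
      gc <- genos[[g]]
      if (is.null(gc$front)) next
      fm <- front_model(gc$front)
      prof <- lapply(seq_len(gc$n_front_leaves %||% 5L), function(i) {
        cm <- gen_cell_map(gc$halfwidth_mm %||% 1, 0.1,
                           gc$cell_area_um2 %||% 150,
                           seed = seeds[2] %% 100000L + 131L * i +
                             match(g, names(genos)))
        cm <- assign_gus(cm, fm, seed = seeds[3] %% 100000L + 17L * i +
                           match(g, names(genos)))
        fraction_profile(bin_fields(cm))
      })
      profiles[[g]] <- average_profiles(prof)
      classifications[[g]] <- classify_front(profiles[[g]])
    }
  })

  zone_fits <- stage("zones", {
    fits <- list()
    for (g in names(genos)) {
      zp <- genos[[g]]$zone_preset
      if (is.null(zp)) next
      zs <- gen_zone_series(zone_series_spec(zp, seed = seeds[4] %% 100000L +
                                               match(g, names(genos))))
      fits[[g]] <- zone_slope(zs)
    }
    fits
  })

  growth_peaks <- stage("growth", {
    pk <- list()
    for (g in names(genos)) {
      gr <- genos[[g]]$growth
      if (is.null(gr)) next
      gs <- gen_growth_series(growth_spec(
        w_max = gr$w_max %||% 9, r_max = gr$r_max %||% 0.5,
        t_mid = gr$t_mid %||% 8, noise_sd = gr$noise_sd %||% 0,
        seed = seeds[5] %% 100000L + match(g, names(genos))))
      pk[[g]] <- growth_rates(gs)$peak_rate
    }
    pk
  })

  stage("write", {
    write.table(format_summary_table(summary),
                file.path(outdir, "shape_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(profiles)) {
      pdf_rows <- do.call(rbind, lapply(names(profiles), function(g)
        cbind(genotype = g, as.data.frame(profiles[[g]]))))
      write.table(pdf_rows, file.path(outdir, "front_profiles.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      cls <- data.frame(genotype = names(classifications),
                        label = vapply(classifications, `[[`, "", "label"))
      write.table(cls, file.path(outdir, "front_classifications.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(zone_fits)) {
      zf <- data.frame(genotype = names(zone_fits),
                       slope = vapply(zone_fits, `[[`, 1, "slope"),
                       r_squared = vapply(zone_fits, `[[`, 1, "r_squared"),
                       n = vapply(zone_fits, `[[`, 1L, "n"))
      write.table(zf, file.path(outdir, "zone_fits.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(growth_peaks)) {
      gp <- data.frame(genotype = names(growth_peaks),
                       peak_rate_mm_day = unlist(growth_peaks))
      write.table(gp, file.path(outdir, "growth_peaks.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    log <- list(seed = seed,
                package_version = as.character(utils::packageVersion("laminametrics")),
                genotypes = names(genos))
    jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(summary = summary, measurements = measurements,
                 profiles = profiles, classifications = classifications,
                 zone_fits = zone_fits, growth_peaks = growth_peaks))
}

#' Default pipeline configuration
#'
#' Two genotype presets shaped like the wild-type and round-leaf-mutant
#' study conditions: outline dimensions near the published group means
#' with boundary roughness 0.25 (calibrated so wild-type-like cohorts
#' reproduce the measured group proxy of ~3.8, above the smooth-ellipse
#' value of ~3.6 -- real laminae exceed the elliptical prediction), the
#' matching arrest-front presets, zone-dynamics presets, and logistic
#' growth with peak rates 0.5 and 1.0 mm/day.
#'
#' @param seed root seed recorded in the run log.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = seed,
    genotypes = list(
      col0 = list(length_mm = 12.8, width_mm = 9.0, n_leaves = 10L,
                  roughness = 0.25, front = "col0", n_front_leaves = 11L,
                  halfwidth_mm = 1.0, cell_area_um2 = 150,
                  zone_preset = "col0",
                  growth = list(w_max = 9, r_max = 0.5, t_mid = 8)),
      tni = list(length_mm = 14.2, width_mm = 16.2, n_leaves = 9L,
                 roughness = 0.25, front = "tni", n_front_leaves = 5L,
                 halfwidth_mm = 1.2, cell_area_um2 = 150,
                 zone_preset = "tni",
                 growth = list(w_max = 16, r_max = 1.0, t_mid = 8))))
}

# round a group summary for a published-table-shaped TSV
format_summary_table <- function(s) {
  data.frame(genotype = s$genotype,
             length = sprintf("%.1f+/-%.1f", s$length_mean, s$length_sem),
             width = sprintf("%.1f+/-%.1f", s$width_mean, s$width_sem),
             perimeter = sprintf("%.1f+/-%.1f", s$perimeter_mean, s$perimeter_sem),
             area = sprintf("%.1f+/-%.1f", s$area_mean, s$area_sem),
             length_width_ratio = sprintf("%.1f", s$ratio_mean),
             ratio_sem = sprintf("%.2f", s$ratio_sem),
             proxy = sprintf("%.1f", s$proxy_of_means),
             proxy_sem = sprintf("%.2f", s$proxy_sem),
             n = s$n)
}
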