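test_that("field binning tiles midrib to margin with the centroid rule", {
  cm <- assign_gus(gen_cell_map(1, 0.1, 150, seed = 1), front_model("col0"),
                   seed = 2)
  fields <- bin_fields(cm)
  expect_equal(nrow(fields), 5)          # 1000 um / 200 um
  expect_equal(fields$x_center_um, seq(100, 900, by = 200))
  expect_equal(sum(fields$n_total), nrow(cm$cells))  # each cell in one field
  # near-uniform lattice: similar totals per field
  expect_lt(diff(range(fields$n_total)), 0.2 * mean(fields$n_total))

  all_on <- assign_gus(gen_cell_map(1, 0.1, 150, seed = 1),
                       front_model("custom", p = function(x) rep(1, length(x))),
                       seed = 3)
  fr <- fraction_profile(bin_fields(all_on))
  expect_true(all(fr$fraction == 1))

  expect_error(bin_fields(cm, band = c(-50, 500)), "band")
})

test_that("trailing partial fields follow the half-width rule", {
  # width 1.12 mm: remainder 120 um >= 100 -> kept as its own field
  cm_keep <- gen_cell_map(1.12, 0.1, 150, seed = 4)
  expect_equal(nrow(bin_fields(cm_keep)), 6)
  # width 1.08 mm: remainder 80 um < 100 -> merged into field 5
  cm_merge <- gen_cell_map(1.08, 0.1, 150, seed = 4)
  f <- bin_fields(cm_merge)
  expect_equal(nrow(f), 5)
  expect_equal(sum(f$n_total), nrow(cm_merge$cells))
})

test_that("binned profiles recover the generating front within binomial error", {
  # aggregate 2-SE coverage across replicates x bins, and near-total
  # 3-SE coverage per replicate
  fm <- front_model("col0")
  truth <- oracle_field_means(fm, 1000)
  reps <- 60
  hits2 <- 0; bins2 <- 0; all_within3 <- 0
  for (s in seq_len(reps)) {
    cm <- assign_gus(gen_cell_map(1, 0.1, 150, seed = 1000 + s), fm,
                     seed = 2000 + s)
    pr <- fraction_profile(bin_fields(cm))
    se_t <- sqrt(truth * (1 - truth) / pr$n_total)
    dev <- abs(pr$fraction - truth)
    hits2 <- hits2 + sum(dev <= 2 * se_t)
    bins2 <- bins2 + length(truth)
    if (all(dev <= 3 * se_t)) all_within3 <- all_within3 + 1
  }
  expect_gt(hits2 / bins2, 0.93)
  expect_gt(all_within3 / reps, 0.95)
})

test_that("front classification reproduces the three preset shapes", {
  # noiseless profiles built from the exact field means at n = 150
  mk_prof <- function(preset, width) {
    mu <- oracle_field_means(front_model(preset), width)
    fraction_profile(data.frame(field = seq_along(mu),
                                x_center_um = seq(100, by = 200,
                                                  length.out = length(mu)),
                                n_total = 150,
                                n_gus = round(150 * mu)))
  }
  expect_identical(classify_front(mk_prof("col0", 1000))$label, "mild_convex")
  expect_identical(classify_front(mk_prof("tni", 1200))$label,
                   "strong_convex_with_midrib_dip")
  expect_identical(classify_front(mk_prof("jawD", 1100))$label, "concave")

  # flat profile classifies flat
  flat <- fraction_profile(data.frame(field = 1:5,
                                      x_center_um = seq(100, 900, 200),
                                      n_total = 150, n_gus = 30))
  expect_identical(classify_front(flat)$label, "flat")
})

test_that("pooled stochastic profiles classify consistently", {
  pooled <- function(preset, width, n_leaves, seed0) {
    profs <- lapply(seq_len(n_leaves), function(i) {
      cm <- assign_gus(gen_cell_map(width / 1000, 0.1, 150,
                                    seed = seed0 + i),
                       front_model(preset), seed = seed0 + 100 + i)
      fraction_profile(bin_fields(cm))
    })
    average_profiles(profs)
  }
  for (r in 1:8) {
    expect_identical(classify_front(pooled("col0", 1000, 5, 3000 + 10 * r))$label,
                     "mild_convex")
    expect_identical(classify_front(pooled("tni", 1200, 5, 4000 + 10 * r))$label,
                     "strong_convex_with_midrib_dip")
    expect_identical(classify_front(pooled("jawD", 1100, 5, 5000 + 10 * r))$label,
                     "concave")
  }
})

test_that("zone length reads the 10% threshold from the midrib column", {
  # step construction: fully proliferating for 0.6 mm of a 2 mm leaf
  cm <- gen_cell_map(0.4, 2, 150, seed = 6)
  cm$cells$gus <- cm$cells$y_um < 600
  expect_equal(zone_length(cm), 0.6, tolerance = 0.1)

  cm_all <- cm; cm_all$cells$gus <- TRUE
  expect_equal(zone_length(cm_all), 2.0)

  # threshold sweep on a monotone-declining profile: a laxer (higher)
  # threshold is reached closer to the base, so zone length cannot grow
  cm2 <- gen_cell_map(0.4, 2, 150, seed = 7)
  set.seed(8)
  cm2$cells$gus <- runif(nrow(cm2$cells)) < pmax(0, 1 - cm2$cells$y_um / 2000)
  zl <- vapply(seq(0.05, 0.20, by = 0.025), function(th)
    zone_length(cm2, threshold = th), numeric(1))
  expect_true(all(diff(zl) <= 0))

  expect_error(zone_length(gen_cell_map(0.4, 2, 150, seed = 6)), "assigned")
})

test_that("zone-slope fitting matches OLS and is scale-consistent", {
  zs <- gen_zone_series(zone_series_spec("col0", seed = 5))
  f <- zone_slope(zs)
  ref <- lm(zone_length_mm ~ leaf_length_mm, data = zs)
  expect_equal(f$slope, unname(coef(ref)[2]))
  expect_equal(f$r_squared, summary(ref)$r.squared)
  # scaling all lengths by c leaves the slope (mm/mm) unchanged
  sc <- zs; sc$leaf_length_mm <- sc$leaf_length_mm * 3
  sc$zone_length_mm <- sc$zone_length_mm * 3
  expect_equal(zone_slope(sc)$slope, f$slope, tolerance = 1e-12)
  expect_error(zone_slope(data.frame(leaf_length_mm = c(2, 2),
                                     zone_length_mm = c(1, 1.2))), "equal")
})
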