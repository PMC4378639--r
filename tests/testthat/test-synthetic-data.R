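test_that("outline generator reproduces ellipse geometry", {
  # degenerate ellipse: a circle of diameter 2
  circ <- gen_outline(outline_spec(2, 2, 512))
  r <- sqrt(rowSums(circ$vertices^2))
  expect_equal(max(abs(r - 1)), 0, tolerance = 1e-12)

  # closed-form area at >= 512 vertices within 0.5%
  ol <- gen_outline(outline_spec(12.8, 9.0, 512))
  expect_equal(polygon_area(ol$vertices), pi * 6.4 * 4.5, tolerance = 0.005)

  # extents are exact for roughness 0
  m <- measure_outline(ol)
  expect_equal(m$length, 12.8, tolerance = 1e-9)
  expect_equal(m$width, 9.0, tolerance = 1e-9)
})

test_that("outline generation is seed-deterministic and stays simple", {
  a <- gen_outline(outline_spec(14.2, 16.2, 256, roughness = 0.08, seed = 11))
  b <- gen_outline(outline_spec(14.2, 16.2, 256, roughness = 0.08, seed = 11))
  expect_identical(a$vertices, b$vertices)
  c <- gen_outline(outline_spec(14.2, 16.2, 256, roughness = 0.08, seed = 12))
  expect_false(identical(a$vertices, c$vertices))

  for (s in 1:20) {
    ol <- gen_outline(outline_spec(10, 8, 128, roughness = 0.3, seed = s))
    expect_true(polygon_is_simple(ol$vertices))
  }
})

test_that("planar outlines respect the isoperimetric floor", {
  # proxy >= 2*sqrt(pi) for every simple closed curve, circle minimal
  expect_equal(measure_outline(make_circle_outline(1, 2048))$curvature_proxy,
               2 * sqrt(pi), tolerance = 1e-4)
  for (s in 1:15) {
    ol <- gen_outline(outline_spec(runif(1, 5, 15), runif(1, 5, 15), 256,
                                   roughness = 0.2, seed = s))
    expect_gt(measure_outline(ol)$curvature_proxy, 2 * sqrt(pi))
  }
})

test_that("surface generator meets its contracts", {
  disc <- gen_surface(surface_spec("flat_disc", 1, mesh_resolution = 0.03))
  expect_true(all(disc$vertices[, 3] == 0))
  expect_equal(mesh_metrics(disc)$surface_area, pi, tolerance = 0.01)

  hemi <- gen_surface(surface_spec("spherical_cap", 1, pi / 2,
                                   mesh_resolution = 0.05))
  expect_equal(max(abs(sqrt(rowSums(hemi$vertices^2)) - 1)), 0, tolerance = 1e-9)

  sad <- gen_surface(surface_spec("saddle", 1, 1, mesh_resolution = 0.05))
  expect_gt(mesh_metrics(sad)$boundary_perimeter, 2 * pi)
})

test_that("cell maps hit the target count and mean area", {
  cm <- gen_cell_map(1, 1, 10000, seed = 1)
  expect_gt(nrow(cm$cells), 85)
  expect_lt(nrow(cm$cells), 115)
  expect_equal(mean(cm$cells$area_um2), 10000, tolerance = 0.1)

  cm6 <- gen_cell_map(1, 1, 6000, seed = 2)
  # recomputed from the polygon areas, not the target
  areas <- vapply(cm6$polygons, polygon_area, numeric(1))
  expect_equal(mean(areas), 6000, tolerance = 0.1)

  expect_identical(gen_cell_map(0.5, 0.5, 200, seed = 7)$cells,
                   gen_cell_map(0.5, 0.5, 200, seed = 7)$cells)
  expect_error(gen_cell_map(-1, 1, 100))
})

test_that("Bernoulli GUS assignment is calibrated", {
  cm <- gen_cell_map(2, 0.8, 150, seed = 5)   # ~10^4 cells
  n <- nrow(cm$cells)
  expect_gt(n, 8000)

  all_on <- assign_gus(cm, front_model("custom", p = function(x) rep(1, length(x))),
                       seed = 1)
  expect_true(all(all_on$cells$gus))

  flat25 <- assign_gus(cm, front_model("custom", p = function(x) rep(0.25, length(x))),
                       seed = 2)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(flat25$cells$gus) - 0.25), 3 * se)

  expect_error(assign_gus(cm, front_model("custom", p = function(x) x * 2)),
               "outside|\\[0, 1\\]")
})

test_that("front presets encode the reported end and peak values", {
  col0 <- front_model("col0")
  expect_equal(col0$p(0), 0.25)
  expect_equal(col0$p(1), 0.10)
  tni <- front_model("tni")
  expect_equal(tni$p(0), 0.27)
  expect_equal(tni$p(1), 0.15)
  expect_equal(max(tni$p(seq(0, 1, by = 0.001))), 0.40, tolerance = 1e-6)
  jaw <- front_model("jawD")
  expect_true(all(diff(jaw$p(seq(0, 1, 0.05))) > 0))
})

test_that("growth series follow the logistic parameterisation", {
  gs <- gen_growth_series(growth_spec(w_max = 9, r_max = 0.5, t_mid = 8))
  # asymptote
  expect_equal(logistic_width(1e6, 9, 0.5, 8), 9)
  # max two-day finite difference approximates the analytic peak rate
  pk <- growth_rates(gs)$peak_rate
  expect_equal(pk, 0.5, tolerance = 0.05)
  # doubling r_max doubles the peak
  gs2 <- gen_growth_series(growth_spec(w_max = 9, r_max = 1.0, t_mid = 8))
  expect_equal(growth_rates(gs2)$peak_rate / pk, 2, tolerance = 0.05)
  # seeded noise is reproducible
  n1 <- gen_growth_series(growth_spec(noise_sd = 0.2, seed = 3))
  n2 <- gen_growth_series(growth_spec(noise_sd = 0.2, seed = 3))
  expect_identical(n1$width_mm, n2$width_mm)
})

test_that("zone series regenerate their slope under OLS", {
  # noiseless: exact recovery
  zs0 <- gen_zone_series(zone_series_spec("col0", noise_sd = 0))
  f0 <- zone_slope(zs0)
  expect_equal(f0$slope, -0.37, tolerance = 1e-12)
  expect_equal(f0$r_squared, 1)

  # two points: exact interpolation
  z2 <- data.frame(leaf_length_mm = c(1, 2), zone_length_mm = c(0.9, 0.5))
  f2 <- zone_slope(z2)
  expect_equal(f2$slope, -0.4)
  expect_equal(f2$r_squared, 1)

  # calibrated-noise preset scatter lands near the intended R^2
  ft <- zone_slope(gen_zone_series(zone_series_spec("tni", seed = 1)))
  expect_gt(ft$r_squared, 0.5)
  expect_lt(ft$r_squared, 0.95)

  # clipping flags fire only outside [0, leaf_length]
  zz <- gen_zone_series(zone_series_spec("col0", seed = 1))
  expect_true(all(zz$zone_length_mm >= 0 &
                    zz$zone_length_mm <= zz$leaf_length_mm))
})

test_that("noise calibration inverts the R-squared relation", {
  L <- seq(1, 3, length.out = 20)
  sd0 <- zone_noise_for_r2(-0.37, 0.67, L)
  expect_equal((-0.37)^2 * var(L) / ((-0.37)^2 * var(L) + sd0^2), 0.67)
})
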