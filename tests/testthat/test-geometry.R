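test_that("ellipse null-model formulas evaluate correctly", {
  # circle: both perimeter forms coincide and area is pi r^2
  circ <- ellipse_model(1, 1)
  expect_equal(ellipse_predicted_perimeter(circ), 2 * pi)
  expect_equal(ellipse_area(circ), pi)

  # wild-type-like semi-axes
  m <- ellipse_model(6.4, 4.5)
  expect_equal(ellipse_predicted_perimeter(m), 2 * pi * sqrt((6.4^2 + 4.5^2) / 2))
  expect_equal(round(ellipse_predicted_perimeter(m), 2), 34.76)
  expect_equal(round(ellipse_area(m), 2), 90.48)
  expect_equal(round(ellipse_area(ellipse_model(7.1, 8.1)), 1), 180.7)

  # the quadratic-mean approximation overshoots the true perimeter by <1%
  exact <- oracle_ellipse_perimeter(6.4, 4.5)
  expect_equal(round(exact, 2), 34.5, tolerance = 0.01)
  rel_err <- (ellipse_predicted_perimeter(m) - exact) / exact
  expect_gt(rel_err, 0)
  expect_lt(rel_err, 0.01)
  expect_equal(ellipse_perimeter_ramanujan(m), exact)
})

test_that("curvature proxy is P/sqrt(A), unrounded, with rounding at report", {
  expect_equal(curvature_proxy(2 * pi, pi), 2 * sqrt(pi))
  expect_equal(curvature_proxy(36.3, 90.3), 36.3 / sqrt(90.3))
  expect_equal(round(curvature_proxy(36.3, 90.3), 1), 3.8)
  expect_equal(round(curvature_proxy(42.7, 179.5), 1), 3.2)
  expect_error(curvature_proxy(-1, 2))
  expect_error(curvature_proxy(3, 0))
})

test_that("predicted proxy depends only on the length:width ratio", {
  expect_equal(predicted_proxy_from_length_width(1, 1), 2 * sqrt(pi))
  # scale invariance
  p1 <- predicted_proxy_from_length_width(1.4, 1)
  expect_equal(predicted_proxy_from_length_width(14, 10), p1)
  expect_equal(predicted_proxy_from_length_width(0.0014, 0.001), p1)
  # the two genotype ratios agree at one decimal (~3.6)
  expect_equal(round(p1, 3), 3.645)
  expect_equal(round(predicted_proxy_from_length_width(0.9, 1), 3), 3.555)
  expect_equal(round(p1, 1), round(predicted_proxy_from_length_width(0.9, 1), 1))
})

test_that("mesh metrics recover closed forms for the three curvature signs", {
  disc <- gen_surface(surface_spec("flat_disc", radius = 1, mesh_resolution = 0.02))
  md <- mesh_metrics(disc)
  expect_equal(md$surface_area, pi, tolerance = 0.005)
  expect_equal(md$proxy, 2 * sqrt(pi), tolerance = 0.01)
  expect_identical(md$curvature_class, "flat")

  hemi <- gen_surface(surface_spec("spherical_cap", radius = 1,
                                   curvature_param = pi / 2,
                                   mesh_resolution = 0.02))
  mh <- mesh_metrics(hemi)
  expect_equal(mh$surface_area, oracle_cap_area(1, pi / 2), tolerance = 0.005)
  expect_equal(mh$boundary_perimeter, oracle_cap_rim(1, pi / 2), tolerance = 0.005)
  expect_equal(mh$proxy, sqrt(2 * pi), tolerance = 0.01)
  expect_identical(mh$curvature_class, "positive")

  sad <- gen_surface(surface_spec("saddle", radius = 1, curvature_param = 1,
                                  mesh_resolution = 0.02))
  ms <- mesh_metrics(sad)
  expect_equal(ms$surface_area, oracle_saddle_area(1), tolerance = 0.005)
  expect_equal(ms$boundary_perimeter, oracle_saddle_rim(1), tolerance = 0.005)
  expect_gt(ms$proxy, 2 * sqrt(pi))
  expect_identical(ms$curvature_class, "negative")
})

test_that("cap proxy falls and saddle proxy rises with curvature magnitude", {
  cap_proxy <- function(th) mesh_metrics(gen_surface(
    surface_spec("spherical_cap", 1, th, mesh_resolution = 0.03)))$proxy
  caps <- vapply(c(0.3, 0.8, 1.2, pi / 2), cap_proxy, numeric(1))
  expect_true(all(diff(caps) < 0))

  sad_proxy <- function(k) mesh_metrics(gen_surface(
    surface_spec("saddle", 1, k, mesh_resolution = 0.03)))$proxy
  sads <- vapply(c(0.3, 0.7, 1.2, 2), sad_proxy, numeric(1))
  expect_true(all(diff(sads) > 0))
})

test_that("mesh metrics converge to closed forms as resolution shrinks", {
  errs <- vapply(c(0.1, 0.05, 0.025), function(res) {
    m <- mesh_metrics(gen_surface(surface_spec("spherical_cap", 1, pi / 2,
                                               mesh_resolution = res)))
    abs(m$surface_area - oracle_cap_area(1, pi / 2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("meshes without exactly one rim are rejected", {
  disc <- gen_surface(surface_spec("flat_disc", 1, mesh_resolution = 0.2))
  # two disjoint copies -> two boundary loops
  v2 <- rbind(disc$vertices, disc$vertices + 5)
  f2 <- rbind(disc$faces, disc$faces + nrow(disc$vertices))
  expect_error(mesh_metrics(new_leaf_mesh(v2, f2)), "multiple boundary")
})
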