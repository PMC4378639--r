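test_that("measure_outline matches hand geometry", {
  sq <- measure_outline(make_square_outline(1))
  # the square's second moments are isotropic, so the principal angle
  # resolves to 0 and the axis-aligned extents are reported
  expect_equal(sq$length, 1)
  expect_equal(sq$width, 1)
  expect_equal(sq$perimeter, 4)
  expect_equal(sq$area, 1)

  ol <- gen_outline(outline_spec(12.8, 9.0, 2048))
  m <- measure_outline(ol)
  expect_equal(m$area, pi * 6.4 * 4.5, tolerance = 0.005)
  expect_equal(m$perimeter, oracle_ellipse_perimeter(6.4, 4.5), tolerance = 0.005)
  expect_equal(m$length_width_ratio, 12.8 / 9.0, tolerance = 1e-9)
})

test_that("shape metrics are rotation and translation invariant", {
  ol <- gen_outline(outline_spec(12.8, 9.0, 512, roughness = 0.1, seed = 2))
  m0 <- measure_outline(ol)
  th <- 37 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rot <- new_leaf_outline(t(R %*% t(ol$vertices)) +
                            matrix(c(3, -7), nrow(ol$vertices), 2, byrow = TRUE))
  m1 <- measure_outline(rot)
  for (f in c("length", "width", "perimeter", "area", "curvature_proxy"))
    expect_equal(m1[[f]], m0[[f]], tolerance = 1e-6)
})

test_that("cut-and-measure perimeter is conserved across partitions", {
  # circle split through the diameter: cut edges excluded, margin conserved
  circ <- make_circle_outline(1, 1024)
  p0 <- measure_outline(circ)$perimeter
  halves <- split_outline_by_line(circ, c(0, 0), c(1, 0))
  expect_length(halves, 2)
  expect_equal(piecewise_perimeter(halves), p0, tolerance = 1e-9)

  # single piece with no cuts equals the plain perimeter
  expect_equal(piecewise_perimeter(list(circ)), p0)

  # random chords through rough outlines, recursively to 3-4 pieces
  for (s in 1:12) {
    ol <- gen_outline(outline_spec(10, 7, 256, roughness = 0.25, seed = s))
    p_int <- measure_outline(ol)$perimeter
    set.seed(100 + s)
    ang1 <- runif(1, 0, pi); off1 <- runif(2, -0.5, 0.5)
    pieces <- split_outline_by_line(ol, off1, c(cos(ang1), sin(ang1)))
    ang2 <- runif(1, 0, pi); off2 <- runif(2, -0.5, 0.5)
    pieces <- unlist(lapply(pieces, split_outline_by_line,
                            point = off2, dir = c(cos(ang2), sin(ang2))),
                     recursive = FALSE)
    expect_equal(piecewise_perimeter(pieces), p_int, tolerance = 1e-6)
  }
})

test_that("a piece whose edges are all cuts contributes zero, with warning", {
  tri <- new_leaf_outline(rbind(c(0, 0), c(1, 0), c(0, 1)),
                          is_cut = c(TRUE, TRUE, TRUE))
  expect_warning(p <- piecewise_perimeter(list(tri)), "all edges")
  expect_equal(p, 0)
})

test_that("growth rates use centred differences with one-sided ends", {
  lin <- data.frame(day = c(0, 2, 4, 6), width_mm = c(0, 1, 2, 3))
  gr <- growth_rates(lin)
  expect_true(all(abs(gr$rates$rate_mm_per_day - 0.5) < 1e-12))
  expect_equal(gr$peak_rate, 0.5)

  const <- data.frame(day = seq(0, 10, 2), width_mm = rep(4, 6))
  expect_equal(growth_rates(const)$peak_rate, 0)

  gs <- gen_growth_series(growth_spec(w_max = 9, r_max = 0.5, t_mid = 8))
  expect_equal(growth_rates(gs)$peak_rate, 0.5, tolerance = 0.05)

  bad <- data.frame(day = c(0, 4, 2), width_mm = c(0, 1, 2))
  expect_error(growth_rates(bad), "increasing")
  expect_error(growth_rates(lin[1:2, ]), "3 time points")
})

test_that("mean cell size averages field_area / n_cells with SEM", {
  f8 <- data.frame(field_area_um2 = rep(20000, 8), n_cells = rep(10, 8))
  cs <- mean_cell_size(f8)
  expect_equal(cs$mean_um2, 2000)
  expect_equal(cs$sem_um2, 0)
  expect_warning(mean_cell_size(f8[1:7, ]), "7 counting fields")
  expect_error(mean_cell_size(data.frame()))

  # synthetic mature lattice measured back through counting fields
  cm <- gen_cell_map(1.2, 1.2, 6000, seed = 9)
  set.seed(1)
  fields <- do.call(rbind, lapply(1:8, function(i) {
    x0 <- runif(1, 0, 900); y0 <- runif(1, 0, 900)
    inf <- cm$cells$x_um >= x0 & cm$cells$x_um < x0 + 300 &
      cm$cells$y_um >= y0 & cm$cells$y_um < y0 + 300
    data.frame(field_area_um2 = 300^2, n_cells = sum(inf))
  }))
  expect_equal(mean_cell_size(fields)$mean_um2, 6000, tolerance = 0.10)
})

test_that("cell-count estimation is exact arithmetic and inverse-linear", {
  expect_equal(estimate_cell_count(90.3, 6000), 90.3 * 1e6 / 6000)
  expect_equal(round(estimate_cell_count(90.3, 6000), -3), 15000)
  expect_equal(estimate_cell_count(1, 1e6), 1)
  # the mutant-to-wild-type count ratio lands near fourfold
  ratio <- estimate_cell_count(179.5, 3000) / estimate_cell_count(90.3, 6000)
  expect_equal(ratio, 3.97, tolerance = 0.01)
  # inverse linearity
  expect_equal(estimate_cell_count(50, 1000), 2 * estimate_cell_count(50, 2000))
})

test_that("trichome frequencies normalise to 100%", {
  tf <- trichome_frequencies(data.frame(branches = c(3, 4), count = c(50, 50)))
  expect_equal(tf$percent, c(50, 50))
  one <- trichome_frequencies(c("2" = 297))
  expect_equal(one$percent, 100)
  set.seed(4)
  rnd <- trichome_frequencies(data.frame(branches = 2:6,
                                         count = rpois(5, 80) + 1))
  expect_equal(sum(rnd$percent), 100, tolerance = 0.01)
  expect_error(trichome_frequencies(data.frame(branches = 2, count = 0)))
})

test_that("cell-size histograms conserve mass and keep surfaces apart", {
  h1 <- cell_size_histogram(rep(500, 10), bin_edges = c(0, 1000, 2000))
  expect_equal(h1$count, c(10, 0))
  set.seed(2)
  x <- exp(rnorm(500, log(3000), 0.4))
  h2 <- cell_size_histogram(x, bin_edges = seq(0, 20000, 1000))
  expect_equal(sum(h2$count), 500)
  g <- rep(c("adaxial", "abaxial"), each = 250)
  h3 <- cell_size_histogram(x, seq(0, 20000, 1000), group = g)
  expect_equal(sum(h3$adaxial) + sum(h3$abaxial), 500)
  expect_error(cell_size_histogram(numeric(0), c(0, 1)))
})
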