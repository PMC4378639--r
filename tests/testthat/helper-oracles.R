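# Independent oracles and small fixture builders used across the suite.

# Ramanujan's second approximation to the ellipse perimeter: the
# high-accuracy reference the quadratic-mean approximation is compared
# against (written out here so the test does not lean on the package's
# own helper).
oracle_ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# closed forms for a spherical cap of radius R and half-angle theta
oracle_cap_area <- function(R, theta) 2 * pi * R^2 * (1 - cos(theta))
oracle_cap_rim <- function(R, theta) 2 * pi * R * sin(theta)

# saddle z = k*x*y over the unit-radius disc: surface area has a closed
# form; the rim length is computed by adaptive quadrature of the space
# curve (cos t, sin t, k cos t sin t)
oracle_saddle_area <- function(k, R = 1) 2 * pi * ((1 + k^2 * R^2)^1.5 - 1) / (3 * k^2)
oracle_saddle_rim <- function(k, R = 1) {
  integrand <- function(t) sqrt(R^2 + (k * R^2 * cos(2 * t))^2)
  integrate(integrand, 0, 2 * pi, rel.tol = 1e-10)$value
}

# mean of the front-model probability over each counting field, i.e.
# the estimand of the binned profile (numeric quadrature, independent
# of the binning code)
oracle_field_means <- function(model, width_um, field_w_um = 200) {
  edges <- seq(0, width_um, by = field_w_um)
  if (edges[length(edges)] < width_um) edges <- c(edges, width_um)
  vapply(seq_len(length(edges) - 1L), function(i) {
    integrate(function(u) model$p(u / width_um), edges[i], edges[i + 1L],
              rel.tol = 1e-9)$value / (edges[i + 1L] - edges[i])
  }, numeric(1))
}

# regular polygon fixtures
make_circle_outline <- function(r = 1, n = 256) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  new_leaf_outline(cbind(r * cos(th), r * sin(th)))
}
make_square_outline <- function(side = 1) {
  new_leaf_outline(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
}

# a small assigned band map shared by segmentation tests
make_band_map <- function(width_mm = 1, seed_map = 3, seed_gus = 4,
                          preset = "col0", cell_area = 150) {
  m <- gen_cell_map(width_mm, 0.1, cell_area, seed = seed_map)
  assign_gus(m, front_model(preset), seed = seed_gus)
}
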