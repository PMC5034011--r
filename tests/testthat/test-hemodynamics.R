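# Flow scaling law, elliptical-duct WSS, binning and normalisation.

straight_geom <- function(a = 1.5, b = a, L = 10, branches = NULL) {
  vessel_geometry(data.frame(
    s_mm = seq(0, L, by = 0.1), x_mm = 0, y_mm = 0,
    z_mm = seq(0, L, by = 0.1), a_mm = a, b_mm = b, psi_deg = 0,
    extension = FALSE), branches = branches)
}

manual_flows <- function(Q, L = 10) {
  structure(list(inlet_q_m3s = Q,
                 segments = data.frame(s_from = 0, s_to = L, q_m3s = Q),
                 branches = data.frame()),
            class = "flow_assignment")
}

test_that("flow is conserved and constant without branches", {
  fl <- assign_flows(straight_geom())
  expect_equal(length(unique(fl$segments$q_m3s)), 1)
  expect_equal(fl$inlet_q_m3s, fl$segments$q_m3s[1])
})

test_that("bifurcation splits follow D^e and conserve flow exactly", {
  # two daughters 2.5 mm and 2.0 mm at e = 2.27: split 0.624 / 0.376.
  # Model the distal main vessel as the 2.0 mm daughter.
  g <- straight_geom(a = 1.0, b = 1.0,
                     branches = data.frame(s_mm = 5, angle_deg = 90,
                                           diameter_mm = 2.5))
  fl <- assign_flows(g)
  expect_equal(fl$branches$fraction,
               2.5^2.27 / (2.5^2.27 + 2.0^2.27), tolerance = 1e-12)
  expect_equal(fl$branches$fraction, 0.624, tolerance = 1e-3)
  expect_equal(fl$inlet_q_m3s,
               sum(fl$branches$q_out_m3s) + fl$segments$q_m3s[2],
               tolerance = 0)
  # identical diameters: 50/50
  g2 <- straight_geom(a = 1.0, b = 1.0,
                      branches = data.frame(s_mm = 5, angle_deg = 90,
                                            diameter_mm = 2.0))
  expect_equal(assign_flows(g2)$branches$fraction, 0.5, tolerance = 1e-12)
})

test_that("circular-section WSS equals the Hagen-Poiseuille closed form", {
  mu <- 3.5e-3
  Q <- 1e-6
  w <- surrogate_wss(straight_geom(a = 1.5), manual_flows(Q),
                     hemo_config(viscosity_pa_s = mu))
  tau_ref <- 4 * mu * Q / (pi * (1.5e-3)^3)
  expect_equal(tau_ref, 1.3204, tolerance = 1e-4)
  expect_lt(max(abs(w$wss_pa - tau_ref)) / tau_ref, 1e-9)
})

test_that("elliptical WSS peaks at the minor axis and scales as r^-3", {
  w <- surrogate_wss(straight_geom(a = 2e-3 * 1000 / 2, b = 0.5),
                     manual_flows(1e-6))
  s0 <- w[w$s_mm == 0, ]
  i_max <- which.max(s0$wss_pa)
  i_min <- which.min(s0$wss_pa)
  # minor axis at 90/270 deg, major at 0/180
  expect_lt(min(abs(s0$theta_deg[i_max] - c(90, 270))), 10)
  expect_lt(min(abs(s0$theta_deg[i_min] - c(0, 180, 360))), 10)
  # halving the radius of a circular duct at fixed Q multiplies WSS by 8
  w1 <- surrogate_wss(straight_geom(a = 1), manual_flows(1e-6))
  w2 <- surrogate_wss(straight_geom(a = 0.5), manual_flows(1e-6))
  expect_equal(w2$wss_pa / w1$wss_pa, rep(8, nrow(w1)), tolerance = 1e-12)
})

test_that("surrogate boundary shear matches the finite-difference oracle", {
  skip_if_not_installed("Matrix")
  mu <- 3.5e-3
  Q <- 1e-6
  a <- 2e-3
  b <- 1e-3
  w <- surrogate_wss(straight_geom(a = 2, b = 1, L = 1), manual_flows(Q, 1),
                     hemo_config(viscosity_pa_s = mu), n_boundary = 24)
  s0 <- w[w$s_mm == 0, ]
  phi <- (seq_len(24) - 0.5) * 2 * pi / 24   # boundary parameter angles
  tau_fd <- poisson_duct_wss(a, b, mu, Q, phi, n = 200)
  expect_lt(max(abs(s0$wss_pa - tau_fd) / s0$wss_pa), 0.01)
})

test_that("external WSS import round-trips, ignores order, rejects bad rows", {
  w <- surrogate_wss(straight_geom(), manual_flows(1e-6))
  f <- tempfile(fileext = ".csv")
  write.csv(w, f, row.names = FALSE)
  w2 <- import_external_wss(f)
  expect_equal(bin_wss(w2, length_mm = 10)$values,
               bin_wss(w, length_mm = 10)$values)
  # shuffled rows give the identical map
  shuf <- w[sample(nrow(w)), ]
  write.csv(shuf, f, row.names = FALSE)
  expect_equal(bin_wss(import_external_wss(f), length_mm = 10)$values,
               bin_wss(w, length_mm = 10)$values)
  # one negative value is rejected with its row number
  bad <- w
  bad$wss_pa[5] <- -1
  bad <- bad[order(bad$s_mm, bad$theta_deg), ]
  write.csv(bad, f, row.names = FALSE)
  expect_error(import_external_wss(f), "row")
  # missing column
  write.csv(w[, 1:2], f, row.names = FALSE)
  expect_error(import_external_wss(f), "missing column")
})

test_that("binning averages per bin with half-open edges", {
  d <- data.frame(s_mm = c(0.05, 0.1, 3), theta_deg = c(2, 7, 100),
                  wss_pa = c(1, 3, 2))
  m <- bin_wss(d, bin_grid(), length_mm = 7.2)
  expect_equal(dim(m$values), c(36L, 36L))   # 7.2 mm / 0.2 and 360/10
  expect_equal(m$values[1, 1], 2)            # mean of 1 and 3
  expect_equal(m$counts[1, 1], 2)
  expect_equal(sum(m$counts), 3)
  # a uniform field fills every counted bin with the same value
  g <- expand.grid(s_mm = seq(0.1, 7.1, by = 0.2),
                   theta_deg = seq(5, 355, by = 10))
  g$wss_pa <- 2
  mu <- bin_wss(g, length_mm = 7.2)
  expect_true(all(mu$values[mu$counts > 0] == 2))
})

test_that("normalisation fixes the median at one and is scale-invariant", {
  set.seed(11)
  d <- expand.grid(s_mm = seq(0.1, 5.9, by = 0.2),
                   theta_deg = seq(5, 355, by = 10))
  d$wss_pa <- rexp(nrow(d)) + 0.1
  m <- bin_wss(d, length_mm = 6)
  nm <- normalize_map(m)
  expect_identical(nm$normalized, TRUE)
  expect_equal(stats::median(nm$values[nm$counts > 0]), 1)
  # scaling the input by any c > 0 leaves the normalised map unchanged
  for (c_ in c(0.1, 10)) {
    ds <- d
    ds$wss_pa <- ds$wss_pa * c_
    expect_equal(normalize_map(bin_wss(ds, length_mm = 6))$values,
                 nm$values, tolerance = 1e-12)
  }
  # idempotent after the first application
  expect_equal(normalize_map(nm)$values, nm$values, tolerance = 1e-15)
  # degenerate maps raise normalisation errors
  z <- d
  z$wss_pa <- 0
  expect_error(normalize_map(bin_wss(z, length_mm = 6)), "not positive")
})
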