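# Cost image, dynamic-programming contour extraction, cap thickness.

test_that("cost image localises step edges by polarity", {
  img <- matrix(0, 1, 30)
  img[1, 15:30] <- 1
  cost <- polar_cost_image(img, "dark_to_bright")
  expect_true(all(cost >= 0 & cost <= 1))
  expect_equal(which.min(cost[1, ]), 15)
  expect_equal(sum(cost[1, ] < 1 - 1e-9), 1)   # unique minimum
  # same column, falling polarity: only the falling edge is cheap
  img2 <- matrix(1, 1, 30)
  img2[1, 20:30] <- 0
  cost2 <- polar_cost_image(img2, "bright_to_dark")
  expect_equal(which.min(cost2[1, ]), 20)
  rising <- polar_cost_image(img2, "dark_to_bright")
  expect_true(all(rising == 1))   # no rising edge anywhere
})

test_that("a constant frame yields uniform cost one", {
  expect_true(all(polar_cost_image(matrix(3.7, 5, 9)) == 1))
})

test_that("extract_contour reduces to per-column argmin when lambda = 0", {
  set.seed(41)
  cost <- matrix(runif(20 * 15), 20, 15)
  path <- extract_contour(cost, lambda = 0, max_step = 15)
  expect_equal(as.integer(path), apply(cost, 1, which.min))
})

test_that("a large lambda forces the best constant-radius contour", {
  set.seed(42)
  cost <- matrix(runif(12 * 10), 12, 10)
  path <- extract_contour(cost, lambda = 1e6, max_step = 9)
  expect_equal(length(unique(as.integer(path))), 1)
  expect_equal(unique(as.integer(path)), which.min(colSums(cost)))
})

test_that("the DP path matches exhaustive search on random small grids", {
  set.seed(7)
  for (k in 1:12) {
    cost <- matrix(runif(8 * 12), 8, 12)
    lam <- sample(c(0, 0.3, 0.5, 1), 1)
    ms <- sample(2:3, 1)
    for (closed in c(FALSE, TRUE)) {
      path <- extract_contour(cost, lambda = lam, max_step = ms,
                              closed = closed)
      expect_equal(attr(path, "cost"),
                   brute_force_path_cost(cost, lam, ms, closed),
                   tolerance = 1e-12)
      expect_equal(path_objective(cost, as.integer(path), lam),
                   attr(path, "cost"), tolerance = 1e-12)
      expect_true(all(abs(diff(as.integer(path))) <= ms))
      if (closed)
        expect_lte(abs(path[length(path)] - path[1]), ms)
    }
  }
})

test_that("an infeasible search window raises a segmentation error", {
  cost <- matrix(Inf, 6, 8)
  expect_error(extract_contour(cost), "no admissible path")
})

test_that("lumen segmentation recovers the truth contour", {
  cfg <- small_phantom(noise_amplitude = 0)
  tr <- make_phantom_vessel(cfg)
  pb <- render_oct_pullback(tr, frames = 40)
  lum <- segment_lumen(pb, 40)
  truth_px <- tr$lumen_um[40, ] / pb$radial_pixel_um + 1
  expect_lt(max(abs(lum$radius_px - truth_px)), 1)
  # speckle: mean error within 3 radial pixels
  cfg2 <- small_phantom(noise_amplitude = 0.2)
  tr2 <- make_phantom_vessel(cfg2)
  pb2 <- render_oct_pullback(tr2, frames = 40)
  lum2 <- segment_lumen(pb2, 40)
  expect_lt(mean(abs(lum2$radius_px - truth_px)), 3)
})

test_that("segmentation is equivariant to circular shifts of the frame", {
  cfg <- small_phantom(noise_amplitude = 0.15)
  tr <- make_phantom_vessel(cfg)
  pb <- render_oct_pullback(tr, frames = 35)
  lum <- segment_lumen(pb, 35)
  k <- 17
  pb_shift <- pb
  img <- pb$frames[[1]]
  pb_shift$frames[[1]] <- img[c((k + 1):nrow(img), 1:k), ]
  lum_shift <- segment_lumen(pb_shift, 35)
  expect_equal(lum_shift$radius_px,
               lum$radius_px[c((k + 1):nrow(img), 1:k)],
               tolerance = 1e-9)
})

test_that("abluminal segmentation recovers a constant cap and stays below the lumen", {
  cfg <- small_phantom(noise_amplitude = 0,
                       cap_thickness = list(type = "constant",
                                            thickness_um = 200))
  tr <- make_phantom_vessel(cfg)
  ann <- phantom_annotations(tr)
  f <- 53   # z = 10.4 mm, mid-cap
  pb <- render_oct_pullback(tr, frames = f)
  lum <- segment_lumen(pb, f)
  abl <- segment_cap_abluminal(pb, f, ann$roi, lum)
  # hard ordering constraint
  expect_true(all(abl$radius_um >= lum$radius_um[abl$alines] + 40 - 1e-9))
  # where the cap truly exists (away from its angular boundary, which the
  # 5-A-line pre-smoothing blurs), the offset is 200 +/- 20 um
  truth_cap <- !is.na(tr$abluminal_um[f, abl$alines])
  shift_mask <- function(m, k) {
    n <- length(m)
    if (k >= 0) c(rep(FALSE, k), m)[seq_len(n)]
    else c(m[(-k + 1):n], rep(FALSE, -k))
  }
  interior <- Reduce(`&`, lapply(-3:3, function(k) shift_mask(truth_cap, k)))
  d <- abl$radius_um[interior] - lum$radius_um[abl$alines][interior]
  expect_gt(length(d), 30)
  expect_true(all(abs(d - 200) < 20))
})

test_that("a single-A-line ROI degenerates to the per-column optimum", {
  cfg <- small_phantom(noise_amplitude = 0)
  tr <- make_phantom_vessel(cfg)
  f <- 53
  pb <- render_oct_pullback(tr, frames = f)
  lum <- segment_lumen(pb, f)
  roi1 <- list(alines = c(20, 20))
  abl <- segment_cap_abluminal(pb, f, roi1, lum)
  expect_equal(length(abl$alines), 1)
  expect_false(abl$closed)
})

test_that("thickness of concentric circles equals the radius difference", {
  n <- 968
  mk <- function(r_mm, alines = seq_len(n), closed = TRUE) {
    px <- 10
    structure(list(alines = as.integer(alines),
                   radius_px = rep(r_mm * 1000 / px + 1, length(alines)),
                   radius_um = rep(r_mm * 1000, length(alines)),
                   radial_pixel_um = px, n_alines = n, closed = closed,
                   frame_index = 1L, z_mm = 0),
              class = "oct_contour")
  }
  lum <- mk(1.0)
  abl <- mk(1.2, alines = 100:400, closed = FALSE)
  tp <- thickness_profile(lum, abl)
  ok <- !tp$samples$missing
  expect_true(all(abs(tp$samples$thickness_um[ok] - 200) < 1e-3))
  expect_false(tp$degenerate)
  # identical contours: zero thickness, flagged degenerate
  tp0 <- thickness_profile(lum, mk(1.0, alines = 100:400, closed = FALSE))
  expect_true(all(abs(tp0$samples$thickness_um[!tp0$samples$missing]) < 1e-6))
  expect_true(tp0$degenerate)
})

test_that("the minimum of a Gaussian-dip cap is recovered from the rendering", {
  cfg <- small_phantom(noise_amplitude = 0, n_radial = 160,
                       cap_thickness = list(type = "gaussian_dip",
                                            base_um = 300, min_um = 100,
                                            sigma_s_mm = 1.5,
                                            sigma_theta_deg = 45))
  tr <- make_phantom_vessel(cfg)
  ann <- phantom_annotations(tr)
  frames <- seq(ann$roi$frames[1], ann$roi$frames[2], by = 2)
  pb <- render_oct_pullback(tr, frames = frames)
  mins <- vapply(frames, function(f) {
    lum <- segment_lumen(pb, f)
    abl <- segment_cap_abluminal(pb, f, ann$roi, lum)
    thickness_profile(lum, abl)$min_um
  }, numeric(1))
  truth_min <- min(tr$abluminal_um - tr$lumen_um, na.rm = TRUE)
  expect_lt(abs(min(mins) - truth_min), 20)
  expect_lt(abs(truth_min - 100), 2)   # sampled truth close to nominal
})

test_that("representative thickness behaves on constant and ramp fields", {
  # constant field: exactly 200 um for any seed
  profs <- lapply(1:21, function(k)
    fake_profile(k, (k - 1) * 0.2, rep(200, 60)))
  for (seed in c(1, 99))
    expect_equal(representative_thickness(profs, seed = seed), 200)
  # spacing larger than the plaque: single frame contributes
  expect_equal(representative_thickness(profs[1:3], spacing_mm = 10,
                                        seed = 1), 200)
  # ROI narrower than the requested sites: warn and use all
  narrow <- list(fake_profile(1, 0, rep(150, 3)))
  expect_warning(v <- representative_thickness(narrow, sites = 5, seed = 1),
                 "narrower")
  expect_equal(v, 150)
})

test_that("lumen_area matches closed-form areas and scales quadratically", {
  n <- 968
  phi <- (seq_len(n) - 1) * 2 * pi / n
  mk <- function(r_um) {
    structure(list(alines = seq_len(n), radius_px = r_um / 10 + 1,
                   radius_um = r_um, radial_pixel_um = 10, n_alines = n,
                   closed = TRUE, frame_index = 1L, z_mm = 0),
              class = "oct_contour")
  }
  circ <- mk(rep(1500, n))
  expect_equal(lumen_area(circ), pi * 1.5^2, tolerance = 1e-3)
  ell_r <- 2000 * 1000 / sqrt((1000 * cos(phi))^2 + (2000 * sin(phi))^2)
  ell <- mk(ell_r)
  expect_equal(lumen_area(ell), pi * 2 * 1, tolerance = 1e-3)
  expect_equal(lumen_area(mk(rep(3000, n))) / lumen_area(circ), 4,
               tolerance = 1e-9)
  open_c <- circ; open_c$closed <- FALSE
  expect_error(lumen_area(open_c), "closed")
})
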