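# Axial and rotational registration, cap resampling, agreement statistics.

test_that("axial registration interpolates anchors linearly", {
  ax <- axial_map(data.frame(frame = c(10, 110), s_mm = c(2, 21)))
  expect_equal(axial_s(ax, 60), 11.5)
  expect_equal(axial_s(ax, c(10, 110)), c(2, 21))
  # linear extrapolation beyond the anchors
  expect_equal(axial_s(ax, 120), 21 + 19 / 100 * 10)
  # identity scaling when OCT and angio lengths agree
  id <- axial_map(data.frame(frame = c(1, 101), s_mm = c(0, 20)))
  expect_equal(axial_s(id, 51), 10)
  # a third collinear anchor changes nothing
  ax3 <- axial_map(data.frame(frame = c(10, 60, 110), s_mm = c(2, 11.5, 21)))
  f <- seq(0, 120, by = 7)
  expect_equal(axial_s(ax3, f), axial_s(ax, f))
})

test_that("non-monotone or insufficient anchors raise registration errors", {
  expect_error(axial_map(data.frame(frame = 5, s_mm = 1)), "at least two")
  expect_error(axial_map(data.frame(frame = c(1, 50), s_mm = c(5, 2))),
               "monotone")
  expect_error(axial_map(data.frame(frame = c(5, 5), s_mm = c(1, 2))),
               "monotone|conflicting")
})

test_that("rotational registration interpolates offsets and holds outside", {
  A <- landmark("A", 20, 4, oct_angle_deg = 20, map_angle_deg = 30)
  B <- landmark("B", 80, 16, oct_angle_deg = 90, map_angle_deg = 120)
  rot <- rotational_map(A, B)
  expect_equal(rotation_offset(rot, c(20, 80)), c(10, 30))
  expect_equal(rotation_offset(rot, 50), 20)   # midpoint
  # constant beyond the anchors
  expect_equal(rotation_offset(rot, c(1, 120)), c(10, 30))
  # equal offsets: constant rotation
  B2 <- landmark("B", 80, 16, oct_angle_deg = 110, map_angle_deg = 120)
  expect_equal(rotation_offset(rotational_map(A, B2), c(5, 33, 71)),
               rep(10, 3))
})

test_that("offset interpolation crosses the +/-180 seam by the shortest arc", {
  A <- landmark("A", 10, 0, oct_angle_deg = 0, map_angle_deg = 170)
  B <- landmark("B", 30, 5, oct_angle_deg = 0, map_angle_deg = -170 + 360)
  rot <- rotational_map(A, B)
  expect_equal(rotation_offset(rot, c(10, 30)), c(170, -170))
  expect_equal(rotation_offset(rot, 20), 180)   # through 180, not 0
})

test_that("a linear probe drift is recovered between the branch anchors", {
  cfg <- small_phantom(rotation_drift_deg_per_frame = 0.5)
  tr <- make_phantom_vessel(cfg)
  ann <- phantom_annotations(tr)
  brs <- ann$landmarks[ann$landmarks$type == "side_branch", ]
  rot <- rotational_map(brs[1, ], brs[2, ])
  f_in <- seq(min(brs$frame), max(brs$frame))
  rec <- rotation_offset(rot, f_in)
  truth <- wrap_180(tr$rotation_offset_deg[f_in])
  expect_lt(max(abs(wrap_180(rec - truth))), 1)
  anchor_err <- wrap_180(rotation_offset(rot, brs$frame) -
                           tr$rotation_offset_deg[brs$frame])
  expect_equal(anchor_err, c(0, 0), tolerance = 1e-9)
})

test_that("cap resampling fills bins, conserves counts, and shifts with rotation", {
  n_fr <- 21
  profs <- lapply(seq_len(n_fr), function(k)
    fake_profile(k, (k - 1) * 0.2, rep(200, 60), alines = 1:60,
                 n_alines = 120))
  reg <- identity_registration(n_fr)
  cm <- resample_cap_to_grid(profs, reg, bin_grid(), length_mm = 4.2)
  expect_s3_class(cm, "cap_map")
  expect_true(all(abs(cm$values[cm$counts > 0] - 200) < 1e-9))
  # conservation: every thickness sample lands in exactly one bin
  expect_equal(sum(cm$counts), n_fr * 60)
  # rotating the registration by +90 degrees shifts the map by 9 bins
  reg90 <- identity_registration(n_fr, offset_deg = 90)
  cm90 <- resample_cap_to_grid(profs, reg90, bin_grid(), length_mm = 4.2)
  shift <- 9
  expect_equal(cm90$counts,
               cm$counts[, ((seq_len(36) - 1 - shift) %% 36) + 1])
})

test_that("end-to-end cap map agrees with the phantom truth field", {
  cfg <- small_phantom(noise_amplitude = 0, n_radial = 160)
  tr <- make_phantom_vessel(cfg)
  ann <- phantom_annotations(tr)
  frames <- seq(ann$roi$frames[1], ann$roi$frames[2])
  pb <- render_oct_pullback(tr, frames = frames)
  profs <- lapply(frames, function(f) {
    lum <- segment_lumen(pb, f)
    abl <- segment_cap_abluminal(pb, f, ann$roi, lum)
    thickness_profile(lum, abl)
  })
  lm <- ann$landmarks
  reg <- registration(
    axial_map(lm[, c("frame", "s_mm")]),
    rotational_map(lm[1, ], lm[2, ]))
  cm <- resample_cap_to_grid(profs, reg, bin_grid(),
                             length_mm = cfg$tube_length_mm)
  truth <- tr$thickness_truth
  both <- cm$counts > 0 & truth$counts > 0
  expect_gt(sum(both), 50)
  expect_lt(mean(abs(cm$values[both] - truth$values[both])), 25)
})

test_that("length agreement reproduces Bland-Altman quantities", {
  a <- c(10, 20)
  st <- length_agreement(a, c(9, 21))
  expect_equal(st$mean_abs_diff_mm, 1)
  expect_equal(st$bias_mm, 0)
  # identical lists: zero bias, degenerate limits, perfect correlation
  st2 <- length_agreement(c(5, 9, 14), c(5, 9, 14))
  expect_equal(st2$bias_mm, 0)
  expect_equal(unname(st2$loa_mm), c(0, 0))
  expect_equal(st2$pearson_r, 1)
  # adding a constant shifts the bias by that constant
  st3 <- length_agreement(c(5, 9, 14) + 2, c(5, 9, 14))
  expect_equal(st3$bias_mm, 2)
  expect_equal(unname(st3$loa_mm), c(2, 2))
  # limits are symmetric about the bias
  st4 <- length_agreement(c(10, 12, 15, 19), c(9, 13, 14, 21))
  expect_equal(mean(st4$loa_mm), st4$bias_mm)
})

test_that("area agreement reports Pearson R with its contract", {
  x <- c(3, 5, 9, 12)
  expect_equal(area_agreement(x, 2.5 * x), 1)
  expect_equal(area_agreement(x, -2 * x + 40), -1)
  expect_error(area_agreement(x, rep(4, 4)), "zero variance")
  expect_error(area_agreement(x[1:2], x[1:2]), "length >= 3")
})
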