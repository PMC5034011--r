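# Parametric vessel phantom: ground-truth geometry and cap, biplane
# projections and polar OCT pullback rendering. Everything downstream of
# this module can be exercised without clinical data.

#' Phantom vessel configuration
#'
#' Describes a synthetic coronary segment: a tube with an optional Gaussian
#' stenosis and elliptical cross-sections, two side branches, a fibrous cap
#' of known thickness over a patch of the wall, a linear per-frame rotation
#' drift of the OCT probe, and multiplicative speckle.
#'
#' Defaults emulate the imaging conditions of a mildly diseased coronary
#' segment: a 20 mm inter-branch segment of base radius 1.5 mm, a plaque
#' ~5 mm long covering ~140 degrees of the circumference, OCT frames of
#' 968 A-lines by 504 radial samples over a 4.3 mm scan depth (radial pixel
#' ~8.5 um), 200 um inter-frame distance, and 0.5 deg/frame catheter twist.
#'
#' @param tube_length_mm Segment length (mm).
#' @param base_radius_mm Major semi-axis of the undiseased lumen (mm).
#' @param stenosis_depth Fractional lumen narrowing at the stenosis centre,
#'   in `[0, 1)`; both semi-axes are scaled by `1 - depth` at the centre.
#' @param stenosis_center_mm,stenosis_width_mm Centre and width of the
#'   Gaussian stenosis profile; the Gaussian sigma is `width / 2`.
#' @param ellipticity Ratio `b/a` of the cross-section semi-axes, in `(0, 1]`.
#' @param branch_positions_mm Arc-lengths of the two side branches (mm).
#' @param branch_angles_deg Angular orientations of the branches, `[0, 360)`.
#' @param branch_diameters_mm Daughter-vessel diameters (mm), used by the
#'   flow scaling law.
#' @param cap_region List with `s_mm = c(from, to)` and
#'   `theta_deg = c(from, to)` (angular range may wrap through 0).
#' @param cap_thickness Thickness field descriptor: one of
#'   `list(type = "constant", thickness_um)`,
#'   `list(type = "ramp", from_um, to_um)` (linear in arc-length), or
#'   `list(type = "gaussian_dip", base_um, min_um, sigma_s_mm,
#'   sigma_theta_deg)` (dip centred on the cap region).
#' @param rotation_drift_deg_per_frame Linear probe rotation drift.
#' @param noise_amplitude Multiplicative speckle amplitude (fraction).
#' @param inter_frame_um OCT inter-frame distance (um).
#' @param n_alines,n_radial OCT polar raster size (A-lines x radial samples).
#' @param scan_depth_mm OCT radial scan depth (mm).
#' @param seed Integer seed; rendering is deterministic given the seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(tube_length_mm = 20,
                           base_radius_mm = 1.5,
                           stenosis_depth = 0.3,
                           stenosis_center_mm = 10,
                           stenosis_width_mm = 3,
                           ellipticity = 0.9,
                           branch_positions_mm = c(3, 17),
                           branch_angles_deg = c(30, 120),
                           branch_diameters_mm = c(2.2, 1.8),
                           cap_region = list(s_mm = c(8, 13),
                                             theta_deg = c(40, 180)),
                           cap_thickness = list(type = "gaussian_dip",
                                                base_um = 300, min_um = 120,
                                                sigma_s_mm = 1.5,
                                                sigma_theta_deg = 45),
                           rotation_drift_deg_per_frame = 0.5,
                           noise_amplitude = 0.2,
                           inter_frame_um = 200,
                           n_alines = 968,
                           n_radial = 504,
                           scan_depth_mm = 4.3,
                           seed = 7) {
  cfg <- structure(
    list(tube_length_mm = tube_length_mm,
         base_radius_mm = base_radius_mm,
         stenosis_depth = stenosis_depth,
         stenosis_center_mm = stenosis_center_mm,
         stenosis_width_mm = stenosis_width_mm,
         ellipticity = ellipticity,
         branch_positions_mm = branch_positions_mm,
         branch_angles_deg = branch_angles_deg,
         branch_diameters_mm = branch_diameters_mm,
         cap_region = cap_region,
         cap_thickness = cap_thickness,
         rotation_drift_deg_per_frame = rotation_drift_deg_per_frame,
         noise_amplitude = noise_amplitude,
         inter_frame_um = inter_frame_um,
         n_alines = as.integer(n_alines),
         n_radial = as.integer(n_radial),
         scan_depth_mm = scan_depth_mm,
         seed = as.integer(seed)),
    class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (!is.numeric(cfg$tube_length_mm) || cfg$tube_length_mm <= 0)
    stop_cfg("tube_length_mm", "must be a positive length in mm")
  if (cfg$base_radius_mm <= 0)
    stop_cfg("base_radius_mm", "must be positive")
  if (cfg$stenosis_depth < 0 || cfg$stenosis_depth >= 1)
    stop_cfg("stenosis_depth", "must lie in [0, 1)")
  if (cfg$stenosis_center_mm - cfg$stenosis_width_mm < 0 ||
      cfg$stenosis_center_mm + cfg$stenosis_width_mm > cfg$tube_length_mm)
    stop_cfg("stenosis_center_mm",
             "+/- stenosis_width_mm must lie inside the tube")
  if (cfg$ellipticity <= 0 || cfg$ellipticity > 1)
    stop_cfg("ellipticity", "must lie in (0, 1]")
  if (length(cfg$branch_positions_mm) != 2 ||
      any(cfg$branch_positions_mm < 0) ||
      any(cfg$branch_positions_mm > cfg$tube_length_mm))
    stop_cfg("branch_positions_mm", "must be two arc-lengths inside the tube")
  if (cfg$branch_positions_mm[1] == cfg$branch_positions_mm[2])
    stop_cfg("branch_positions_mm", "must be distinct")
  if (length(cfg$branch_angles_deg) != 2 ||
      any(cfg$branch_angles_deg < 0) || any(cfg$branch_angles_deg >= 360))
    stop_cfg("branch_angles_deg", "must be two angles in [0, 360)")
  if (any(cfg$branch_diameters_mm <= 0))
    stop_cfg("branch_diameters_mm", "must be positive")
  if (!is.list(cfg$cap_region) || length(cfg$cap_region$s_mm) != 2 ||
      length(cfg$cap_region$theta_deg) != 2)
    stop_cfg("cap_region", "needs s_mm and theta_deg ranges")
  if (cfg$cap_region$s_mm[1] >= cfg$cap_region$s_mm[2] ||
      cfg$cap_region$s_mm[1] < 0 ||
      cfg$cap_region$s_mm[2] > cfg$tube_length_mm)
    stop_cfg("cap_region", "s_mm range must be increasing and inside the tube")
  ct <- cfg$cap_thickness
  ok <- switch(ct$type %||% "",
    constant = isTRUE(ct$thickness_um > 0),
    ramp = isTRUE(ct$from_um > 0) && isTRUE(ct$to_um > 0),
    gaussian_dip = isTRUE(ct$base_um > 0) && isTRUE(ct$min_um > 0) &&
      isTRUE(ct$min_um <= ct$base_um) && isTRUE(ct$sigma_s_mm > 0) &&
      isTRUE(ct$sigma_theta_deg > 0),
    FALSE)
  if (!ok)
    stop_cfg("cap_thickness",
             "must be constant / ramp / gaussian_dip with positive thickness")
  if (cfg$noise_amplitude < 0)
    stop_cfg("noise_amplitude", "must be >= 0")
  if (cfg$inter_frame_um <= 0) stop_cfg("inter_frame_um", "must be positive")
  if (cfg$n_alines < 8) stop_cfg("n_alines", "must be at least 8")
  if (cfg$n_radial < 8) stop_cfg("n_radial", "must be at least 8")
  if (cfg$scan_depth_mm <= 0) stop_cfg("scan_depth_mm", "must be positive")
  invisible(cfg)
}

# Evaluate the configured cap thickness field (um); NA outside the cap
# region. Vectorised over (s_mm, theta_deg).
#' @noRd
cap_thickness_field <- function(cfg, s_mm, theta_deg) {
  reg <- cfg$cap_region
  inside <- s_mm >= reg$s_mm[1] & s_mm <= reg$s_mm[2] &
    angle_in_range(theta_deg, reg$theta_deg[1], reg$theta_deg[2])
  ct <- cfg$cap_thickness
  t_um <- switch(ct$type,
    constant = rep(ct$thickness_um, length(s_mm)),
    ramp = ct$from_um + (ct$to_um - ct$from_um) *
      (s_mm - reg$s_mm[1]) / diff(reg$s_mm),
    gaussian_dip = {
      s_c <- mean(reg$s_mm)
      span <- wrap_360(reg$theta_deg[2] - reg$theta_deg[1])
      th_c <- wrap_360(reg$theta_deg[1] + span / 2)
      dth <- wrap_180(theta_deg - th_c)
      ct$base_um - (ct$base_um - ct$min_um) *
        exp(-0.5 * (((s_mm - s_c) / ct$sigma_s_mm)^2 +
                      (dth / ct$sigma_theta_deg)^2))
    })
  t_um[!inside] <- NA_real_
  t_um
}

#' Generate a phantom vessel and its ground truth
#'
#' Builds the analytic geometry (centerline plus elliptical cross-sections
#' sampled every 0.1 mm), the per-frame true lumen and cap-abluminal
#' contours, the per-frame rotation offsets, and the true thickness field
#' binned on the standard cut-open grid.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_truth` with elements `config`,
#'   `geometry` (a `vessel_geometry`), `frame_z_mm`, `rotation_offset_deg`,
#'   `lumen_um` (frames x A-lines true lumen radius), `abluminal_um`
#'   (NA where no cap), and `thickness_truth` (a cut-open map, um).
#' @export
make_phantom_vessel <- function(config) {
  validate_phantom_config(config)
  cfg <- config
  L <- cfg$tube_length_mm
  s <- seq(0, L, by = 0.1)
  sigma <- cfg$stenosis_width_mm / 2
  shape <- 1 - cfg$stenosis_depth *
    exp(-(s - cfg$stenosis_center_mm)^2 / (2 * sigma^2))
  a <- cfg$base_radius_mm * shape
  b <- cfg$ellipticity * a
  branches <- data.frame(s_mm = cfg$branch_positions_mm,
                         angle_deg = cfg$branch_angles_deg,
                         diameter_mm = cfg$branch_diameters_mm)
  geometry <- vessel_geometry(
    data.frame(s_mm = s, x_mm = 0, y_mm = 0, z_mm = s,
               a_mm = a, b_mm = b, psi_deg = 0, extension = FALSE),
    branches = branches)

  dz <- cfg$inter_frame_um / 1000
  n_frames <- floor(L / dz + 1e-9) + 1
  frame_z <- (seq_len(n_frames) - 1) * dz
  offsets <- cfg$rotation_drift_deg_per_frame * (seq_len(n_frames) - 1)

  aline_angle <- (seq_len(cfg$n_alines) - 1) * 360 / cfg$n_alines
  shape_f <- 1 - cfg$stenosis_depth *
    exp(-(frame_z - cfg$stenosis_center_mm)^2 / (2 * sigma^2))
  lumen <- matrix(NA_real_, n_frames, cfg$n_alines)
  abluminal <- matrix(NA_real_, n_frames, cfg$n_alines)
  for (f in seq_len(n_frames)) {
    theta_v <- wrap_360(aline_angle + offsets[f])
    af <- cfg$base_radius_mm * shape_f[f]
    bf <- cfg$ellipticity * af
    r_mm <- ellipse_polar_radius(theta_v, af, bf)
    lumen[f, ] <- r_mm * 1000
    t_um <- cap_thickness_field(cfg, rep(frame_z[f], cfg$n_alines), theta_v)
    abluminal[f, ] <- lumen[f, ] + t_um
  }
  stopifnot(all(abluminal > lumen, na.rm = TRUE))

  # Truth thickness on the cut-open grid: per-bin mean of the analytic
  # field evaluated at the frame positions falling inside each row (the
  # ideal binned measurement of this pullback) and subsampled over the
  # angular bin; rows without a frame use the row midpoints. Bins only
  # partially covered by the cap average over the covered part.
  grid <- bin_grid()
  n_s <- grid_n_s(grid, L)
  sub <- (seq_len(5) - 0.5) / 5
  tt <- matrix(NA_real_, n_s, grid$n_theta)
  for (is in seq_len(n_s)) {
    lo <- (is - 1) * grid$ds_mm
    ss <- frame_z[frame_z >= lo & frame_z < lo + grid$ds_mm]
    if (!length(ss)) ss <- lo + sub * grid$ds_mm
    for (it in seq_len(grid$n_theta)) {
      th <- (it - 1 + sub) * grid$dtheta_deg
      v <- cap_thickness_field(cfg, rep(ss, each = length(th)),
                               rep(th, length(ss)))
      if (any(!is.na(v))) tt[is, it] <- mean(v, na.rm = TRUE)
    }
  }
  thickness_truth <- vessel_map(tt, counts = 1 * !is.na(tt), grid = grid,
                                length_mm = L, kind = "cap")

  structure(
    list(config = cfg, geometry = geometry, frame_z_mm = frame_z,
         rotation_offset_deg = offsets, lumen_um = lumen,
         abluminal_um = abluminal, thickness_truth = thickness_truth),
    class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<phantom_truth> %.1f mm tube, base radius %.2f mm, %d frames x %d A-lines\n",
    cfg$tube_length_mm, cfg$base_radius_mm, length(x$frame_z_mm),
    cfg$n_alines))
  cat(sprintf("  cap: %s over s [%.1f, %.1f] mm, theta [%g, %g] deg\n",
              cfg$cap_thickness$type, cfg$cap_region$s_mm[1],
              cfg$cap_region$s_mm[2], cfg$cap_region$theta_deg[1],
              cfg$cap_region$theta_deg[2]))
  invisible(x)
}

#' Annotation records for a phantom (landmarks and ROI)
#'
#' Stands in for the manual steps of the clinical workflow: side-branch
#' landmark identification in both modalities and the selection of the
#' region of interest containing the cap. Orientations seen in the OCT
#' frame are the true branch orientations minus the frame's rotation
#' offset, i.e. what an observer would annotate on the raw frames.
#'
#' @param truth A [make_phantom_vessel()] result.
#' @return A list with `landmarks` (data frame: label, frame, s_mm,
#'   oct_angle_deg, map_angle_deg, type) and `roi` (list: `frames`,
#'   `alines`; the A-line span may wrap).
#' @export
phantom_annotations <- function(truth) {
  cfg <- truth$config
  dz <- cfg$inter_frame_um / 1000
  br <- truth$geometry$branches
  frame_of <- function(s) {
    f <- round(s / dz) + 1
    pmin(pmax(f, 1L), length(truth$frame_z_mm))
  }
  bf <- frame_of(br$s_mm)
  lm <- data.frame(
    label = c("branch_A", "branch_B", "pullback_start", "pullback_end"),
    frame = c(bf, 1L, length(truth$frame_z_mm)),
    s_mm = c(br$s_mm, 0, cfg$tube_length_mm),
    oct_angle_deg = c(
      wrap_360(br$angle_deg - truth$rotation_offset_deg[bf]), NA, NA),
    map_angle_deg = c(br$angle_deg, NA, NA),
    type = c("side_branch", "side_branch", "pullback_end", "pullback_end"),
    stringsAsFactors = FALSE)

  reg <- cfg$cap_region
  in_s <- which(truth$frame_z_mm >= reg$s_mm[1] - 1e-9 &
                  truth$frame_z_mm <= reg$s_mm[2] + 1e-9)
  offs <- truth$rotation_offset_deg[in_s]
  d <- 360 / cfg$n_alines
  a0 <- wrap_360(reg$theta_deg[1] - max(offs))
  a1 <- wrap_360(reg$theta_deg[2] - min(offs))
  roi <- list(frames = c(min(in_s), max(in_s)),
              alines = c(floor(a0 / d) + 1L, ceiling(a1 / d) %% cfg$n_alines + 1L))
  list(landmarks = lm, roi = roi)
}

#' Render two angiographic silhouettes of a phantom vessel
#'
#' Orthographic projection of the lumen: a view with angle `v` measures
#' positions along the in-plane axis at angle `v` (degrees, counterclockwise
#' from the first sample's major axis); the silhouette at each longitudinal
#' position is the support interval of the local ellipse along that axis.
#' Vertices are sampled on the 76 um angiographic pixel grid longitudinally,
#' with sub-pixel transverse edge positions (as observer segmentation of a
#' 76 um image yields).
#'
#' @param truth A [make_phantom_vessel()] result.
#' @param view_angles Two view angles (degrees); their measurement axes must
#'   differ by at least 30 degrees.
#' @param pixel_mm Angiographic pixel size (mm).
#' @return A list of two `projection_contours` objects.
#' @export
render_biplane <- function(truth, view_angles = c(0, 90), pixel_mm = 0.076) {
  if (length(view_angles) != 2)
    stop_cfg("view_angles", "must contain exactly two angles")
  d <- abs(wrap_180(view_angles[1] - view_angles[2]))
  d <- min(d, 180 - d)
  if (d < 30)
    stop("view angles are only ", round(d, 1), " deg apart; angiographic ",
         "views must differ by at least 30 deg for a stable reconstruction. ",
         "Choose a wider pair, e.g. 0/90.", call. = FALSE)
  geom <- truth$geometry$samples
  L <- max(geom$s_mm)
  z <- seq(0, L, by = pixel_mm)
  a <- stats::approx(geom$s_mm, geom$a_mm, z)$y
  b <- stats::approx(geom$s_mm, geom$b_mm, z)$y
  psi <- stats::approx(geom$s_mm, geom$psi_deg, z)$y
  cx <- stats::approx(geom$s_mm, geom$x_mm, z)$y
  cy <- stats::approx(geom$s_mm, geom$y_mm, z)$y
  lapply(view_angles, function(v) {
    u <- c(cos(v * pi / 180), sin(v * pi / 180))
    mid <- cx * u[1] + cy * u[2]
    h <- ellipse_support_halfwidth(v, a, b, psi)
    structure(list(view_deg = v, z_mm = z, y_left = mid + h,
                   y_right = mid - h, pixel_mm = pixel_mm),
              class = "projection_contours")
  })
}

# Noise-free radial intensity template for one frame (A-lines x radial).
# Edges are anti-aliased over one radial pixel (partial-volume model), so
# the rendered interface position carries sub-pixel information the way a
# finite detector pixel does.
#' @noRd
oct_frame_template <- function(lumen_um, abluminal_um, rho_um,
                               wall_band_um = 250, lumen_level = 0.04,
                               wall_level = 1, behind_level = 0.35,
                               attenuation_um = 400) {
  n_alines <- length(lumen_um)
  n_r <- length(rho_um)
  drho <- rho_um[2] - rho_um[1]
  outer_um <- ifelse(is.na(abluminal_um), lumen_um + wall_band_um,
                     abluminal_um)
  R <- matrix(rho_um, n_alines, n_r, byrow = TRUE)
  Lm <- matrix(lumen_um, n_alines, n_r)
  Om <- matrix(outer_um, n_alines, n_r)
  rise <- pmin(pmax((R - Lm) / drho + 0.5, 0), 1)
  fall <- pmin(pmax((R - Om) / drho + 0.5, 0), 1)
  beyond <- behind_level * exp(-pmax(R - Om, 0) / attenuation_um)
  lumen_level + rise * (wall_level - lumen_level) -
    fall * (wall_level - beyond)
}

#' Render a polar OCT pullback of a phantom vessel
#'
#' Each frame is a polar image (A-line index by radial index) with a dark
#' lumen, a bright wall band between the true luminal and cap-abluminal
#' interfaces (or a fixed-depth wall band where no cap is defined), a darker
#' attenuated region beyond, and multiplicative speckle of the configured
#' amplitude. The per-frame rotation drift is baked into the truth contours.
#' Rendering is deterministic: frame `f` uses seed `config$seed + f`.
#'
#' @param truth A [make_phantom_vessel()] result.
#' @param frames Integer frame indices to render (default: all frames).
#' @return An object of class `oct_pullback`: list of frame matrices plus
#'   calibration metadata.
#' @export
render_oct_pullback <- function(truth, frames = NULL) {
  cfg <- truth$config
  frames <- frames %||% seq_along(truth$frame_z_mm)
  if (any(frames < 1 | frames > length(truth$frame_z_mm)))
    stop_cfg("frames", "must lie within the pullback")
  radial_pixel <- cfg$scan_depth_mm * 1000 / cfg$n_radial
  rho <- (seq_len(cfg$n_radial) - 0.5) * radial_pixel
  imgs <- lapply(frames, function(f) {
    img <- oct_frame_template(truth$lumen_um[f, ], truth$abluminal_um[f, ],
                              rho)
    if (cfg$noise_amplitude > 0) {
      img <- with_seed(cfg$seed + f, {
        img * (1 + cfg$noise_amplitude * stats::rnorm(length(img)))
      })
      img[img < 0] <- 0
    }
    img
  })
  structure(
    list(frames = imgs, frame_index = as.integer(frames),
         z_mm = truth$frame_z_mm[frames], n_alines = cfg$n_alines,
         n_radial = cfg$n_radial, radial_pixel_um = radial_pixel,
         inter_frame_um = cfg$inter_frame_um),
    class = "oct_pullback")
}

#' @export
print.oct_pullback <- function(x, ...) {
  cat(sprintf(
    "<oct_pullback> %d frames, %d A-lines x %d radial px (%.2f um/px, %g um between frames)\n",
    length(x$frames), x$n_alines, x$n_radial, x$radial_pixel_um,
    x$inter_frame_um))
  invisible(x)
}
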