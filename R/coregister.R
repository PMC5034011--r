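# Co-registration of the OCT pullback with the reconstructed geometry:
# axial (landmark pairs -> piecewise-linear frame-to-arc-length map) and
# rotational (side-branch orientations -> per-frame rotation offset,
# linear between the two branch anchors, constant outside).
#
# Convention used throughout: OCT A-line i sits at angle
# (i - 1) * 360 / n_alines degrees, counterclockwise; the rotational
# offset is added to the A-line angle to obtain the map angle.

#' Landmark record
#'
#' @param label Free-text label.
#' @param frame OCT frame index.
#' @param s_mm Arc-length on the reconstructed centerline (mm).
#' @param oct_angle_deg Orientation observed in the OCT frame (degrees;
#'   side branches only).
#' @param map_angle_deg Orientation on the cut-open map (degrees; side
#'   branches only).
#' @param type One of `"side_branch"`, `"narrowing"`, `"pullback_end"`.
#' @return A one-row data frame.
#' @export
landmark <- function(label, frame, s_mm, oct_angle_deg = NA_real_,
                     map_angle_deg = NA_real_,
                     type = c("side_branch", "narrowing", "pullback_end")) {
  type <- match.arg(type)
  data.frame(label = label, frame = as.integer(frame), s_mm = s_mm,
             oct_angle_deg = oct_angle_deg, map_angle_deg = map_angle_deg,
             type = type, stringsAsFactors = FALSE)
}

#' Axial registration from landmark pairs
#'
#' Piecewise-linear monotone mapping from OCT frame index to centerline
#' arc-length, interpolating the landmark anchors exactly and extrapolating
#' linearly beyond the outermost anchors.
#'
#' @param pairs Data frame with columns `frame` and `s_mm` (at least two
#'   rows, distinct frames).
#' @return An `axial_registration` object; evaluate with [axial_s()].
#' @export
axial_map <- function(pairs) {
  stopifnot(all(c("frame", "s_mm") %in% names(pairs)))
  pairs <- pairs[order(pairs$frame), c("frame", "s_mm")]
  pairs <- unique(pairs)
  if (nrow(pairs) < 2)
    stop("registration error: need at least two distinct landmark pairs",
         call. = FALSE)
  if (any(duplicated(pairs$frame)))
    stop("registration error: conflicting arc-lengths for one frame",
         call. = FALSE)
  if (any(diff(pairs$s_mm) <= 0))
    stop("registration error: landmark arc-lengths are not monotone in ",
         "frame order", call. = FALSE)
  structure(list(anchors = pairs), class = "axial_registration")
}

#' Evaluate an axial registration
#'
#' @param reg An [axial_map()] result.
#' @param frames Frame indices (numeric).
#' @return Arc-lengths (mm).
#' @export
axial_s <- function(reg, frames) {
  a <- reg$anchors
  s <- stats::approx(a$frame, a$s_mm, frames, rule = 2)$y
  n <- nrow(a)
  lo <- frames < a$frame[1]
  hi <- frames > a$frame[n]
  if (any(lo)) {
    sl <- (a$s_mm[2] - a$s_mm[1]) / (a$frame[2] - a$frame[1])
    s[lo] <- a$s_mm[1] + sl * (frames[lo] - a$frame[1])
  }
  if (any(hi)) {
    sl <- (a$s_mm[n] - a$s_mm[n - 1]) / (a$frame[n] - a$frame[n - 1])
    s[hi] <- a$s_mm[n] + sl * (frames[hi] - a$frame[n])
  }
  s
}

#' Rotational registration from two side-branch orientations
#'
#' The anchor offsets are the map orientation minus the OCT orientation of
#' each branch, wrapped to `(-180, 180]`. Between the two branch frames the
#' offset is interpolated linearly along the shortest signed arc between
#' the anchor offsets; outside, the nearest anchor's offset is held
#' constant. Anchor frames reproduce the anchor offsets exactly.
#'
#' @param branchA,branchB One-row landmark data frames (`frame`,
#'   `oct_angle_deg`, `map_angle_deg`) at distinct frames.
#' @return A `rotational_registration`; evaluate with [rotation_offset()].
#' @export
rotational_map <- function(branchA, branchB) {
  if (branchA$frame == branchB$frame)
    stop("registration error: branch landmarks must be at distinct frames",
         call. = FALSE)
  if (branchA$frame > branchB$frame) { tmp <- branchA; branchA <- branchB; branchB <- tmp }
  oA <- wrap_180(branchA$map_angle_deg - branchA$oct_angle_deg)
  oB <- wrap_180(branchB$map_angle_deg - branchB$oct_angle_deg)
  structure(list(frames = c(branchA$frame, branchB$frame),
                 offsets = c(oA, oB),
                 arc = wrap_180(oB - oA)),
            class = "rotational_registration")
}

#' Evaluate a rotational registration
#'
#' @param reg A [rotational_map()] result.
#' @param frames Frame indices (numeric).
#' @return Rotation offsets (degrees, wrapped to `(-180, 180]`).
#' @export
rotation_offset <- function(reg, frames) {
  fA <- reg$frames[1]
  fB <- reg$frames[2]
  u <- (frames - fA) / (fB - fA)
  u <- pmin(pmax(u, 0), 1)   # constant extrapolation outside the anchors
  wrap_180(reg$offsets[1] + u * reg$arc)
}

#' Combined registration
#'
#' @param axial An [axial_map()] result.
#' @param rotational A [rotational_map()] result.
#' @return A `registration` object.
#' @export
registration <- function(axial, rotational) {
  stopifnot(inherits(axial, "axial_registration"),
            inherits(rotational, "rotational_registration"))
  structure(list(axial = axial, rotational = rotational),
            class = "registration")
}

#' Resample cap thickness onto the shared cut-open grid
#'
#' Each thickness sample of frame `f`, A-line `i` is placed at
#' `s = axial(f)` and `theta = (i-1) * 360 / n_alines + rotation(f)`
#' (wrapped), then bin means are taken on the shared grid. Bins without
#' any cap sample carry count 0 (no-cap).
#'
#' @param profiles List of `thickness_profile` objects.
#' @param reg A [registration()].
#' @param grid A [bin_grid()].
#' @param length_mm Longitudinal extent of the map (mm); must match the
#'   WSS map it will be fused with.
#' @return A `cap_map` `vessel_map` (values in um).
#' @export
resample_cap_to_grid <- function(profiles, reg, grid = bin_grid(),
                                 length_mm) {
  rows <- lapply(profiles, function(p) {
    ok <- !p$samples$missing
    if (!any(ok)) return(NULL)
    f <- p$frame_index
    data.frame(
      s_mm = axial_s(reg$axial, rep(f, sum(ok))),
      theta_deg = wrap_360((p$samples$aline[ok] - 1) * 360 / p$n_alines +
                             rotation_offset(reg$rotational, f)),
      thickness_um = p$samples$thickness_um[ok])
  })
  d <- do.call(rbind, rows)
  if (is.null(d) || !nrow(d))
    stop("no valid thickness samples to resample", call. = FALSE)
  bin_wss(d, grid = grid, length_mm = length_mm, value = "thickness_um",
          kind = "cap")
}

#' Agreement statistics between paired length measurements
#'
#' Mean absolute difference (also as a percentage of the pairwise mean
#' length), Bland-Altman bias and 95 percent limits of agreement
#' (bias +/- 1.96 SD of the differences), and the Pearson correlation.
#'
#' @param oct_lengths,angio_lengths Paired length lists (mm), n >= 2.
#' @return A list of class `agreement_stats`.
#' @export
length_agreement <- function(oct_lengths, angio_lengths) {
  if (length(oct_lengths) != length(angio_lengths) ||
      length(oct_lengths) < 2)
    stop("need paired lists of equal length >= 2", call. = FALSE)
  d <- oct_lengths - angio_lengths
  m <- (oct_lengths + angio_lengths) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  r <- if (stats::sd(oct_lengths) > 0 && stats::sd(angio_lengths) > 0)
    stats::cor(oct_lengths, angio_lengths) else NA_real_
  structure(
    list(mean_abs_diff_mm = mean(abs(d)),
         mean_abs_diff_pct = mean(abs(d) / m) * 100,
         bias_mm = bias,
         loa_mm = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
         pearson_r = r, n = length(d)),
    class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> n=%d: |diff| %.2f mm (%.1f%%), bias %.2f mm, LoA [%.2f, %.2f] mm, R=%.3f\n",
    x$n, x$mean_abs_diff_mm, x$mean_abs_diff_pct, x$bias_mm, x$loa_mm[1],
    x$loa_mm[2], x$pearson_r))
  invisible(x)
}

#' Pearson correlation between paired lumen areas
#'
#' @param oct_areas,recon_areas Paired area lists (mm^2), n >= 3.
#' @return Pearson correlation coefficient.
#' @export
area_agreement <- function(oct_areas, recon_areas) {
  if (length(oct_areas) != length(recon_areas) || length(oct_areas) < 3)
    stop("need paired lists of equal length >= 3", call. = FALSE)
  if (stats::sd(oct_areas) == 0 || stats::sd(recon_areas) == 0)
    stop("correlation undefined: an area list has zero variance",
         call. = FALSE)
  stats::cor(oct_areas, recon_areas)
}
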