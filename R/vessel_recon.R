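# 3D lumen reconstruction from two angiographic projections, under the
# elliptical cross-section assumption. Views are treated as parallel
# (orthographic) projections; a view with angle v measures positions along
# the in-plane axis at angle v (degrees, counterclockwise).

#' Vessel geometry container
#'
#' Centerline samples with per-sample elliptical cross-sections, plus
#' side-branch records and extension flags.
#'
#' @param samples Data frame with columns `s_mm` (strictly increasing
#'   arc-length), `x_mm`, `y_mm`, `z_mm` (centerline), `a_mm`, `b_mm`
#'   (semi-axes, `a >= b > 0`), `psi_deg` (major-axis orientation) and
#'   logical `extension`.
#' @param branches Data frame with `s_mm`, `angle_deg`, `diameter_mm`
#'   (may be empty).
#' @return A `vessel_geometry` object.
#' @export
vessel_geometry <- function(samples, branches = NULL) {
  need <- c("s_mm", "x_mm", "y_mm", "z_mm", "a_mm", "b_mm", "psi_deg",
            "extension")
  if (!all(need %in% names(samples)))
    stop("geometry samples must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(diff(samples$s_mm) <= 0))
    stop("arc-length s_mm must be strictly increasing", call. = FALSE)
  if (any(samples$b_mm <= 0) || any(samples$a_mm < samples$b_mm - 1e-12))
    stop("semi-axes must satisfy a >= b > 0", call. = FALSE)
  branches <- branches %||% data.frame(s_mm = numeric(0),
                                       angle_deg = numeric(0),
                                       diameter_mm = numeric(0))
  core <- samples$s_mm[!samples$extension]
  if (nrow(branches) &&
      (any(branches$s_mm < min(core) - 1e-9) ||
         any(branches$s_mm > max(core) + 1e-9)))
    stop("branch arc-lengths must lie within the un-extended segment",
         call. = FALSE)
  structure(list(samples = samples, branches = branches),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  s <- x$samples
  core <- s[!s$extension, ]
  cat(sprintf(
    "<vessel_geometry> %d samples over %.1f mm (%d extension), %d branches\n",
    nrow(s), diff(range(core$s_mm)), sum(s$extension), nrow(x$branches)))
  invisible(x)
}

#' Cross-section areas of a vessel geometry
#'
#' Elliptical sections: area = pi * a * b.
#'
#' @param geom A `vessel_geometry`.
#' @param include_extensions Include inlet/outlet extension samples?
#' @return Numeric vector of areas (mm^2).
#' @export
section_area <- function(geom, include_extensions = FALSE) {
  s <- geom$samples
  if (!include_extensions) s <- s[!s$extension, ]
  pi * s$a_mm * s$b_mm
}

# Recover ellipse (a, b, psi) from two measured half support widths.
# Convention: the major axis is aligned with the measurement axis of one
# of the two views; among the valid candidates the one closest to the
# previous sample is kept (mirror-ambiguity resolved toward continuity).
#' @noRd
ellipse_from_widths <- function(hA, hB, vA, vB, prev = NULL) {
  delta <- (vB - vA) * pi / 180
  s2 <- sin(delta)^2
  cand <- list()
  bb <- (hB^2 - hA^2 * cos(delta)^2) / s2
  if (bb > 0 && bb <= hA^2 + 1e-12)
    cand <- c(cand, list(c(a = hA, b = sqrt(min(bb, hA^2)), psi = vA)))
  aa <- (hA^2 - hB^2 * cos(delta)^2) / s2
  if (aa > 0 && aa <= hB^2 + 1e-12)
    cand <- c(cand, list(c(a = hB, b = sqrt(min(aa, hB^2)), psi = vB)))
  if (!length(cand)) {
    # Degenerate measurement (inconsistent widths): fall back to the
    # area-preserving circle of the mean width.
    r <- (hA + hB) / 2
    return(c(a = r, b = r, psi = vA))
  }
  if (length(cand) == 1 || is.null(prev)) return(cand[[1]])
  d <- vapply(cand, function(e)
    abs(e["a"] - prev["a"]) + abs(e["b"] - prev["b"]) +
      abs(wrap_180(e["psi"] - prev["psi"])) / 90, numeric(1))
  cand[[which.min(d)]]
}

#' Reconstruct a 3D lumen from two projections
#'
#' The two silhouettes are matched by normalised longitudinal position,
#' the centerline is obtained by solving the two midline measurements for
#' the transverse position at every sample, and each cross-section is the
#' ellipse whose support widths reproduce both projected widths (major
#' axis aligned with one of the view axes; mirror ambiguity resolved
#' toward continuity with the previous sample). Samples are spaced at most
#' `ds_mm` apart in arc-length.
#'
#' @param pA,pB `projection_contours` objects (see [render_biplane()]), at
#'   view angles at least 30 degrees apart.
#' @param branches Optional side-branch records (data frame `s_mm`,
#'   `angle_deg`, `diameter_mm`), e.g. from landmark annotations.
#' @param ds_mm Maximum longitudinal sampling step (mm). Default 0.15.
#' @param smooth_window Optional boxcar window (samples) applied to the
#'   silhouettes; useful for noisy or pixel-quantised tracings. Default 1
#'   (off): observer-traced polylines are already smooth, and smoothing
#'   flattens genuine width gradients at stenosis shoulders.
#' @return A `vessel_geometry`.
#' @export
reconstruct_lumen <- function(pA, pB, branches = NULL, ds_mm = 0.15,
                              smooth_window = 1) {
  stopifnot(inherits(pA, "projection_contours"),
            inherits(pB, "projection_contours"))
  d <- abs(wrap_180(pA$view_deg - pB$view_deg))
  d <- min(d, 180 - d)
  if (d < 30)
    stop("view angles are only ", round(d, 1), " deg apart; need >= 30 deg",
         call. = FALSE)
  smooth_view <- function(p) {
    list(z = p$z_mm,
         l = moving_average_open(p$y_left, smooth_window),
         r = moving_average_open(p$y_right, smooth_window))
  }
  A <- smooth_view(pA)
  B <- smooth_view(pB)
  fill_gaps <- function(v, what) {
    if (anyNA(v$l) || anyNA(v$r)) {
      warning("silhouette gaps in ", what, " interpolated", call. = FALSE)
      v$l <- stats::approx(v$z[!is.na(v$l)], v$l[!is.na(v$l)], v$z,
                           rule = 2)$y
      v$r <- stats::approx(v$z[!is.na(v$r)], v$r[!is.na(v$r)], v$z,
                           rule = 2)$y
    }
    v
  }
  A <- fill_gaps(A, "view A")
  B <- fill_gaps(B, "view B")

  # Common parameterisation by normalised longitudinal position.
  lenA <- diff(range(A$z))
  lenB <- diff(range(B$z))
  len <- (lenA + lenB) / 2
  n <- max(2L, ceiling(len / ds_mm) + 1L)
  u <- seq(0, 1, length.out = n)
  at <- function(v, len0) {
    zz <- min(v$z) + u * len0
    list(l = stats::approx(v$z, v$l, zz, rule = 2)$y,
         r = stats::approx(v$z, v$r, zz, rule = 2)$y)
  }
  Ai <- at(A, lenA)
  Bi <- at(B, lenB)
  hA <- (Ai$l - Ai$r) / 2
  hB <- (Bi$l - Bi$r) / 2
  mA <- (Ai$l + Ai$r) / 2
  mB <- (Bi$l + Bi$r) / 2
  if (any(hA <= 0) || any(hB <= 0))
    stop("silhouette sides cross: left/right polylines overlap",
         call. = FALSE)

  # Transverse centerline position from the two midline measurements.
  vA <- pA$view_deg * pi / 180
  vB <- pB$view_deg * pi / 180
  M <- rbind(c(cos(vA), sin(vA)), c(cos(vB), sin(vB)))
  ct <- solve(M, rbind(mA, mB))
  x <- ct[1, ]
  y <- ct[2, ]
  z <- u * len

  ell <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("a", "b", "psi")))
  prev <- NULL
  for (i in seq_len(n)) {
    e <- ellipse_from_widths(hA[i], hB[i], pA$view_deg, pB$view_deg, prev)
    ell[i, ] <- e
    prev <- e
  }
  seg <- sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2)
  s <- c(0, cumsum(seg))
  vessel_geometry(
    data.frame(s_mm = s, x_mm = x, y_mm = y, z_mm = z,
               a_mm = ell[, "a"], b_mm = ell[, "b"], psi_deg = ell[, "psi"],
               extension = FALSE),
    branches = branches)
}

#' Extend the vessel inlet and outlet
#'
#' Appends straight extensions of constant end cross-section at both ends,
#' each of length `factor` times the local mean radius (`sqrt(a*b)`), to
#' push computational artifacts away from the segment of interest.
#' Extension samples are flagged and excluded from the cut-open maps.
#'
#' @param geom A `vessel_geometry`.
#' @param factor Extension length in units of the local mean radius.
#'   Default 5.
#' @return The extended `vessel_geometry`.
#' @export
extend_inlets_outlets <- function(geom, factor = 5) {
  stopifnot(factor >= 0)
  if (factor == 0) return(geom)
  s <- geom$samples
  if (nrow(s) < 2) stop("geometry needs at least 2 samples", call. = FALSE)
  ds <- stats::median(diff(s$s_mm))
  ext_block <- function(end) {
    i <- if (end == "inlet") 1L else nrow(s)
    j <- if (end == "inlet") 2L else nrow(s) - 1L
    r <- sqrt(s$a_mm[i] * s$b_mm[i])
    len <- factor * r
    dir <- c(s$x_mm[i] - s$x_mm[j], s$y_mm[i] - s$y_mm[j],
             s$z_mm[i] - s$z_mm[j])
    dir <- dir / sqrt(sum(dir^2))
    k <- max(1L, ceiling(len / ds))
    off <- seq_len(k) / k * len
    data.frame(s_mm = s$s_mm[i] + if (end == "inlet") -rev(off) else off,
               x_mm = s$x_mm[i] + dir[1] * (if (end == "inlet") rev(off) else off),
               y_mm = s$y_mm[i] + dir[2] * (if (end == "inlet") rev(off) else off),
               z_mm = s$z_mm[i] + dir[3] * (if (end == "inlet") rev(off) else off),
               a_mm = s$a_mm[i], b_mm = s$b_mm[i], psi_deg = s$psi_deg[i],
               extension = TRUE)
  }
  out <- rbind(ext_block("inlet"), s, ext_block("outlet"))
  rownames(out) <- NULL
  vessel_geometry(out, branches = geom$branches)
}
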