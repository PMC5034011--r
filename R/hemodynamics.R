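# Wall shear stress on the reconstructed lumen. The paper-scale CFD stage
# is replaced by the exact fully developed laminar elliptical-duct solution
# applied section by section (an importer accepts externally computed CFD
# samples in the same exchange format), followed by cut-open 2D binning and
# 50th-percentile normalisation.

#' Hemodynamic configuration
#'
#' Diameter-based scaling law for the boundary flows: the inflow and every
#' bifurcation split follow `Q = k * D^e` with the local diameter `D` in
#' mm. Defaults: blood viscosity 3.5e-3 Pa s, exponent `e = 2.27`
#' (empirical coronary flow-diameter scaling), `k` chosen to give 1 mL/s at
#' D = 3 mm. These constants are assumptions of this implementation, not
#' measured values.
#'
#' @param viscosity_pa_s Dynamic viscosity (Pa s).
#' @param flow_coef Coefficient `k` (m^3/s per mm^e).
#' @param flow_exp Exponent `e`.
#' @return A list of class `hemo_config`.
#' @export
hemo_config <- function(viscosity_pa_s = 3.5e-3,
                        flow_coef = 1e-6 / 3^2.27,
                        flow_exp = 2.27) {
  if (viscosity_pa_s <= 0) stop_cfg("viscosity_pa_s", "must be > 0")
  if (flow_coef <= 0) stop_cfg("flow_coef", "must be > 0")
  if (flow_exp <= 0) stop_cfg("flow_exp", "must be > 0")
  structure(list(viscosity_pa_s = viscosity_pa_s, flow_coef = flow_coef,
                 flow_exp = flow_exp), class = "hemo_config")
}

#' Cut-open map bin grid
#'
#' The shared 2D grid of the cut-open vessel representation: longitudinal
#' rows of `ds_mm` (default 0.2 mm) and angular bins of `dtheta_deg`
#' (default 10 degrees, 36 bins); both half-open, bin i covering
#' `[i*d, (i+1)*d)`.
#'
#' @param ds_mm Longitudinal bin size (mm).
#' @param dtheta_deg Angular bin width (degrees); must divide 360.
#' @return A `bin_grid` object.
#' @export
bin_grid <- function(ds_mm = 0.2, dtheta_deg = 10) {
  if (ds_mm <= 0) stop_cfg("ds_mm", "must be > 0")
  if (dtheta_deg <= 0 || 360 %% dtheta_deg != 0)
    stop_cfg("dtheta_deg", "must be a positive divisor of 360")
  structure(list(ds_mm = ds_mm, dtheta_deg = dtheta_deg,
                 n_theta = as.integer(360 / dtheta_deg)),
            class = "bin_grid")
}

#' @noRd
grid_n_s <- function(grid, length_mm) {
  as.integer(ceiling(round(length_mm / grid$ds_mm, 9)))
}

#' @noRd
bin_centers <- function(grid, length_mm) {
  n_s <- grid_n_s(grid, length_mm)
  list(s_mm = (seq_len(n_s) - 0.5) * grid$ds_mm,
       theta_deg = (seq_len(grid$n_theta) - 0.5) * grid$dtheta_deg)
}

# Shared container for cut-open 2D maps (WSS in Pa or cap thickness in um).
#' @noRd
vessel_map <- function(values, counts, grid, length_mm, kind,
                       normalized = FALSE) {
  stopifnot(is.matrix(values), all(dim(values) == dim(counts)))
  structure(list(values = values, counts = counts, grid = grid,
                 length_mm = length_mm, kind = kind,
                 normalized = normalized),
            class = c(paste0(kind, "_map"), "vessel_map"))
}

#' @export
print.vessel_map <- function(x, ...) {
  v <- x$values[x$counts > 0]
  cat(sprintf(
    "<%s_map> %d x %d bins (%.1f mm x 360 deg), %d filled%s; range %.3g-%.3g\n",
    x$kind, nrow(x$values), ncol(x$values), x$length_mm, sum(x$counts > 0),
    if (isTRUE(x$normalized)) ", normalized" else "",
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Assign boundary flows by the diameter scaling law
#'
#' The inlet flow is `k * D_inlet^e`; at every side branch the incoming
#' flow splits between the branch and the distal main vessel in proportion
#' to `D^e`, so conservation holds exactly at each bifurcation.
#'
#' @param geom A `vessel_geometry` (branches carried as records).
#' @param cfg A [hemo_config()].
#' @return A `flow_assignment`: `inlet_q_m3s`, `segments` (data frame
#'   `s_from`, `s_to`, `q_m3s` for the main vessel between take-offs),
#'   `branches` (data frame with outflow and split fraction).
#' @export
assign_flows <- function(geom, cfg = hemo_config()) {
  core <- geom$samples[!geom$samples$extension, ]
  diam <- function(s) {
    a <- stats::approx(core$s_mm, core$a_mm, s, rule = 2)$y
    b <- stats::approx(core$s_mm, core$b_mm, s, rule = 2)$y
    2 * sqrt(a * b)
  }
  d_in <- diam(min(core$s_mm))
  if (d_in <= 0) stop_cfg("geometry", "has a zero inlet diameter")
  q_in <- cfg$flow_coef * d_in^cfg$flow_exp
  br <- geom$branches
  br <- br[order(br$s_mm), , drop = FALSE]
  L <- max(core$s_mm)
  bounds <- c(min(core$s_mm), br$s_mm, L)
  q <- q_in
  seg_q <- numeric(nrow(br) + 1)
  frac <- q_br <- numeric(nrow(br))
  seg_q[1] <- q
  if (nrow(br)) {
    for (j in seq_len(nrow(br))) {
      if (br$diameter_mm[j] <= 0)
        stop_cfg("branches", "contains a zero daughter diameter")
      d_main <- diam(min(br$s_mm[j] + 0.25, L))
      wb <- br$diameter_mm[j]^cfg$flow_exp
      wm <- d_main^cfg$flow_exp
      frac[j] <- wb / (wb + wm)
      q_br[j] <- q * frac[j]
      q <- q - q_br[j]
      seg_q[j + 1] <- q
    }
  }
  structure(
    list(inlet_q_m3s = q_in,
         segments = data.frame(s_from = bounds[-length(bounds)],
                               s_to = bounds[-1], q_m3s = seg_q),
         branches = cbind(br, q_out_m3s = q_br, fraction = frac)),
    class = "flow_assignment")
}

#' @noRd
segment_flow_at <- function(flows, s_mm) {
  seg <- flows$segments
  idx <- findInterval(s_mm, c(seg$s_from[1], seg$s_to),
                      rightmost.closed = TRUE, all.inside = TRUE)
  seg$q_m3s[idx]
}

#' Analytic wall shear stress on the lumen surface
#'
#' At each cross-section the flow is modelled as fully developed laminar
#' flow through an elliptical duct carrying the section's assigned flow Q:
#' the axial pressure gradient is `G = 4 mu Q (a^2 + b^2) / (pi a^3 b^3)`
#' and the boundary shear magnitude at ellipse parameter angle phi is
#' `tau(phi) = G a^2 b^2 / (a^2 + b^2) * sqrt(cos^2 phi / a^2 +
#' sin^2 phi / b^2)`. In the circular limit this reduces to the
#' Hagen-Poiseuille wall shear `4 mu Q / (pi r^3)`. Shear is maximal at
#' the ends of the minor axis and minimal at the ends of the major axis.
#'
#' @param geom A `vessel_geometry` (extension samples are skipped: they
#'   exist to keep boundary effects out of real CFD, and never enter maps).
#' @param flows A [assign_flows()] result.
#' @param cfg A [hemo_config()].
#' @param n_boundary Boundary samples per section. Default 120.
#' @param ds_mm Longitudinal sampling step: sections are interpolated onto
#'   a regular arc-length grid of this pitch so that binned averages do
#'   not depend on the geometry's own (possibly irregular) sampling.
#'   Default 0.05.
#' @return Data frame of surface samples: `s_mm`, `theta_deg` (map
#'   convention: 0 at the first sample's major axis, counterclockwise),
#'   `wss_pa`.
#' @export
surrogate_wss <- function(geom, flows, cfg = hemo_config(),
                          n_boundary = 120, ds_mm = 0.05) {
  raw <- geom$samples[!geom$samples$extension, ]
  s_grid <- seq(min(raw$s_mm), max(raw$s_mm), by = ds_mm)
  core <- data.frame(
    s_mm = s_grid,
    a_mm = stats::approx(raw$s_mm, raw$a_mm, s_grid)$y,
    b_mm = stats::approx(raw$s_mm, raw$b_mm, s_grid)$y,
    psi_deg = stats::approx(raw$s_mm, raw$psi_deg, s_grid)$y)
  psi_ref <- core$psi_deg[1]
  phi <- (seq_len(n_boundary) - 0.5) * 2 * pi / n_boundary
  mu <- cfg$viscosity_pa_s
  out <- lapply(seq_len(nrow(core)), function(i) {
    a <- core$a_mm[i] * 1e-3
    b <- core$b_mm[i] * 1e-3
    Q <- segment_flow_at(flows, core$s_mm[i])
    G <- 4 * mu * Q * (a^2 + b^2) / (pi * a^3 * b^3)
    tau <- G * a^2 * b^2 / (a^2 + b^2) *
      sqrt(cos(phi)^2 / a^2 + sin(phi)^2 / b^2)
    theta <- wrap_360(atan2(b * sin(phi), a * cos(phi)) * 180 / pi +
                        core$psi_deg[i] - psi_ref)
    data.frame(s_mm = core$s_mm[i], theta_deg = theta, wss_pa = tau)
  })
  do.call(rbind, out)
}

#' Import externally computed WSS samples
#'
#' Reads a CSV of surface samples (columns `s_mm`, `theta_deg`, `wss_pa`),
#' validates them and returns a sample set interchangeable with
#' [surrogate_wss()] output.
#'
#' @param path CSV file path.
#' @return Data frame sorted by `s_mm`, `theta_deg`.
#' @export
import_external_wss <- function(path) {
  d <- utils::read.csv(path)
  need <- c("s_mm", "theta_deg", "wss_pa")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("WSS sample file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(d$wss_pa) | d$wss_pa < 0)
  if (length(bad))
    stop("WSS sample file contains negative or non-finite wss_pa at row ",
         bad[1], call. = FALSE)
  d <- d[order(d$s_mm, d$theta_deg), need]
  rownames(d) <- NULL
  d
}

#' Bin surface samples onto the cut-open 2D grid
#'
#' Per-bin arithmetic mean of the sample values; empty bins carry count 0
#' and are excluded from all statistics.
#'
#' @param samples Data frame with `s_mm`, `theta_deg` and a value column.
#' @param grid A [bin_grid()].
#' @param length_mm Longitudinal extent of the map (default: max `s_mm`).
#' @param value Name of the value column. Default `"wss_pa"`.
#' @param kind Map kind label (`"wss"` or `"cap"`).
#' @return A `vessel_map` of dimension `n_s x n_theta`.
#' @export
bin_wss <- function(samples, grid = bin_grid(), length_mm = NULL,
                    value = "wss_pa", kind = "wss") {
  length_mm <- length_mm %||% max(samples$s_mm)
  n_s <- grid_n_s(grid, length_mm)
  # round to 9 decimals before flooring: samples sitting exactly on a bin
  # edge (e.g. frames spaced at a multiple of ds) must land in the bin the
  # half-open convention assigns them to, not drift on float jitter
  i_s <- pmin(pmax(floor(round(samples$s_mm / grid$ds_mm, 9)) + 1L, 1L),
              n_s)
  i_t <- floor(round(wrap_360(samples$theta_deg) / grid$dtheta_deg, 9)) + 1L
  i_t <- pmin(i_t, grid$n_theta)
  idx <- (i_t - 1L) * n_s + i_s
  v <- samples[[value]]
  sums <- counts <- numeric(n_s * grid$n_theta)
  tab <- tapply(v, idx, sum)
  cnt <- tapply(rep(1, length(idx)), idx, sum)
  at <- as.integer(names(tab))
  sums[at] <- tab
  counts[at] <- cnt
  vals <- matrix(ifelse(counts > 0, sums / pmax(counts, 1), NA_real_),
                 n_s, grid$n_theta)
  vessel_map(vals, matrix(counts, n_s, grid$n_theta), grid, length_mm, kind)
}

#' Normalise a WSS map by its 50th percentile
#'
#' Divides all counted bins by the median over counted bins, making the
#' map invariant to a global rescaling of the inflow. Idempotent after
#' the first application (the median of the normalised map is exactly 1).
#'
#' @param map A `wss_map` from [bin_wss()].
#' @return The normalised map (`normalized` flag set).
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "vessel_map"))
  v <- map$values[map$counts > 0]
  if (!length(v))
    stop("normalization error: map has no counted bins", call. = FALSE)
  med <- stats::median(v)
  if (!is.finite(med) || med <= 0)
    stop("normalization error: 50th percentile is not positive",
         call. = FALSE)
  map$values <- map$values / med
  map$normalized <- TRUE
  map
}
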