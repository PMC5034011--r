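# Fusion of the co-registered cap-thickness and WSS maps into the
# four-level risk map, region-area quantification, and the threshold
# sensitivity analysis.
#
# Risk index (boundary inclusivities taken literally):
#   cap  > t_cap  &  wss <  t_wss  ->  LOW
#   cap  > t_cap  &  wss >= t_wss  ->  MED_WSS   (high shear only)
#   cap <= t_cap  &  wss <  t_wss  ->  MED_CAP   (thin cap only)
#   cap <= t_cap  &  wss >= t_wss  ->  HIGH      (both factors)

RISK_LEVELS <- c("LOW", "MED_WSS", "MED_CAP", "HIGH")

#' Risk thresholds
#'
#' Defaults: cap-thickness cutoff 151 um (best rupture predictor for
#' representative fibrous caps) and WSS cutoff 1.7 Pa (transition between
#' intermediate and high shear).
#'
#' @param t_cap_um Cap thickness threshold (um); thin means `<=` this.
#' @param t_wss_pa WSS threshold (Pa); high means `>=` this.
#' @return A `risk_thresholds` object.
#' @export
risk_thresholds <- function(t_cap_um = 151, t_wss_pa = 1.7) {
  if (t_cap_um <= 0) stop_cfg("t_cap_um", "must be > 0")
  if (t_wss_pa <= 0) stop_cfg("t_wss_pa", "must be > 0")
  structure(list(t_cap_um = t_cap_um, t_wss_pa = t_wss_pa),
            class = "risk_thresholds")
}

#' Classify bins by cap thickness and WSS
#'
#' Vectorised four-level risk classification. Bins without cap coverage
#' (`NA` cap) are classified as if the cap were above threshold (the WSS
#' map covers the whole segment while the cap covers only the plaque) and
#' reported via the `no_cap` attribute.
#'
#' @param cap_um Cap thickness (um), `NA` for no-cap bins.
#' @param wss_pa WSS (Pa), non-negative.
#' @param thresholds A [risk_thresholds()].
#' @return Factor with levels `LOW`, `MED_WSS`, `MED_CAP`, `HIGH` and a
#'   logical `no_cap` attribute.
#' @export
classify_bin <- function(cap_um, wss_pa, thresholds = risk_thresholds()) {
  if (any(wss_pa < 0, na.rm = TRUE))
    stop("classify_bin: negative WSS violates the contract", call. = FALSE)
  no_cap <- is.na(cap_um)
  cap <- ifelse(no_cap, thresholds$t_cap_um + 1, cap_um)
  thin <- cap <= thresholds$t_cap_um
  high <- wss_pa >= thresholds$t_wss_pa
  lev <- ifelse(!thin & !high, "LOW",
         ifelse(!thin & high, "MED_WSS",
         ifelse(thin & !high, "MED_CAP", "HIGH")))
  structure(factor(lev, levels = RISK_LEVELS), no_cap = no_cap)
}

#' Build the four-level risk map
#'
#' Applies [classify_bin()] bin-wise to a cap map and a WSS map sharing
#' one grid. Bins without WSS coverage are `NO_DATA`. Region area
#' fractions are attached, both over all classified bins and over the
#' cap-covered bins only.
#'
#' @param capmap A `cap_map` (um) from [resample_cap_to_grid()].
#' @param wssmap A `wss_map` (Pa) from [bin_wss()]; pass absolute (not
#'   normalised) values when using the default Pa threshold.
#' @param thresholds A [risk_thresholds()].
#' @return A `risk_map`: integer level matrix (0 LOW, 1 MED_WSS,
#'   2 MED_CAP, 3 HIGH, -1 NO_DATA), `fractions`, `fractions_cap_covered`,
#'   `thresholds`, `grid`.
#' @export
build_risk_map <- function(capmap, wssmap, thresholds = risk_thresholds()) {
  if (!inherits(capmap, "cap_map"))
    stop("`capmap` must be a cap_map (got ", class(capmap)[1],
         "); the argument order is cap map first, WSS map second",
         call. = FALSE)
  if (!inherits(wssmap, "wss_map"))
    stop("`wssmap` must be a wss_map (got ", class(wssmap)[1], ")",
         call. = FALSE)
  if (!identical(dim(capmap$values), dim(wssmap$values)) ||
      !isTRUE(all.equal(capmap$grid$ds_mm, wssmap$grid$ds_mm)) ||
      !isTRUE(all.equal(capmap$grid$dtheta_deg, wssmap$grid$dtheta_deg)))
    stop("fusion error: cap and WSS maps do not share one bin grid",
         call. = FALSE)
  classified <- wssmap$counts > 0
  cap <- capmap$values
  cap[capmap$counts == 0] <- NA_real_
  levels <- matrix(-1L, nrow(cap), ncol(cap))
  cl <- classify_bin(cap[classified], wssmap$values[classified], thresholds)
  levels[classified] <- as.integer(cl) - 1L
  frac <- function(mask) {
    k <- levels[mask]
    if (!length(k)) return(stats::setNames(rep(NA_real_, 4), RISK_LEVELS))
    stats::setNames(tabulate(k + 1L, nbins = 4) / length(k), RISK_LEVELS)
  }
  structure(
    list(levels = levels, grid = capmap$grid, length_mm = capmap$length_mm,
         thresholds = thresholds,
         classified = classified, cap_covered = capmap$counts > 0,
         fractions = frac(classified),
         fractions_cap_covered = frac(classified & capmap$counts > 0)),
    class = "risk_map")
}

#' @export
print.risk_map <- function(x, ...) {
  f <- round(100 * x$fractions, 1)
  cat(sprintf(
    "<risk_map> %d x %d bins, thresholds %g um / %g Pa\n  LOW %.1f%% | MED_WSS %.1f%% | MED_CAP %.1f%% | HIGH %.1f%%\n",
    nrow(x$levels), ncol(x$levels), x$thresholds$t_cap_um,
    x$thresholds$t_wss_pa, f[1], f[2], f[3], f[4]))
  invisible(x)
}

#' Region area fractions of a risk map
#'
#' @param map A [build_risk_map()] result.
#' @param cap_covered_only Restrict to bins with cap coverage?
#' @return Named numeric vector of four fractions summing to 1.
#' @export
region_fractions <- function(map, cap_covered_only = FALSE) {
  stopifnot(inherits(map, "risk_map"))
  f <- if (cap_covered_only) map$fractions_cap_covered else map$fractions
  if (all(is.na(f)))
    stop("risk map has no classified bins", call. = FALSE)
  f
}

#' Threshold sensitivity of the risk map
#'
#' Builds one risk map per combination of the cap and WSS threshold lists
#' (defaults: the central values plus/minus about 7 percent, i.e.
#' 141/151/161 um and 1.6/1.7/1.8 Pa, nine maps) and reports, per region,
#' the minimum and maximum relative area change against the central map.
#'
#' @param capmap,wssmap As in [build_risk_map()].
#' @param cap_list_um Cap thresholds (must contain `central[1]`).
#' @param wss_list_pa WSS thresholds (must contain `central[2]`).
#' @param central Central threshold pair `c(um, Pa)`.
#' @return A `sensitivity_result`: `maps` (list, one per pair), `grid` of
#'   pairs, `variability` (per region min/max change, percent),
#'   `central_fractions`.
#' @export
threshold_sensitivity <- function(capmap, wssmap,
                                  cap_list_um = c(141, 151, 161),
                                  wss_list_pa = c(1.6, 1.7, 1.8),
                                  central = c(151, 1.7)) {
  if (!length(cap_list_um) || !length(wss_list_pa))
    stop_cfg("cap_list_um/wss_list_pa", "must be non-empty")
  if (!any(abs(cap_list_um - central[1]) < 1e-9))
    stop_cfg("cap_list_um", "must contain the central value")
  if (!any(abs(wss_list_pa - central[2]) < 1e-9))
    stop_cfg("wss_list_pa", "must contain the central value")
  pairs <- expand.grid(t_cap_um = cap_list_um, t_wss_pa = wss_list_pa,
                       KEEP.OUT.ATTRS = FALSE)
  maps <- lapply(seq_len(nrow(pairs)), function(k)
    build_risk_map(capmap, wssmap,
                   risk_thresholds(pairs$t_cap_um[k], pairs$t_wss_pa[k])))
  central_k <- which(abs(pairs$t_cap_um - central[1]) < 1e-9 &
                       abs(pairs$t_wss_pa - central[2]) < 1e-9)
  f0 <- maps[[central_k]]$fractions
  changes <- vapply(maps, function(m) {
    ifelse(f0 > 0, (m$fractions - f0) / f0 * 100,
           ifelse(m$fractions == 0, 0, NA_real_))
  }, numeric(4))
  variability <- data.frame(
    region = RISK_LEVELS,
    min_pct = apply(changes, 1, min),
    max_pct = apply(changes, 1, max))
  structure(
    list(maps = maps, grid = pairs, central_index = central_k,
         central_fractions = f0, variability = variability),
    class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %d risk maps\n", length(x$maps)))
  v <- x$variability
  for (i in seq_len(nrow(v)))
    cat(sprintf("  %-8s area change %+.0f%% to %+.0f%%\n", v$region[i],
                v$min_pct[i], v$max_pct[i]))
  invisible(x)
}

#' Plot a risk map
#'
#' Cut-open rendering with the conventional palette: gray LOW, blue
#' MED_WSS (high shear), yellow MED_CAP (thin cap), red HIGH, white
#' NO_DATA.
#'
#' @param x A `risk_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.risk_map <- function(x, ...) {
  pal <- c("white", "gray70", "steelblue3", "gold", "red3")
  z <- x$levels + 1L
  sc <- bin_centers(x$grid, x$length_mm)
  graphics::image(sc$s_mm, sc$theta_deg, z, breaks = seq(-0.5, 4.5, by = 1),
                  col = pal, xlab = "arc-length s (mm)",
                  ylab = "angle (deg)", main = "risk map", ...)
  invisible(x)
}
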