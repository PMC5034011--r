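# Shared fixtures: reduced-raster phantom configurations (fast to render
# and segment while keeping several pixels across the cap) and direct
# constructors for cut-open maps and thickness profiles.

small_phantom <- function(...) {
  args <- utils::modifyList(list(n_alines = 120, n_radial = 80), list(...))
  do.call(phantom_config, args)
}

# Build a vessel map directly from a value matrix (rows = longitudinal
# bins, cols = angular bins); NA entries become uncovered bins.
map_from_matrix <- function(vals, kind = "wss", ds = 0.2, dth = 10) {
  grid <- bin_grid(ds, dth)
  sc_s <- (seq_len(nrow(vals)) - 0.5) * ds
  sc_t <- (seq_len(ncol(vals)) - 0.5) * dth
  d <- expand.grid(s_mm = sc_s, theta_deg = sc_t)
  d$value <- as.vector(vals)
  d <- d[!is.na(d$value), ]
  names(d)[3] <- if (kind == "wss") "wss_pa" else "thickness_um"
  bin_wss(d, grid, length_mm = nrow(vals) * ds, value = names(d)[3],
          kind = kind)
}

# A thickness profile with the given per-A-line thicknesses, bypassing
# segmentation (for registration / resampling / summary-statistics tests).
fake_profile <- function(frame, z_mm, thickness_um, alines = NULL,
                         n_alines = 120) {
  alines <- alines %||% seq_along(thickness_um)
  ok <- is.finite(thickness_um)
  structure(
    list(samples = data.frame(aline = alines, thickness_um = thickness_um,
                              missing = !ok),
         min_um = min(thickness_um[ok]), mean_um = mean(thickness_um[ok]),
         sd_um = if (sum(ok) > 1) stats::sd(thickness_um[ok]) else NA_real_,
         degenerate = FALSE, frame_index = frame, z_mm = z_mm,
         n_alines = n_alines),
    class = "thickness_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Identity registration over `n` frames spaced `dz_mm` apart, with a
# constant rotation offset.
identity_registration <- function(n, dz_mm = 0.2, offset_deg = 0) {
  ax <- axial_map(data.frame(frame = c(1, n), s_mm = c(0, (n - 1) * dz_mm)))
  rot <- rotational_map(
    landmark("A", 1, 0, oct_angle_deg = 0, map_angle_deg = offset_deg),
    landmark("B", n, (n - 1) * dz_mm, oct_angle_deg = 0,
             map_angle_deg = offset_deg))
  registration(ax, rot)
}

# Wrap angles to (-180, 180] (test-local copy; angle arithmetic helper).
wrap_180 <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}
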