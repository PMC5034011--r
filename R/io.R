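# Serialisation of the exchange artifacts: OCT pullbacks as multi-page
# TIFF with a JSON sidecar, projections and contours and maps as CSV,
# geometry / landmarks / registration as JSON.

#' Write an OCT pullback as multi-page TIFF plus JSON sidecar
#'
#' Intensities are clamped to `[0, 1]` and stored as 16-bit grayscale.
#'
#' @param pullback An `oct_pullback`.
#' @param tif_path,sidecar_path Output paths.
#' @return Invisibly, the TIFF path.
#' @export
write_pullback <- function(pullback, tif_path, sidecar_path) {
  imgs <- lapply(pullback$frames, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(imgs, tif_path, bits.per.sample = 16)
  meta <- list(inter_frame_um = pullback$inter_frame_um,
               radial_pixel_um = pullback$radial_pixel_um,
               n_alines = pullback$n_alines,
               n_radial = pullback$n_radial,
               frame_index = pullback$frame_index)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(tif_path)
}

#' Read an OCT pullback from TIFF plus JSON sidecar
#'
#' @param tif_path,sidecar_path Input paths.
#' @return An `oct_pullback`.
#' @export
read_pullback <- function(tif_path, sidecar_path) {
  imgs <- tiff::readTIFF(tif_path, all = TRUE)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  frame_index <- as.integer(meta$frame_index %||% seq_along(imgs))
  structure(
    list(frames = imgs, frame_index = frame_index,
         z_mm = (frame_index - 1) * meta$inter_frame_um / 1000,
         n_alines = as.integer(meta$n_alines),
         n_radial = as.integer(meta$n_radial),
         radial_pixel_um = meta$radial_pixel_um,
         inter_frame_um = meta$inter_frame_um),
    class = "oct_pullback")
}

#' Write/read projection contours as CSV polylines
#'
#' Long format: `x_mm` (longitudinal), `y_mm`, `side` (left/right),
#' `view_deg`.
#'
#' @param projections List of `projection_contours` (see
#'   [render_biplane()]).
#' @param path CSV path.
#' @return Invisibly the path; `read_projections` returns the list.
#' @export
write_projections <- function(projections, path) {
  rows <- lapply(projections, function(p)
    rbind(data.frame(x_mm = p$z_mm, y_mm = p$y_left, side = "left",
                     view_deg = p$view_deg),
          data.frame(x_mm = p$z_mm, y_mm = p$y_right, side = "right",
                     view_deg = p$view_deg)))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$view_deg), function(v) {
    l <- v[v$side == "left", ]
    r <- v[v$side == "right", ]
    l <- l[order(l$x_mm), ]
    r <- r[order(r$x_mm), ]
    structure(list(view_deg = v$view_deg[1], z_mm = l$x_mm,
                   y_left = l$y_mm, y_right = r$y_mm,
                   pixel_mm = stats::median(diff(l$x_mm))),
              class = "projection_contours")
  })
}

#' Write/read a vessel geometry as JSON
#'
#' @param geom A `vessel_geometry`.
#' @param path JSON path.
#' @export
write_geometry <- function(geom, path) {
  jsonlite::write_json(list(samples = geom$samples,
                            branches = geom$branches),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- d$branches
  if (is.null(b) || !length(b))
    b <- data.frame(s_mm = numeric(0), angle_deg = numeric(0),
                    diameter_mm = numeric(0))
  vessel_geometry(as.data.frame(d$samples), branches = as.data.frame(b))
}

#' Write/read a cut-open map as CSV
#'
#' Wide matrix of values with an `s_mm` bin-centre column and one column
#' per angular bin; a companion `*.counts.csv` carries per-bin sample
#' counts.
#'
#' @param map A `vessel_map`.
#' @param path CSV path (counts written next to it).
#' @export
write_map_csv <- function(map, path) {
  sc <- bin_centers(map$grid, map$length_mm)
  hdr <- sprintf("theta_%g", sc$theta_deg)
  v <- as.data.frame(map$values)
  names(v) <- hdr
  utils::write.csv(cbind(s_mm = sc$s_mm, v), path, row.names = FALSE)
  cpath <- sub("\\.csv$", ".counts.csv", path)
  cv <- as.data.frame(map$counts)
  names(cv) <- hdr
  utils::write.csv(cbind(s_mm = sc$s_mm, cv), cpath, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @param kind Map kind (`"wss"` or `"cap"`).
#' @param normalized Was the map normalised?
#' @export
read_map_csv <- function(path, kind = "wss", normalized = FALSE) {
  d <- utils::read.csv(path, check.names = FALSE)
  cd <- utils::read.csv(sub("\\.csv$", ".counts.csv", path),
                        check.names = FALSE)
  vals <- as.matrix(d[, -1, drop = FALSE])
  counts <- as.matrix(cd[, -1, drop = FALSE])
  n_theta <- ncol(vals)
  ds <- if (nrow(d) > 1) d$s_mm[2] - d$s_mm[1] else 2 * d$s_mm[1]
  grid <- bin_grid(ds_mm = ds, dtheta_deg = 360 / n_theta)
  vessel_map(unname(vals), unname(counts), grid,
             length_mm = nrow(d) * ds, kind = kind, normalized = normalized)
}

#' Write/read thickness profiles as a long CSV
#'
#' Columns: `frame`, `z_mm`, `aline`, `thickness_um`, `missing`.
#'
#' @param profiles List of `thickness_profile` objects.
#' @param path CSV path.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    cbind(frame = p$frame_index, z_mm = p$z_mm, n_alines = p$n_alines,
          p$samples))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$frame), function(g) {
    ok <- !g$missing
    th <- g$thickness_um[ok]
    structure(
      list(samples = data.frame(aline = g$aline,
                                thickness_um = g$thickness_um,
                                missing = g$missing),
           min_um = if (any(ok)) min(th) else NA_real_,
           mean_um = if (any(ok)) mean(th) else NA_real_,
           sd_um = if (sum(ok) > 1) stats::sd(th) else NA_real_,
           degenerate = any(ok & g$thickness_um <= 1e-6, na.rm = TRUE),
           frame_index = g$frame[1], z_mm = g$z_mm[1],
           n_alines = g$n_alines[1]),
      class = "thickness_profile")
  })
}

#' Write/read landmark annotations as JSON
#'
#' @param annotations A list with `landmarks` (data frame) and `roi`
#'   (list), e.g. from [phantom_annotations()].
#' @param path JSON path.
#' @export
write_landmarks <- function(annotations, path) {
  jsonlite::write_json(annotations, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  d$landmarks <- as.data.frame(d$landmarks)
  d$roi$frames <- as.integer(d$roi$frames)
  d$roi$alines <- as.integer(d$roi$alines)
  d
}
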