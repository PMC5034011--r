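# End-to-end orchestration: phantom -> OCT segmentation -> biplane
# reconstruction -> WSS -> co-registration -> risk fusion, from a single
# configuration, with per-stage artifacts on disk so any stage can be
# re-run from the serialised outputs of the previous ones.

#' Default pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed; forwarded to every stochastic stage.
#' @param phantom Named list of [phantom_config()] overrides.
#' @param view_angles Biplane view angles (degrees).
#' @param stages Named logical list enabling `segment`, `reconstruct`,
#'   `wss`, `register`, `fuse`.
#' @param seg Named list of [oct_seg_params()] overrides.
#' @param hemo Named list of [hemo_config()] overrides.
#' @param thresholds Named list of [risk_thresholds()] overrides.
#' @param sensitivity Run the nine-map threshold sensitivity analysis?
#' @param validation_stride Frame stride for the lumen-area validation
#'   sweep (0 disables it).
#' @return A configuration list, YAML-serialisable.
#' @export
pipeline_config <- function(out_dir = tempfile("plaquefuse_run_"),
                            seed = 7,
                            phantom = list(),
                            view_angles = c(0, 90),
                            stages = list(),
                            seg = list(),
                            hemo = list(),
                            thresholds = list(),
                            sensitivity = TRUE,
                            validation_stride = 10) {
  st <- utils::modifyList(
    list(segment = TRUE, reconstruct = TRUE, wss = TRUE, register = TRUE,
         fuse = TRUE), stages)
  list(out_dir = out_dir, seed = as.integer(seed), phantom = phantom,
       view_angles = view_angles, stages = st, seg = seg, hemo = hemo,
       thresholds = thresholds, sensitivity = isTRUE(sensitivity),
       validation_stride = as.integer(validation_stride))
}

#' @noRd
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  do.call(pipeline_config, config[intersect(names(config),
                                            names(formals(pipeline_config)))])
}

#' @noRd
stage_log <- function(name, ...) {
  message(sprintf("[plaquefuse] %s: %s", name, sprintf(...)))
}

#' @noRd
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full risk-mapping pipeline on a phantom
#'
#' Executes the enabled stages in order (phantom simulation, OCT cap
#' segmentation, biplane 3D reconstruction, WSS computation and mapping,
#' co-registration, risk fusion), writes every intermediate artifact into
#' `config$out_dir`, and returns a summary record. Any stage error aborts
#' with the stage name and cause; artifacts of completed stages are
#' retained.
#'
#' @param config A [pipeline_config()] list or the path of a YAML file
#'   with the same fields.
#' @return A summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = cfg$seed, stages = cfg$stages, artifacts = list())
  art <- function(name) file.path(cfg$out_dir, name)

  ## --- phantom ---------------------------------------------------------
  truth <- run_stage("phantom", {
    pcfg <- do.call(phantom_config,
                    utils::modifyList(cfg$phantom, list(seed = cfg$seed)))
    make_phantom_vessel(pcfg)
  })
  ann <- phantom_annotations(truth)
  write_landmarks(ann, art("landmarks.json"))
  write_geometry(truth$geometry, art("geometry_truth.json"))
  summary$artifacts$landmarks <- "landmarks.json"
  pcfg <- truth$config
  roi_frames <- seq(ann$roi$frames[1], ann$roi$frames[2])
  stage_log("phantom", "%d frames, ROI frames %d-%d",
            length(truth$frame_z_mm), ann$roi$frames[1], ann$roi$frames[2])

  val_frames <- integer(0)
  if (cfg$validation_stride > 0)
    val_frames <- seq(1, length(truth$frame_z_mm),
                      by = cfg$validation_stride)
  render_frames <- sort(unique(c(roi_frames, val_frames)))
  pullback <- run_stage("phantom", render_oct_pullback(truth, render_frames))
  write_pullback(pullback, art("pullback.tif"), art("pullback.json"))
  summary$artifacts$pullback <- "pullback.tif"

  ## --- OCT cap segmentation -------------------------------------------
  profiles <- NULL
  lumens <- list()
  if (cfg$stages$segment) {
    seg <- do.call(oct_seg_params, cfg$seg)
    out <- run_stage("segment", {
      profiles <- list()
      for (f in render_frames) {
        lum <- segment_lumen(pullback, f, seg)
        lumens[[as.character(f)]] <- lum
        if (f %in% roi_frames) {
          abl <- segment_cap_abluminal(pullback, f, ann$roi, lum, seg)
          profiles[[length(profiles) + 1L]] <- thickness_profile(lum, abl)
        }
      }
      list(profiles = profiles, lumens = lumens)
    })
    profiles <- out$profiles
    lumens <- out$lumens
    write_profiles_csv(profiles, art("thickness_profiles.csv"))
    summary$artifacts$thickness <- "thickness_profiles.csv"
    all_th <- unlist(lapply(profiles, function(p)
      p$samples$thickness_um[!p$samples$missing]))
    summary$cap <- list(
      mean_um = mean(all_th),
      min_um = min(vapply(profiles, `[[`, numeric(1), "min_um")),
      representative_um = representative_thickness(profiles,
                                                   seed = cfg$seed))
    stage_log("segment", "%d ROI frames, cap min %.0f um, mean %.0f um",
              length(profiles), summary$cap$min_um, summary$cap$mean_um)
  }

  ## --- biplane reconstruction -----------------------------------------
  geom <- NULL
  if (cfg$stages$reconstruct) {
    geom <- run_stage("reconstruct", {
      proj <- render_biplane(truth, cfg$view_angles)
      write_projections(proj, art("projections.csv"))
      br <- truth$geometry$branches
      reconstruct_lumen(proj[[1]], proj[[2]], branches = br)
    })
    write_geometry(geom, art("geometry_recon.json"))
    summary$artifacts$geometry <- "geometry_recon.json"
    stage_log("reconstruct", "%d samples over %.1f mm",
              nrow(geom$samples), max(geom$samples$s_mm))
    if (length(val_frames) >= 3 && cfg$stages$segment) {
      oct_areas <- vapply(val_frames, function(f)
        lumen_area(lumens[[as.character(f)]]), numeric(1))
      gs <- geom$samples
      recon_areas <- stats::approx(gs$s_mm, pi * gs$a_mm * gs$b_mm,
                                   truth$frame_z_mm[val_frames],
                                   rule = 2)$y
      summary$validation <- list(
        lumen_area_pearson_r = area_agreement(oct_areas, recon_areas),
        n_validation_frames = length(val_frames))
    }
  }

  ## --- WSS -------------------------------------------------------------
  wssmap <- wssmap_norm <- NULL
  if (cfg$stages$wss) {
    if (is.null(geom)) stop("stage `wss` failed: no geometry available",
                            call. = FALSE)
    hemo <- do.call(hemo_config, cfg$hemo)
    wss_out <- run_stage("wss", {
      ext <- extend_inlets_outlets(geom, factor = 5)
      flows <- assign_flows(ext, hemo)
      samples <- surrogate_wss(ext, flows, hemo)
      utils::write.csv(samples, art("wss_samples.csv"), row.names = FALSE)
      wssmap <- bin_wss(samples, bin_grid(),
                        length_mm = pcfg$tube_length_mm)
      list(flows = flows, map = wssmap, norm = normalize_map(wssmap))
    })
    wssmap <- wss_out$map
    wssmap_norm <- wss_out$norm
    write_map_csv(wssmap, art("wss_map.csv"))
    write_map_csv(wssmap_norm, art("wss_map_normalized.csv"))
    summary$artifacts$wss_map <- "wss_map.csv"
    summary$wss <- list(
      inlet_q_ml_s = wss_out$flows$inlet_q_m3s * 1e6,
      median_pa = stats::median(wssmap$values[wssmap$counts > 0]))
    stage_log("wss", "median %.2f Pa over %d bins", summary$wss$median_pa,
              sum(wssmap$counts > 0))
  }

  ## --- co-registration -------------------------------------------------
  reg <- NULL
  capmap <- NULL
  if (cfg$stages$register) {
    if (is.null(profiles)) stop("stage `register` failed: no thickness ",
                                "profiles available", call. = FALSE)
    reg <- run_stage("register", {
      lm <- ann$landmarks
      ax <- axial_map(lm[!is.na(lm$s_mm), c("frame", "s_mm")])
      brs <- lm[lm$type == "side_branch", ]
      rot <- rotational_map(brs[1, ], brs[2, ])
      registration(ax, rot)
    })
    capmap <- run_stage("register",
      resample_cap_to_grid(profiles, reg, bin_grid(),
                           length_mm = pcfg$tube_length_mm))
    write_map_csv(capmap, art("cap_map.csv"))
    summary$artifacts$cap_map <- "cap_map.csv"
    if (!is.null(wssmap)) {
      at_cap <- capmap$counts > 0 & wssmap$counts > 0
      summary$wss_at_cap <- list(
        mean_pa = mean(wssmap$values[at_cap]),
        mean_normalized = mean(wssmap_norm$values[at_cap]))
      stage_log("register", "mean WSS at cap %.2f Pa (normalized %.2f)",
                summary$wss_at_cap$mean_pa,
                summary$wss_at_cap$mean_normalized)
    }
  }

  ## --- fusion ----------------------------------------------------------
  if (cfg$stages$fuse) {
    if (is.null(capmap) || is.null(wssmap))
      stop("stage `fuse` failed: needs both the cap and the WSS map",
           call. = FALSE)
    thr <- do.call(risk_thresholds, cfg$thresholds)
    risk <- run_stage("fuse", build_risk_map(capmap, wssmap, thr))
    utils::write.csv(risk$levels, art("risk_map.csv"), row.names = FALSE)
    summary$artifacts$risk_map <- "risk_map.csv"
    summary$risk <- list(
      thresholds = unclass(thr),
      fractions = as.list(risk$fractions),
      fractions_cap_covered = as.list(risk$fractions_cap_covered))
    if (cfg$sensitivity) {
      sens <- run_stage("fuse", threshold_sensitivity(capmap, wssmap))
      jsonlite::write_json(
        list(grid = sens$grid, variability = sens$variability,
             central_fractions = as.list(sens$central_fractions)),
        art("sensitivity.json"), auto_unbox = TRUE, digits = NA)
      summary$risk$sensitivity <- list(
        n_maps = length(sens$maps),
        variability = sens$variability)
      summary$artifacts$sensitivity <- "sensitivity.json"
    }
    stage_log("fuse", "fractions LOW %.2f MED_WSS %.2f MED_CAP %.2f HIGH %.2f",
              risk$fractions[1], risk$fractions[2], risk$fractions[3],
              risk$fractions[4])
  }

  summary$out_dir <- cfg$out_dir
  jsonlite::write_json(summary, art("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(summary)
}

#' Write a human-readable run report
#'
#' Produces `report.txt` plus, when the three maps exist, a `report.png`
#' triptych (WSS map, cap map, risk map) regenerated from the stored CSV
#' artifacts alone.
#'
#' @param summary A [run_pipeline()] summary (or the path of a
#'   `summary.json`).
#' @param out_dir Directory holding the artifacts (default: the run's).
#' @return Invisibly, the report path.
#' @export
write_report <- function(summary, out_dir = NULL) {
  if (is.character(summary))
    summary <- jsonlite::read_json(summary, simplifyVector = TRUE)
  out_dir <- out_dir %||% summary$out_dir
  lines <- c("plaquefuse run report",
             strrep("=", 40),
             sprintf("seed: %d", summary$seed))
  if (!is.null(summary$cap)) {
    lines <- c(lines, "",
               sprintf("cap thickness: mean %.0f um, min %.0f um, representative %.0f um",
                       summary$cap$mean_um, summary$cap$min_um,
                       summary$cap$representative_um))
  } else {
    lines <- c(lines, "", "no cap analyzed (segmentation disabled or empty ROI)")
  }
  if (!is.null(summary$wss))
    lines <- c(lines, sprintf("WSS: inlet flow %.2f mL/s, map median %.2f Pa",
                              summary$wss$inlet_q_ml_s,
                              summary$wss$median_pa))
  if (!is.null(summary$wss_at_cap))
    lines <- c(lines,
               sprintf("WSS at cap: %.2f Pa (normalized %.2f)",
                       summary$wss_at_cap$mean_pa,
                       summary$wss_at_cap$mean_normalized))
  if (!is.null(summary$risk)) {
    f <- unlist(summary$risk$fractions)
    lines <- c(lines, "",
               sprintf("risk map (thresholds %g um / %g Pa):",
                       summary$risk$thresholds$t_cap_um,
                       summary$risk$thresholds$t_wss_pa),
               sprintf("  LOW      %5.1f %%", 100 * f[["LOW"]]),
               sprintf("  MED_WSS  %5.1f %%", 100 * f[["MED_WSS"]]),
               sprintf("  MED_CAP  %5.1f %%", 100 * f[["MED_CAP"]]),
               sprintf("  HIGH     %5.1f %%", 100 * f[["HIGH"]]))
  }
  if (!is.null(summary$validation))
    lines <- c(lines, "",
               sprintf("lumen area agreement (OCT vs reconstruction): R = %.3f over %d frames",
                       summary$validation$lumen_area_pearson_r,
                       summary$validation$n_validation_frames))
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)

  wss_p <- file.path(out_dir, "wss_map.csv")
  cap_p <- file.path(out_dir, "cap_map.csv")
  if (!is.null(summary$risk) && file.exists(wss_p) && file.exists(cap_p)) {
    wssmap <- read_map_csv(wss_p, kind = "wss")
    capmap <- read_map_csv(cap_p, kind = "cap")
    thr <- risk_thresholds(summary$risk$thresholds$t_cap_um,
                           summary$risk$thresholds$t_wss_pa)
    risk <- build_risk_map(capmap, wssmap, thr)
    grDevices::png(file.path(out_dir, "report.png"), width = 900,
                   height = 900, res = 100)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
    sc <- bin_centers(wssmap$grid, wssmap$length_mm)
    graphics::image(sc$s_mm, sc$theta_deg, wssmap$values,
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "s (mm)", ylab = "angle (deg)",
                    main = "WSS (Pa)")
    capv <- capmap$values
    capv[capmap$counts == 0] <- NA
    graphics::image(sc$s_mm, sc$theta_deg, capv,
                    col = grDevices::hcl.colors(64, "inferno"),
                    xlab = "s (mm)", ylab = "angle (deg)",
                    main = "cap thickness (um)")
    plot(risk)
  }
  invisible(path)
}
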