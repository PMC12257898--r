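#' Segment, reconstruct and fit every spot of a simulated acquisition
#'
#' Runs the standard analysis chain on a `listmode_sim`: time histogram,
#' beam-structure segmentation (validated against the delivery log),
#' per-spot window extraction, mid-plane reconstruction, lateral projection
#' and sigmoid fit of the distal fall-off.
#'
#' @param sim A [simulate_listmode()] result.
#' @param spot_ids Spots to analyse (default: all spots in the log).
#' @param fit_range Length-2 fitting range in mm (default `c(8, 96)`, the
#'   head setting).
#' @param pixel_mm Reconstruction pixel pitch (mm).
#' @param plane_y_mm Reconstruction plane.
#' @return List with `intervals`, and per-spot named lists `events`,
#'   `images`, `profiles`, `fits`, plus `window_counts` and the `report`
#'   tibble from [fit_report()].
#' @export
analyze_spots <- function(sim, spot_ids = NULL, fit_range = c(8, 96),
                          pixel_mm = 8, plane_y_mm = 0) {
  if (is.null(spot_ids)) spot_ids <- sim$log$spot_id
  hist <- time_histogram(sim$stream, sim$acquisition$timestamp_resolution_ms)
  seg_cfg <- segmentation_config(saturation = sim$acquisition$saturation_model)
  intervals <- segment_intervals(hist, seg_cfg, log = sim$log)
  grid <- recon_grid(sim$geometry, pixel_mm)
  window <- sim$acquisition$window_after_spot_ms
  events <- list(); images <- list(); profiles <- list(); fits <- list()
  for (id in spot_ids) {
    ev <- tryCatch(
      extract_spot_window_events(sim$stream, intervals, id, window),
      error = function(e) NULL)
    if (is.null(ev)) next
    img <- reconstruct(ev, grid, plane_y_mm)
    prof <- longitudinal_profile(img)
    events[[id]] <- ev
    images[[id]] <- img
    profiles[[id]] <- prof
    fits[[id]] <- tryCatch(fit_sigmoid(prof, fit_range[1], fit_range[2]),
                           error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  list(intervals = intervals, events = events, images = images,
       profiles = profiles, fits = fits,
       window_counts = vapply(events, function(e) as.numeric(attr(e, "n")),
                              numeric(1)),
       report = fit_report(fits[ok]))
}

#' Scenario-aware run configuration
#'
#' Bundles every module configuration plus the scenario definition.  The
#' shifter scenarios convert the physical slab thickness to water-equivalent
#' thickness via slab density and relative stopping power:
#' `WET = thickness * density * RSP`.
#'
#' @param seed Integer seed (required for every stochastic stage).
#' @param scenario `"nominal"`, `"shifter_2mm"`, `"shifter_5mm"` or
#'   `"custom"`.
#' @param shifter_wet_mm WET override for `"custom"`.
#' @param slab_density_gcm3 Density of the solid-water slab (g/cm^3).
#' @param rsp Relative stopping power of the slab material.
#' @param plan,phantom,geometry,acquisition,production Module configurations.
#' @param fit_range Sigmoid fitting range (mm).
#' @param pixel_mm Reconstruction pixel pitch (mm).
#' @return A `run_config`.
#' @export
run_config <- function(seed,
                       scenario = c("nominal", "shifter_2mm", "shifter_5mm",
                                    "custom"),
                       shifter_wet_mm = 0,
                       slab_density_gcm3 = 1.045,
                       rsp = 0.98,
                       plan = head_like_plan(),
                       phantom = phantom_model(),
                       geometry = panel_geometry(),
                       acquisition = acquisition_config(),
                       production = production_model(),
                       fit_range = c(8, 96),
                       pixel_mm = 8) {
  if (missing(seed)) stop("`seed` is required")
  scenario <- match.arg(scenario)
  wet <- switch(scenario,
                nominal = 0,
                shifter_2mm = 2 * slab_density_gcm3 * rsp,
                shifter_5mm = 5 * slab_density_gcm3 * rsp,
                custom = shifter_wet_mm)
  phantom$shifter_wet_mm <- wet
  structure(list(seed = seed, scenario = scenario, shifter_wet_mm = wet,
                 plan = plan, phantom = phantom, geometry = geometry,
                 acquisition = acquisition, production = production,
                 fit_range = fit_range, pixel_mm = pixel_mm),
            class = "run_config")
}

.run_one_scenario <- function(config) {
  sim <- simulate_listmode(config$plan, config$phantom, config$geometry,
                           config$acquisition, config$production,
                           seed = config$seed)
  ana <- analyze_spots(sim, fit_range = config$fit_range,
                       pixel_mm = config$pixel_mm)
  pdrs <- lapply(seq_len(nrow(sim$log)), function(k) {
    pdr_from_dose(depth_dose_profile(as.list(sim$log[k, ]), config$phantom),
                  spot_id = sim$log$spot_id[k])
  })
  names(pdrs) <- sim$log$spot_id
  preds <- lapply(sim$log$spot_id, function(id) {
    predict_spot_image(sim, id,
                       measured_total_counts = ana$window_counts[[id]])
  })
  names(preds) <- sim$log$spot_id
  list(sim = sim, analysis = ana, pdrs = pdrs, predictions = preds)
}

#' Run the full verification pipeline and write its artifacts
#'
#' Simulates the configured scenario, segments and reconstructs it, fits the
#' per-spot activity ranges, predicts per-spot images from the production
#' maps and the log, computes per-spot proton dose ranges, and (for shifted
#' scenarios) re-runs the nominal scenario with the same seed and reports
#' per-spot and aggregated range shifts.  All artifacts are written as
#' CSV/JSON into `out_dir` together with a manifest.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param compare_with_nominal Compare against a nominal run with the same
#'   seed (default: whenever the scenario is not nominal).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         compare_with_nominal =
                           config$scenario != "nominal") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- .run_one_scenario(config)
  p <- function(f) file.path(out_dir, f)

  write_delivery_log_csv(res$sim$log, p("delivery_log.csv"))
  write_listmode_csv(res$sim$stream, p("listmode.csv"))
  write_intervals_csv(res$analysis$intervals, p("intervals.csv"))
  utils::write.csv(as.data.frame(res$analysis$report), p("fits.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(prediction_report(res$predictions)),
                   p("predictions.csv"), row.names = FALSE)

  offsets <- par_pdr_offset_table(res$analysis$fits, res$pdrs)
  utils::write.csv(as.data.frame(offsets), p("par_pdr_offsets.csv"),
                   row.names = FALSE)

  comparison <- NULL
  if (compare_with_nominal) {
    nom_cfg <- config
    nom_cfg$scenario <- "nominal"
    nom_cfg$phantom$shifter_wet_mm <- 0
    nom <- .run_one_scenario(nom_cfg)
    ids <- intersect(names(nom$analysis$fits), names(res$analysis$fits))
    shifts <- lapply(ids, function(id) {
      par_shift(nom$analysis$fits[[id]], res$analysis$fits[[id]])
    })
    names(shifts) <- ids
    agg <- aggregate_shifts(shifts)
    pdr_shift <- vapply(ids, function(id) {
      nom$pdrs[[id]]$PDR_mm - res$pdrs[[id]]$PDR_mm
    }, numeric(1))
    comparison <- tibble::tibble(
      spot_id = c(ids, "aggregate"),
      par_shift_mm = c(vapply(shifts, `[[`, numeric(1), "shift_mm"),
                       agg$shift_mm),
      sigma_mm = c(vapply(shifts, `[[`, numeric(1), "sigma_mm"),
                   agg$sigma_mm),
      pdr_shift_mm = c(pdr_shift, mean(pdr_shift))
    )
    utils::write.csv(as.data.frame(comparison), p("comparison.csv"),
                     row.names = FALSE)
  }

  files <- c("delivery_log.csv", "listmode.csv", "intervals.csv",
             "fits.csv", "predictions.csv", "par_pdr_offsets.csv",
             if (!is.null(comparison)) "comparison.csv")
  manifest <- list(
    package = "spotpet",
    version = as.character(utils::packageVersion("spotpet")),
    seed = config$seed,
    scenario = config$scenario,
    shifter_wet_mm = config$shifter_wet_mm,
    pixel_mm = config$pixel_mm,
    fit_range_mm = config$fit_range,
    artifacts = lapply(files, function(f) {
      list(file = f, md5 = unname(tools::md5sum(p(f))))
    })
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(result = res, comparison = comparison,
                 manifest = manifest, out_dir = out_dir))
}
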