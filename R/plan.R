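#' Pencil-beam-scanning irradiation plan
#'
#' A plan is an ordered set of energy layers, each an ordered set of beam
#' spots, delivered in order of strictly decreasing energy.  Between spots of
#' one layer the beam pauses for `inter_spot_gap_ms` (the window in which the
#' per-spot PET data are acquired); switching layers takes
#' `layer_switch_gap_ms[1]`-`layer_switch_gap_ms[2]` of beam-off time.
#'
#' @param layers List of layers; each layer is a list with `energy_mev`
#'   (scalar), `n_protons` (vector, one per spot) and optionally
#'   `lateral_x_mm` (vector, defaults to 0).
#' @param inter_spot_gap_ms Beam-off pause inserted after every spot (ms).
#' @param layer_switch_gap_ms Length-2 range for the layer-switch beam-off
#'   period (ms).
#' @param pre_beam_s Beam-free acquisition time before the first spot (s).
#' @param spot_duration_range_ms Length-2 range from which actual spot
#'   durations are sampled at delivery time (ms).
#' @return An `irradiation_plan`: a data frame of spots (columns
#'   `spot_id`, `layer_index`, `spot_index`, `energy_mev`, `n_protons`,
#'   `lateral_x_mm`) with the timing settings stored as attributes.
#' @export
irradiation_plan <- function(layers,
                             inter_spot_gap_ms = 60,
                             layer_switch_gap_ms = c(700, 800),
                             pre_beam_s = 60,
                             spot_duration_range_ms = c(10, 25)) {
  stopifnot(length(layers) >= 1, inter_spot_gap_ms > 0,
            length(layer_switch_gap_ms) == 2,
            all(layer_switch_gap_ms > 0), pre_beam_s >= 0,
            length(spot_duration_range_ms) == 2,
            all(spot_duration_range_ms > 0))
  energies <- vapply(layers, `[[`, numeric(1), "energy_mev")
  if (any(diff(energies) >= 0)) {
    stop("layer energies must be strictly decreasing in delivery order")
  }
  rows <- lapply(seq_along(layers), function(li) {
    lay <- layers[[li]]
    np <- lay$n_protons
    if (any(np <= 0)) stop("n_protons must be > 0")
    x <- lay$lateral_x_mm
    if (is.null(x)) x <- rep(0, length(np))
    stopifnot(length(x) == length(np))
    data.frame(
      spot_id = sprintf("%02d/%02d", li, seq_along(np)),
      layer_index = li,
      spot_index = seq_along(np),
      energy_mev = lay$energy_mev,
      n_protons = np,
      lateral_x_mm = x,
      stringsAsFactors = FALSE
    )
  })
  plan <- do.call(rbind, rows)
  if (anyDuplicated(plan$spot_id)) stop("spot_id values must be unique")
  structure(plan,
            inter_spot_gap_ms = inter_spot_gap_ms,
            layer_switch_gap_ms = layer_switch_gap_ms,
            pre_beam_s = pre_beam_s,
            spot_duration_range_ms = spot_duration_range_ms,
            class = c("irradiation_plan", "data.frame"))
}

#' Two-layer head-like plan
#'
#' The default synthetic study condition: the first two energy layers of a
#' head irradiation -- one 146.5 MeV spot of 5.28e8 protons followed by a
#' seven-spot 143.5 MeV layer with 2.8-5.2e8 protons per spot on an 8-mm
#' lateral raster.  These layers carry the most protons and define the distal
#' edge, which is what spot-by-spot 12N imaging verifies.
#'
#' @param pre_beam_s Beam-free acquisition time before the first spot (s).
#' @return An [irradiation_plan()].
#' @export
head_like_plan <- function(pre_beam_s = 60) {
  irradiation_plan(
    layers = list(
      list(energy_mev = 146.5, n_protons = 5.28e8, lateral_x_mm = 0),
      list(energy_mev = 143.5,
           n_protons = c(5.2, 4.8, 4.4, 4.0, 3.6, 3.2, 2.8) * 1e8,
           lateral_x_mm = seq(-24, 24, by = 8))
    ),
    pre_beam_s = pre_beam_s
  )
}

#' Single-spot plan
#'
#' One head-like beam spot, used for per-spot precision studies.
#'
#' @param energy_mev Beam energy (MeV).
#' @param n_protons Protons in the spot.
#' @param pre_beam_s Beam-free acquisition time before the spot (s).
#' @return An [irradiation_plan()] with a single layer and spot.
#' @export
single_spot_plan <- function(energy_mev = 146.5, n_protons = 5.28e8,
                             pre_beam_s = 60) {
  irradiation_plan(
    layers = list(list(energy_mev = energy_mev, n_protons = n_protons,
                       lateral_x_mm = 0)),
    pre_beam_s = pre_beam_s
  )
}

#' Phantom model
#'
#' Uniform water-equivalent phantom along the beam axis, optionally with an
#' upstream range shifter expressed as water-equivalent thickness (WET).
#'
#' @param entry_z_mm Beam entry position on the z axis (mm; z = 0 is the
#'   plan isocenter).
#' @param density_gcm3 Uniform density (g/cm^3, > 0).
#' @param shifter_wet_mm Water-equivalent thickness added upstream (mm, >= 0).
#' @return A `phantom_model`.
#' @export
phantom_model <- function(entry_z_mm = -85.2, density_gcm3 = 1.0,
                          shifter_wet_mm = 0) {
  stopifnot(density_gcm3 > 0, shifter_wet_mm >= 0)
  structure(list(entry_z_mm = entry_z_mm, density_gcm3 = density_gcm3,
                 shifter_wet_mm = shifter_wet_mm),
            class = "phantom_model")
}

#' Dual-panel PET geometry
#'
#' Two parallel rectangular panels in the x-z plane at y = +/- separation/2,
#' with the beam along +z.  The reconstruction plane (y = 0 by default) lies
#' midway between them.
#'
#' @param panel_separation_mm Center-to-center panel distance (mm, > 0).
#' @param panel_half_width_x_mm Panel half-size along x (mm).
#' @param panel_half_length_z_mm Panel half-size along z (mm).
#' @param panel_center_z_mm Panel center position along z (mm).
#' @param detection_efficiency_per_photon Probability that a photon
#'   geometrically hitting a panel is detected, in [0, 1].  Absorbs the
#'   energy window and intrinsic crystal efficiency; 0 yields an empty
#'   stream.
#' @return A `panel_geometry`.
#' @export
panel_geometry <- function(panel_separation_mm = 400,
                           panel_half_width_x_mm = 110,
                           panel_half_length_z_mm = 240,
                           panel_center_z_mm = 0,
                           detection_efficiency_per_photon = 0.30) {
  stopifnot(panel_separation_mm > 0,
            detection_efficiency_per_photon >= 0,
            detection_efficiency_per_photon <= 1)
  if (panel_half_width_x_mm <= 0 || panel_half_length_z_mm <= 0) {
    stop("panel half-sizes must be > 0 (zero geometric acceptance)")
  }
  structure(list(panel_separation_mm = panel_separation_mm,
                 panel_half_width_x_mm = panel_half_width_x_mm,
                 panel_half_length_z_mm = panel_half_length_z_mm,
                 panel_center_z_mm = panel_center_z_mm,
                 detection_efficiency_per_photon =
                   detection_efficiency_per_photon),
            class = "panel_geometry")
}

#' List-mode acquisition settings
#'
#' @param window_after_spot_ms Duration of the per-spot analysis window that
#'   opens when a spot ends (ms); must not exceed the inter-spot gap.
#' @param timestamp_resolution_ms Coincidence time-stamp resolution (ms).
#' @param log_resolution_us Delivery-log time resolution (microseconds).
#' @param saturation_model `"hard_off"` (no events recorded while the beam is
#'   on) or `"fractional"` (count rate reduced to `saturation_fraction`).
#' @param saturation_fraction Fraction of events kept during beam-on under
#'   the fractional model.
#' @param post_beam_s Acquisition time kept after the last spot (s).
#' @return An `acquisition_config`.
#' @export
acquisition_config <- function(window_after_spot_ms = 60,
                               timestamp_resolution_ms = 1,
                               log_resolution_us = 200,
                               saturation_model = c("hard_off", "fractional"),
                               saturation_fraction = 0.05,
                               post_beam_s = 0.25) {
  saturation_model <- match.arg(saturation_model)
  stopifnot(window_after_spot_ms > 0, timestamp_resolution_ms > 0,
            log_resolution_us > 0, post_beam_s >= 0,
            saturation_fraction >= 0, saturation_fraction <= 1)
  structure(list(window_after_spot_ms = window_after_spot_ms,
                 timestamp_resolution_ms = timestamp_resolution_ms,
                 log_resolution_us = log_resolution_us,
                 saturation_model = saturation_model,
                 saturation_fraction = saturation_fraction,
                 post_beam_s = post_beam_s),
            class = "acquisition_config")
}

#' Isotope production and positron-range model
#'
#' Per-isotope effective production thresholds and flat-above-threshold
#' production rates (emitters per proton per water-equivalent mm), the
#' lateral beam sigma, and the shape of the annihilation-position blur.
#'
#' The annihilation-distance blur along z and x is a two-component mixture
#' whose overall 1D RMS equals the isotope's `positron_range_rms_gcm2`: a
#' narrow logistic-shaped core (weight `blur_core_fraction`, RMS
#' `blur_core_rms_gcm2`) plus a broad Gaussian tail that carries the rest of
#' the RMS.  This mimics the cusp-like annihilation-distance distribution of
#' a high-endpoint beta spectrum: most positrons stop within a few mm while
#' a small fraction travels several cm, which is what gives 12N its large
#' (1.8 g/cm^2) projected RMS.
#'
#' Default production rates are calibrated so that a head-like 146.5 MeV spot
#' of 5.28e8 protons yields on the order of 900 coincidences in the 60-ms
#' post-spot window, with 15O/11C production rates 20x that of 12N.
#' 10C and 8B are available as optional background emitters (excluded from
#' prediction) and are disabled by default.
#'
#' @param n12_q,o15_q,c11_q,c10_q,b8_q Production rates per proton per mm.
#' @param n12_threshold_mev,o15_threshold_mev,c11_threshold_mev,
#'   c10_threshold_mev,b8_threshold_mev Effective production thresholds (MeV).
#' @param include_c10,include_b8 Enable the optional background emitters.
#' @param lateral_sigma_mm Gaussian beam sigma in x and y (mm).
#' @param blur_core_fraction Mixture weight of the narrow blur core.
#' @param blur_core_rms_gcm2 RMS of the narrow core (g/cm^2).
#' @param random_background_cps Uniform random-coincidence background rate
#'   (counts/s) spread over the whole acquisition; 0 disables it.
#' @return A `production_model`.
#' @export
production_model <- function(n12_q = 1.05e-6,
                             o15_q = 20 * 1.05e-6,
                             c11_q = 20 * 1.05e-6,
                             c10_q = 0.4e-6,
                             b8_q = 2e-6,
                             n12_threshold_mev = 20,
                             o15_threshold_mev = 16.6,
                             c11_threshold_mev = 20,
                             c10_threshold_mev = 20,
                             b8_threshold_mev = 25,
                             include_c10 = FALSE,
                             include_b8 = FALSE,
                             lateral_sigma_mm = 4,
                             blur_core_fraction = 0.95,
                             blur_core_rms_gcm2 = 0.4,
                             random_background_cps = 0) {
  stopifnot(blur_core_fraction >= 0, blur_core_fraction <= 1,
            blur_core_rms_gcm2 >= 0, lateral_sigma_mm > 0,
            random_background_cps >= 0)
  structure(list(
    isotopes = list(
      "N-12" = list(q_per_proton_mm = n12_q,
                    threshold_mev = n12_threshold_mev, include = TRUE),
      "O-15" = list(q_per_proton_mm = o15_q,
                    threshold_mev = o15_threshold_mev, include = TRUE),
      "C-11" = list(q_per_proton_mm = c11_q,
                    threshold_mev = c11_threshold_mev, include = TRUE),
      "C-10" = list(q_per_proton_mm = c10_q,
                    threshold_mev = c10_threshold_mev, include = include_c10),
      "B-8"  = list(q_per_proton_mm = b8_q,
                    threshold_mev = b8_threshold_mev, include = include_b8)
    ),
    lateral_sigma_mm = lateral_sigma_mm,
    blur_core_fraction = blur_core_fraction,
    blur_core_rms_gcm2 = blur_core_rms_gcm2,
    random_background_cps = random_background_cps
  ), class = "production_model")
}

# mixture blur parameters (in mm) for one isotope in a given medium:
# logistic core (scale = RMS * sqrt(3)/pi) plus broad Gaussian tail
.blur_params <- function(iso, production, density_gcm3) {
  rms_mm <- iso$positron_range_rms_gcm2 / density_gcm3 * 10
  core_mm <- production$blur_core_rms_gcm2 / density_gcm3 * 10
  w <- production$blur_core_fraction
  if (rms_mm <= 0) {
    return(list(w = 1, core_rms = 0, core_scale = 0, sigma_broad = 0))
  }
  if (core_mm >= rms_mm || w >= 1) {
    return(list(w = 1, core_rms = rms_mm,
                core_scale = rms_mm * sqrt(3) / pi, sigma_broad = 0))
  }
  broad2 <- (rms_mm^2 - w * core_mm^2) / (1 - w)
  list(w = w, core_rms = core_mm, core_scale = core_mm * sqrt(3) / pi,
       sigma_broad = sqrt(broad2))
}
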