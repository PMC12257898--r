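#' Proton range in water from a range-energy power law
#'
#' Bragg-Kleeman style parametrisation `R = alpha * E^p` used by the synthetic
#' beam model.  With the defaults a 146.5 MeV beam has a range of about
#' 150 mm of water.
#'
#' @param energy_mev Proton energy in MeV, within [1, 250].
#' @param alpha,p Power-law coefficients (mm and dimensionless).
#' @return Range in mm of water (vectorised, monotone increasing in energy).
#' @export
proton_range_water <- function(energy_mev, alpha = 0.022, p = 1.77) {
  if (!is.numeric(energy_mev) || any(!is.finite(energy_mev)) ||
      any(energy_mev < 1) || any(energy_mev > 250)) {
    stop("`energy_mev` must lie in [1, 250]")
  }
  alpha * energy_mev^p
}

# residual-range bookkeeping for a spot in a (possibly shifted) phantom:
# water-equivalent ranges are converted to geometric depth via the uniform
# phantom density.
.beam_depths <- function(energy_mev, phantom, threshold_mev = NULL,
                         alpha = 0.022, p = 1.77) {
  r_wet <- proton_range_water(energy_mev, alpha, p) - phantom$shifter_wet_mm
  rho <- phantom$density_gcm3
  out <- list(
    z_entry = phantom$entry_z_mm,
    z_range = phantom$entry_z_mm + r_wet / rho,
    residual_wet_mm = r_wet
  )
  if (!is.null(threshold_mev)) {
    cut_wet <- r_wet - proton_range_water(threshold_mev, alpha, p)
    out$z_cutoff <- phantom$entry_z_mm + cut_wet / rho
    out$production_wet_mm <- cut_wet
  }
  out
}

#' Per-spot isotope production image
#'
#' Expected positron-emitter creation density per proton on a 2D (x, z) grid.
#' The depth profile is flat (in water-equivalent depth) from the phantom
#' entry down to the depth at which the residual proton energy reaches the
#' reaction threshold, i.e. strictly proximal to the proton range; the lateral
#' profile is Gaussian around the spot position.  The image contains emitter
#' creation positions only: no positron-range blur is applied here.
#'
#' @param spot One-row data frame (or list) with `energy_mev` and
#'   `lateral_x_mm` (as in an [irradiation_plan()] spot table).
#' @param phantom A [phantom_model()].
#' @param isotope_name Isotope label (bookkeeping only).
#' @param threshold_mev Effective production threshold energy in MeV; must be
#'   below the beam energy, otherwise an all-zero image is returned with a
#'   warning.
#' @param grid Image grid from [recon_grid()] (or any list with `x_edges`,
#'   `z_edges` in mm).
#' @param q_per_proton_mm Emitters created per proton per mm of
#'   water-equivalent path above threshold.
#' @param lateral_sigma_mm Gaussian beam sigma in x (mm).
#' @return A `production_image`: list with `isotope`, `x_edges`, `z_edges`,
#'   `yield_density` (matrix, rows = x bins, cols = z bins, expected emitters
#'   per proton per bin) and `z_cutoff_mm`.
#' @export
production_depth_profile <- function(spot, phantom, isotope_name,
                                     threshold_mev, grid,
                                     q_per_proton_mm = 1e-6,
                                     lateral_sigma_mm = 4) {
  spot <- as.list(spot)
  nx <- length(grid$x_edges) - 1L
  nz <- length(grid$z_edges) - 1L
  img <- structure(
    list(isotope = isotope_name, x_edges = grid$x_edges,
         z_edges = grid$z_edges,
         yield_density = matrix(0, nrow = nx, ncol = nz),
         z_cutoff_mm = NA_real_),
    class = "production_image"
  )
  if (threshold_mev >= spot$energy_mev) {
    warning("production threshold at or above beam energy: empty image")
    return(img)
  }
  d <- .beam_depths(spot$energy_mev, phantom, threshold_mev)
  if (d$production_wet_mm <= 0) {
    warning("no residual range above threshold inside the phantom: empty image")
    return(img)
  }
  # per-bin overlap with [z_entry, z_cutoff], flat density per geometric mm
  q_geo <- q_per_proton_mm * phantom$density_gcm3
  lo <- pmax(grid$z_edges[-(nz + 1L)], d$z_entry)
  hi <- pmin(grid$z_edges[-1L], d$z_cutoff)
  z_w <- pmax(hi - lo, 0) * q_geo
  x_w <- diff(stats::pnorm(grid$x_edges, mean = spot$lateral_x_mm,
                           sd = lateral_sigma_mm))
  img$yield_density <- outer(x_w, z_w)
  img$z_cutoff_mm <- d$z_cutoff
  img
}

#' Synthetic longitudinal depth-dose curve
#'
#' Analytic Bragg-curve stand-in: a slowly rising plateau with a smooth distal
#' cutoff plus a Gaussian-smeared peak (sigma `peak_sigma_mm`) at the proton
#' range.  Adding water-equivalent material upstream (`phantom$shifter_wet_mm`)
#' translates the whole curve proximally by exactly that amount, which makes
#' the injected range shift of a scenario exact by construction.
#'
#' @param spot One-row spot record with `energy_mev`.
#' @param phantom A [phantom_model()].
#' @param dz_mm Sampling step in mm.
#' @param peak_sigma_mm Gaussian smearing of the Bragg peak in mm.
#' @return A data frame with columns `z_mm` and `dose` (arbitrary units).
#' @export
depth_dose_profile <- function(spot, phantom, dz_mm = 0.1, peak_sigma_mm = 3) {
  spot <- as.list(spot)
  d <- .beam_depths(spot$energy_mev, phantom)
  z <- seq(d$z_entry - 5, d$z_range + 8 * peak_sigma_mm, by = dz_mm)
  # plateau ramp referenced to the full (unshifted) range so that upstream
  # material translates the whole curve rigidly, as it does physically
  l_full <- proton_range_water(spot$energy_mev) / phantom$density_gcm3
  xi <- pmin(pmax(1 + (z - d$z_range) / l_full, 0), 1)
  plateau <- 0.35 * (1 + 0.8 * xi) *
    stats::pnorm(d$z_range, mean = z, sd = peak_sigma_mm)
  peak <- exp(-(z - d$z_range)^2 / (2 * peak_sigma_mm^2))
  data.frame(z_mm = z, dose = plateau + peak)
}
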