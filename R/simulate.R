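#' Simulate a pencil-beam-scanning delivery log
#'
#' Spot durations are drawn uniformly from the plan's
#' `spot_duration_range_ms`; spots within a layer are separated by the fixed
#' inter-spot gap and layers by a beam-off period drawn uniformly from the
#' layer-switch range.  All times are quantized to the delivery-log
#' resolution (200 us by default).
#'
#' @param plan An [irradiation_plan()].
#' @param seed Integer seed; the log is fully reproducible given the seed.
#' @param log_resolution_us Log time resolution in microseconds.
#' @return A `delivery_log`: tibble with `spot_id`, `layer_index`,
#'   `energy_mev`, `n_protons`, `t_start_us`, `t_end_us`.
#' @export
simulate_delivery <- function(plan, seed, log_resolution_us = 200) {
  if (missing(seed)) stop("`seed` is required")
  withr::local_seed(seed)
  .sample_delivery(plan, log_resolution_us)
}

.sample_delivery <- function(plan, log_resolution_us = 200) {
  spots <- as.data.frame(plan)
  n <- nrow(spots)
  gap_us <- attr(plan, "inter_spot_gap_ms") * 1000
  switch_range_us <- attr(plan, "layer_switch_gap_ms") * 1000
  dur_range_us <- attr(plan, "spot_duration_range_ms") * 1000
  q <- function(x) round(x / log_resolution_us) * log_resolution_us

  durations <- q(stats::runif(n, dur_range_us[1], dur_range_us[2]))
  t_start <- numeric(n)
  t_end <- numeric(n)
  cursor <- q(attr(plan, "pre_beam_s") * 1e6)
  for (i in seq_len(n)) {
    t_start[i] <- cursor
    t_end[i] <- cursor + durations[i]
    if (i < n) {
      gap <- if (spots$layer_index[i + 1L] != spots$layer_index[i]) {
        q(stats::runif(1, switch_range_us[1], switch_range_us[2]))
      } else {
        gap_us
      }
      cursor <- t_end[i] + gap
    }
  }
  out <- tibble::tibble(
    spot_id = spots$spot_id,
    layer_index = spots$layer_index,
    energy_mev = spots$energy_mev,
    n_protons = spots$n_protons,
    t_start_us = t_start,
    t_end_us = t_end
  )
  class(out) <- c("delivery_log", class(out))
  out
}

# creation times of nuclei that decay before t_max: density on [t_s, t_e]
# proportional to 1 - exp(-lambda (t_max - t)), sampled by rejection against
# a uniform envelope.
.sample_creation_times <- function(n, t_s, t_e, lambda, t_max) {
  if (n == 0L) return(numeric(0))
  p_max <- -expm1(-lambda * (t_max - t_s))
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.3) + 8L
    cand <- stats::runif(m, t_s, t_e)
    acc <- stats::runif(m) < -expm1(-lambda * (t_max - cand)) / p_max
    out <- c(out, cand[acc])
  }
  out[seq_len(n)]
}

# positron annihilation-distance blur: logistic core + broad Gaussian tail,
# one independent draw per axis per emitter.
.rpositron <- function(n, blur) {
  if (n == 0L) return(numeric(0))
  if (blur$core_rms <= 0 && blur$sigma_broad <= 0) return(numeric(n))
  core <- stats::runif(n) < blur$w
  out <- numeric(n)
  out[core] <- stats::rlogis(sum(core), 0, blur$core_scale)
  out[!core] <- stats::rnorm(sum(!core), 0, blur$sigma_broad)
  out
}

#' Simulate a per-spot list-mode PET acquisition
#'
#' End-to-end synthetic stand-in for accelerator, phantom, particle transport
#' and PET detection.  For each spot and isotope the expected number of
#' created emitters follows the flat-above-threshold production model;
#' creation times are uniform within the spot, decay times exponential,
#' annihilation positions are the creation positions blurred along z and x by
#' the isotope's positron-range mixture kernel, and each decay emits a
#' back-to-back photon pair in an isotropic random direction.  An event is
#' recorded when both photons geometrically intersect opposite panels and
#' both pass the per-photon detection efficiency.  Decays during beam-on are
#' suppressed according to the saturation model (no events at all under
#' `"hard_off"`).  Long-lived emitters persist across spots and layers, so
#' later windows contain growing 15O/11C background.  Event times are
#' quantized to the time-stamp resolution (1 ms by default).
#'
#' Emitters are sampled with an exact decay-time-truncation scheme: only
#' nuclei that decay before the end of the acquisition are drawn, which makes
#' the cost proportional to the number of decays rather than to the (much
#' larger) number of long-lived nuclei created.
#'
#' @param plan An [irradiation_plan()].
#' @param phantom A [phantom_model()].
#' @param geometry A [panel_geometry()].
#' @param acquisition An [acquisition_config()].
#' @param production A [production_model()].
#' @param isotopes An isotope table from [default_isotope_table()].
#' @param seed Integer seed (mandatory).
#' @param include_truth_images If `TRUE`, attach per-spot per-isotope
#'   [production_depth_profile()] images as ground truth.
#' @param grid Image grid used for the ground-truth production images.
#' @return A `listmode_sim`: list with `stream` (a `listmode_stream`: events
#'   tibble `t_ms, x1_mm, y1_mm, z1_mm, x2_mm, y2_mm, z2_mm`, plus the total
#'   duration), `log` (the [simulate_delivery()] log) and `truth` (per-spot
#'   production images and event origins).
#' @export
simulate_listmode <- function(plan,
                              phantom = phantom_model(),
                              geometry = panel_geometry(),
                              acquisition = acquisition_config(),
                              production = production_model(),
                              isotopes = default_isotope_table(),
                              seed,
                              include_truth_images = TRUE,
                              grid = recon_grid(geometry)) {
  if (missing(seed)) stop("`seed` is required for reproducibility")
  if (acquisition$window_after_spot_ms > attr(plan, "inter_spot_gap_ms")) {
    stop("analysis window exceeds the inter-spot gap")
  }
  withr::local_seed(seed)
  log <- .sample_delivery(plan, acquisition$log_resolution_us)
  spots <- as.data.frame(log)
  spots$lateral_x_mm <- as.data.frame(plan)$lateral_x_mm[
    match(spots$spot_id, plan$spot_id)]
  t_end_s <- max(spots$t_end_us) / 1e6 + acquisition$post_beam_s
  sat_bounds <- as.vector(rbind(spots$t_start_us, spots$t_end_us)) / 1e6
  half_sep <- geometry$panel_separation_mm / 2
  hw <- geometry$panel_half_width_x_mm
  hl <- geometry$panel_half_length_z_mm
  zc_panel <- geometry$panel_center_z_mm
  eff <- geometry$detection_efficiency_per_photon
  res_ms <- acquisition$timestamp_resolution_ms

  ev <- list()
  origins <- list()
  n_decays <- 0L
  n_geom_rejected <- 0L

  for (iso_name in names(production$isotopes)) {
    cfg <- production$isotopes[[iso_name]]
    if (!isTRUE(cfg$include)) next
    iso <- .get_isotope(isotopes, iso_name)
    lam <- decay_constant(iso$half_life_s)
    blur <- .blur_params(iso, production, phantom$density_gcm3)

    for (k in seq_len(nrow(spots))) {
      sp <- spots[k, ]
      if (cfg$threshold_mev >= sp$energy_mev) next
      d <- .beam_depths(sp$energy_mev, phantom, cfg$threshold_mev)
      if (d$production_wet_mm <= 0) next
      n_expected <- sp$n_protons * cfg$q_per_proton_mm * d$production_wet_mm
      t_s <- sp$t_start_us / 1e6
      t_e <- sp$t_end_us / 1e6
      t0 <- t_e - t_s
      # mean survival-to-acquisition-end over uniform creation times
      e_term <- exp(-lam * (t_end_s - t_e)) * -expm1(-lam * t0) / (lam * t0)
      p_decay <- 1 - e_term
      n_dec <- stats::rpois(1, n_expected * p_decay)
      if (n_dec == 0L) next
      tc <- .sample_creation_times(n_dec, t_s, t_e, lam, t_end_s)
      p_i <- -expm1(-lam * (t_end_s - tc))
      td <- tc - log1p(-stats::runif(n_dec) * p_i) / lam
      # detector saturation while any beam spot is on
      idx <- findInterval(td, sat_bounds)
      on_beam <- idx %% 2L == 1L
      keep <- if (acquisition$saturation_model == "hard_off") {
        !on_beam
      } else {
        !on_beam | stats::runif(n_dec) < acquisition$saturation_fraction
      }
      td <- td[keep]
      n <- length(td)
      n_decays <- n_decays + n
      if (n == 0L) next
      # creation position, then annihilation blur along z and x
      z <- stats::runif(n, d$z_entry, d$z_cutoff) + .rpositron(n, blur)
      x <- stats::rnorm(n, sp$lateral_x_mm, production$lateral_sigma_mm) +
        .rpositron(n, blur)
      y <- stats::rnorm(n, 0, production$lateral_sigma_mm)
      # isotropic back-to-back photon pair
      uz <- stats::runif(n, -1, 1)
      ph <- stats::runif(n, 0, 2 * pi)
      s <- sqrt(1 - uz^2)
      dx <- s * cos(ph)
      dy <- s * sin(ph)
      tp <- (half_sep - y) / dy
      tm <- (-half_sep - y) / dy
      xp <- x + dx * tp
      zp <- z + uz * tp
      xm <- x + dx * tm
      zm <- z + uz * tm
      ok <- is.finite(tp) & is.finite(tm) &
        abs(xp) <= hw & abs(xm) <= hw &
        abs(zp - zc_panel) <= hl & abs(zm - zc_panel) <= hl
      n_geom_rejected <- n_geom_rejected + sum(!ok)
      ok <- ok & stats::runif(n) < eff & stats::runif(n) < eff
      if (!any(ok)) next
      ev[[length(ev) + 1L]] <- data.frame(
        t_ms = floor(td[ok] * 1000 / res_ms) * res_ms,
        x1_mm = xp[ok], y1_mm = half_sep, z1_mm = zp[ok],
        x2_mm = xm[ok], y2_mm = -half_sep, z2_mm = zm[ok]
      )
      origins[[length(origins) + 1L]] <- data.frame(
        isotope = iso_name, source_spot = sp$spot_id,
        t_ms = floor(td[ok] * 1000 / res_ms) * res_ms,
        stringsAsFactors = FALSE
      )
    }
  }

  # optional uniform random-coincidence background over the acquisition
  if (production$random_background_cps > 0) {
    nb <- stats::rpois(1, production$random_background_cps * t_end_s)
    if (nb > 0) {
      ev[[length(ev) + 1L]] <- data.frame(
        t_ms = floor(stats::runif(nb, 0, t_end_s) * 1000 / res_ms) * res_ms,
        x1_mm = stats::runif(nb, -hw, hw), y1_mm = half_sep,
        z1_mm = stats::runif(nb, zc_panel - hl, zc_panel + hl),
        x2_mm = stats::runif(nb, -hw, hw), y2_mm = -half_sep,
        z2_mm = stats::runif(nb, zc_panel - hl, zc_panel + hl)
      )
      origins[[length(origins) + 1L]] <- data.frame(
        isotope = "background", source_spot = NA_character_,
        t_ms = ev[[length(ev)]]$t_ms, stringsAsFactors = FALSE
      )
    }
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(t_ms = numeric(0), x1_mm = numeric(0), y1_mm = numeric(0),
               z1_mm = numeric(0), x2_mm = numeric(0), y2_mm = numeric(0),
               z2_mm = numeric(0))
  origin <- if (length(origins)) do.call(rbind, origins) else
    data.frame(isotope = character(0), source_spot = character(0),
               t_ms = numeric(0))
  ord <- order(events$t_ms)
  events <- tibble::as_tibble(events[ord, , drop = FALSE])
  origin <- origin[ord, , drop = FALSE]

  stream <- structure(
    list(events = events, total_duration_s = t_end_s,
         n_decays_beam_off = n_decays,
         n_geometry_rejected = n_geom_rejected),
    class = "listmode_stream"
  )

  truth <- list(log = log, event_origins = tibble::as_tibble(origin))
  if (include_truth_images) {
    truth$production_images <- lapply(seq_len(nrow(spots)), function(k) {
      sp <- spots[k, ]
      imgs <- list()
      for (iso_name in names(production$isotopes)) {
        cfg <- production$isotopes[[iso_name]]
        if (!isTRUE(cfg$include) || cfg$threshold_mev >= sp$energy_mev) next
        imgs[[iso_name]] <- production_depth_profile(
          list(energy_mev = sp$energy_mev, lateral_x_mm = sp$lateral_x_mm),
          phantom, iso_name, cfg$threshold_mev, grid,
          q_per_proton_mm = cfg$q_per_proton_mm,
          lateral_sigma_mm = production$lateral_sigma_mm
        )
      }
      imgs
    })
    names(truth$production_images) <- spots$spot_id
  }

  structure(list(stream = stream, log = log, truth = truth,
                 phantom = phantom, geometry = geometry,
                 acquisition = acquisition, production = production,
                 plan = plan, seed = seed),
            class = "listmode_sim")
}

#' @export
print.listmode_stream <- function(x, ...) {
  cat(sprintf("<listmode_stream> %d events over %.3f s\n",
              nrow(x$events), x$total_duration_s))
  invisible(x)
}

#' Read/write list-mode and delivery-log CSV files
#'
#' The list-mode CSV has one row per coincidence with columns
#' `t_ms, x1_mm, y1_mm, z1_mm, x2_mm, y2_mm, z2_mm`; the delivery-log CSV has
#' `spot_id, layer_index, energy_mev, n_protons, t_start_us, t_end_us`.
#'
#' @param stream A `listmode_stream`.
#' @param path File path.
#' @return Readers return the corresponding object.
#' @export
write_listmode_csv <- function(stream, path) {
  utils::write.csv(as.data.frame(stream$events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_listmode_csv
#' @param total_duration_s Acquisition length to attach when reading; by
#'   default the last event time rounded up to the next second.
#' @export
read_listmode_csv <- function(path, total_duration_s = NULL) {
  ev <- tibble::as_tibble(utils::read.csv(path))
  need <- c("t_ms", "x1_mm", "y1_mm", "z1_mm", "x2_mm", "y2_mm", "z2_mm")
  if (!all(need %in% names(ev))) {
    stop("list-mode CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(total_duration_s)) {
    total_duration_s <- if (nrow(ev)) ceiling(max(ev$t_ms) / 1000) else 0
  }
  structure(list(events = ev[need], total_duration_s = total_duration_s,
                 n_decays_beam_off = NA_integer_,
                 n_geometry_rejected = NA_integer_),
            class = "listmode_stream")
}

#' @rdname write_listmode_csv
#' @param log A `delivery_log`.
#' @export
write_delivery_log_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_listmode_csv
#' @export
read_delivery_log_csv <- function(path) {
  log <- tibble::as_tibble(utils::read.csv(path))
  need <- c("spot_id", "layer_index", "energy_mev", "n_protons",
            "t_start_us", "t_end_us")
  if (!all(need %in% names(log))) {
    stop("delivery-log CSV must have columns: ", paste(need, collapse = ", "))
  }
  log <- log[need]
  class(log) <- c("delivery_log", class(log))
  log
}
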