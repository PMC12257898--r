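#' Decay weight of the 12N image for one spot
#'
#' Expected number of 12N decays in the acquisition window that follows a
#' spot, per unit of the per-proton production image:
#' \deqn{N_p \frac{1 - e^{-\lambda t_0}}{t_0} \frac{1 - e^{-\lambda t_D}}{\lambda}}
#' with `t0` the spot duration from the delivery log and `tD` the window
#' length.  Because of the very short half-life, 12N created in one spot does
#' not contribute to later spots.  At `t0 = 0` the analytic limit
#' `Np (1 - exp(-lambda tD))` is used.
#'
#' @param n_protons Protons in the spot (> 0).
#' @param t0_s Spot duration in seconds (>= 0).
#' @param t_d_s Acquisition window in seconds (> 0).
#' @param lambda_per_s 12N decay constant in s^-1 (> 0).
#' @return Scalar multiplier for the per-proton 12N production image.
#' @export
n12_weight <- function(n_protons, t0_s, t_d_s, lambda_per_s) {
  stopifnot(n_protons > 0, t0_s >= 0, t_d_s > 0, lambda_per_s > 0)
  window_term <- -expm1(-lambda_per_s * t_d_s) / lambda_per_s
  spot_term <- if (t0_s == 0) lambda_per_s else -expm1(-lambda_per_s * t0_s) / t0_s
  n_protons * spot_term * window_term
}

#' Decay weights of a long-lived isotope image for one spot
#'
#' 15O and 11C created by every spot delivered so far keep decaying, so the
#' image predicted for the window after spot i sums contributions from all
#' spots j <= i, each weighted by
#' \deqn{N_{p,j}\,\lambda_X\,t_D\,e^{-\lambda_X (t_{e,i} - t_{e,j})}}
#' with `te` the spot end times from the delivery log (the linearised window
#' factor `lambda tD` is accurate because `lambda_X * tD` is tiny).
#'
#' @param log A [simulate_delivery()] log.
#' @param spot_id Target spot (window after this spot).
#' @param lambda_per_s Decay constant of the long-lived isotope (s^-1).
#' @param t_d_s Acquisition window in seconds.
#' @return Tibble with `source_spot_id` and `multiplier` for every spot
#'   j <= i in delivery order.
#' @export
long_lived_weight <- function(log, spot_id, lambda_per_s, t_d_s) {
  i <- match(spot_id, log$spot_id)
  if (is.na(i)) stop("spot_id not found in the delivery log: ", spot_id)
  te <- log$t_end_us / 1e6
  j <- seq_len(i)
  tibble::tibble(
    source_spot_id = log$spot_id[j],
    multiplier = log$n_protons[j] * lambda_per_s * t_d_s *
      exp(-lambda_per_s * (te[i] - te[j]))
  )
}

# discrete 1D mixture-Gaussian convolution matrix mapping source bins to
# destination bins (same edges); column sums <= 1, mass blurred outside the
# grid is lost, matching the finite field of view.
.blur_matrix <- function(edges, blur) {
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  n <- length(centers)
  if (blur$core_rms <= 0 && blur$sigma_broad <= 0) return(diag(n))
  pmix <- function(q, mu) {
    broad <- if (blur$sigma_broad > 0) {
      stats::pnorm(q, mu, blur$sigma_broad)
    } else {
      as.numeric(q >= mu)
    }
    blur$w * stats::plogis(q, mu, blur$core_scale) + (1 - blur$w) * broad
  }
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    K[, j] <- pmix(edges[-1], centers[j]) - pmix(edges[-length(edges)],
                                                 centers[j])
  }
  K
}

# apply the per-isotope annihilation blur to a production image (z and x)
.blur_image_matrix <- function(m, x_edges, z_edges, blur) {
  Kx <- .blur_matrix(x_edges, blur)
  Kz <- .blur_matrix(z_edges, blur)
  Kx %*% m %*% t(Kz)
}

# geometric pair-acceptance of the dual-panel system for an emitter on the
# mid-plane at (x, z): the line of response hits both panels when its
# direction falls in the solid angle of the effective rectangle with
# half-sizes (hw - |x|, hl - |z - zc|) at the panel distance; the analytic
# rectangle solid-angle formula then gives the acceptance.
.acceptance_map <- function(grid, geometry) {
  cx <- (grid$x_edges[-1] + grid$x_edges[-length(grid$x_edges)]) / 2
  cz <- (grid$z_edges[-1] + grid$z_edges[-length(grid$z_edges)]) / 2
  d <- geometry$panel_separation_mm / 2
  ax <- pmax(geometry$panel_half_width_x_mm - abs(cx), 0)
  bz <- pmax(geometry$panel_half_length_z_mm -
               abs(cz - geometry$panel_center_z_mm), 0)
  acc <- function(a, b) {
    (2 / pi) * atan(a * b / (d * sqrt(a^2 + b^2 + d^2)))
  }
  outer(ax, bz, acc)
}

#' Compose the total predicted image for one spot
#'
#' Pixelwise weighted sum of the per-isotope images with the overall
#' normalization `M`: `ITot = M * (I_N12 + I_C11 + I_O15)`.  When a measured
#' total count is supplied, `M` scales the prediction to match it exactly
#' (mirroring the unknown absolute normalization of externally produced
#' production maps); otherwise `M = 1`.
#'
#' @param images Named list (by isotope) of weighted image matrices on a
#'   common grid, or of `production_image`-like lists with `yield_density`.
#' @param measured_total_counts Optional measured total to normalise to.
#' @param spot_id Optional label carried through to the result.
#' @return A `spot_prediction`: list with `spot_id`, `images` (per isotope),
#'   `total` (matrix), `M`, `fractions` (per-isotope share of the predicted
#'   counts) and `flags`.
#' @export
compose_total_image <- function(images, measured_total_counts = NULL,
                                spot_id = NA_character_) {
  mats <- lapply(images, function(im) {
    if (is.matrix(im)) im else im$yield_density
  })
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1L) {
    stop("per-isotope images are not on a common grid: ",
         paste(unique(dims), collapse = " vs "))
  }
  unnorm <- Reduce(`+`, mats)
  tot_unnorm <- sum(unnorm)
  flags <- character(0)
  if (tot_unnorm <= 0) {
    flags <- "zero_prediction"
    m_const <- NA_real_
  } else if (!is.null(measured_total_counts)) {
    m_const <- measured_total_counts / tot_unnorm
  } else {
    m_const <- 1
  }
  per_iso <- vapply(mats, sum, numeric(1))
  structure(list(
    spot_id = spot_id,
    images = mats,
    total = if (is.na(m_const)) unnorm else m_const * unnorm,
    M = m_const,
    fractions = if (tot_unnorm > 0) per_iso / tot_unnorm else
      rep(NA_real_, length(per_iso)),
    flags = flags),
    class = "spot_prediction")
}

#' Predict the per-spot PET image from production maps and the delivery log
#'
#' Applies the 12N spot weighting and the cross-spot long-lived weighting to
#' the per-proton production images of every isotope, blurs each isotope
#' image with its annihilation-distance kernel, and composes the total
#' predicted image.  10C and 8B are never included in the prediction, even
#' when enabled as generator background.
#'
#' @param sim A `listmode_sim` (uses its ground-truth production images and
#'   log), or a list with elements `truth$production_images`, `log`,
#'   `acquisition`, `production`, `phantom`.
#' @param spot_id Spot to predict.
#' @param measured_total_counts Optional measured window total for the `M`
#'   normalization.
#' @param isotopes Isotope table.
#' @param blur Apply the positron-range blur (TRUE for comparison with
#'   reconstructed images).
#' @param detector_response Weight the predicted images by the geometric
#'   pair acceptance of the panels, mirroring the sensitivity profile baked
#'   into the uncorrected measured images.
#' @return A `spot_prediction` (see [compose_total_image()]).
#' @export
predict_spot_image <- function(sim, spot_id, measured_total_counts = NULL,
                               isotopes = default_isotope_table(),
                               blur = TRUE, detector_response = TRUE) {
  imgs <- sim$truth$production_images
  if (is.null(imgs)) stop("simulation carries no ground-truth images")
  log <- sim$log
  i <- match(spot_id, log$spot_id)
  if (is.na(i)) stop("spot_id not found in the delivery log: ", spot_id)
  t_d <- sim$acquisition$window_after_spot_ms / 1000
  predicted <- list()
  for (iso_name in c("N-12", "O-15", "C-11")) {
    if (is.null(imgs[[spot_id]][[iso_name]])) next
    iso <- .get_isotope(isotopes, iso_name)
    lam <- decay_constant(iso$half_life_s)
    if (iso_name == "N-12") {
      t0 <- (log$t_end_us[i] - log$t_start_us[i]) / 1e6
      w <- n12_weight(log$n_protons[i], t0, t_d, lam)
      acc <- w * imgs[[spot_id]][[iso_name]]$yield_density / log$n_protons[i]
    } else {
      ws <- long_lived_weight(log, spot_id, lam, t_d)
      acc <- 0
      for (j in seq_len(nrow(ws))) {
        src <- imgs[[ws$source_spot_id[j]]][[iso_name]]
        if (is.null(src)) next
        acc <- acc + ws$multiplier[j] * src$yield_density /
          log$n_protons[match(ws$source_spot_id[j], log$spot_id)]
      }
      if (identical(acc, 0)) next
    }
    ref <- imgs[[spot_id]][[iso_name]]
    if (blur) {
      bl <- .blur_params(iso, sim$production, sim$phantom$density_gcm3)
      acc <- .blur_image_matrix(acc, ref$x_edges, ref$z_edges, bl)
    }
    if (detector_response) {
      acc <- acc * .acceptance_map(list(x_edges = ref$x_edges,
                                        z_edges = ref$z_edges),
                                   sim$geometry)
    }
    predicted[[iso_name]] <- acc
  }
  compose_total_image(predicted, measured_total_counts, spot_id)
}

#' Longitudinal profile of a predicted image
#'
#' @param prediction A `spot_prediction`.
#' @param z_edges z bin edges of the underlying grid (mm).
#' @return An `activity_profile` tibble (`sigma` = sqrt of predicted counts,
#'   floored at 1), suitable for [fit_sigmoid()].
#' @export
prediction_profile <- function(prediction, z_edges) {
  counts <- colSums(prediction$total)
  z <- (z_edges[-1] + z_edges[-length(z_edges)]) / 2
  out <- tibble::tibble(z_mm = z, counts = counts,
                        sigma = sqrt(pmax(counts, 1)))
  class(out) <- c("activity_profile", class(out))
  out
}

#' Isotope share of the distal part of a predicted profile
#'
#' Fraction of the predicted counts contributed by one isotope within the
#' most distal portion of the longitudinal profile (the region that holds
#' `distal_fraction` of the total predicted counts, accumulated from the
#' distal end).
#'
#' @param prediction A `spot_prediction`.
#' @param isotope_name Isotope label, default `"N-12"`.
#' @param distal_fraction Fraction of the total counts defining the distal
#'   region (0.1 = distal 10%).
#' @return Scalar fraction in [0, 1].
#' @export
distal_isotope_fraction <- function(prediction, isotope_name = "N-12",
                                    distal_fraction = 0.1) {
  tot_z <- colSums(Reduce(`+`, prediction$images))
  iso_z <- colSums(prediction$images[[isotope_name]])
  total <- sum(tot_z)
  if (total <= 0) return(NA_real_)
  cum_back <- rev(cumsum(rev(tot_z)))
  zone <- cum_back <= distal_fraction * total
  if (!any(zone)) zone[length(zone)] <- TRUE
  sum(iso_z[zone]) / sum(tot_z[zone])
}

#' Per-spot prediction report
#'
#' @param predictions Named list of `spot_prediction` objects.
#' @return Tibble with per-isotope predicted counts, fractional
#'   contributions and the normalization constant `M` per spot.
#' @export
prediction_report <- function(predictions) {
  rows <- lapply(predictions, function(p) {
    cnt <- vapply(p$images, sum, numeric(1))
    get <- function(nm) if (nm %in% names(cnt)) unname(cnt[nm]) else 0
    getf <- function(nm) if (nm %in% names(p$fractions))
      unname(p$fractions[nm]) else 0
    tibble::tibble(
      spot_id = p$spot_id,
      counts_N12 = get("N-12"), counts_C11 = get("C-11"),
      counts_O15 = get("O-15"),
      frac_N12 = getf("N-12"), frac_C11 = getf("C-11"),
      frac_O15 = getf("O-15"),
      M = p$M)
  })
  do.call(rbind, rows)
}
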