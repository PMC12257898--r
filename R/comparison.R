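#' Proton dose range from a depth-dose profile
#'
#' The proton dose range (PDR) is the z position where the dose drops to 80%
#' of the profile maximum on the distal side, found by linear interpolation
#' between the two samples bracketing the crossing.
#'
#' @param dose_profile Data frame with `z_mm` and `dose`, e.g. from
#'   [depth_dose_profile()].
#' @param level Relative dose level defining the range (0.8 by default,
#'   relative to the profile maximum).
#' @param spot_id Optional label.
#' @return A `pdr_result`: list with `spot_id`, `PDR_mm`, `level` and
#'   `method`.
#' @export
pdr_from_dose <- function(dose_profile, level = 0.8,
                          spot_id = NA_character_) {
  z <- dose_profile$z_mm
  d <- dose_profile$dose
  imax <- which.max(d)
  target <- level * d[imax]
  distal_d <- d[imax:length(d)]
  distal_z <- z[imax:length(z)]
  below <- which(distal_d < target)
  if (!length(below)) stop("no distal crossing of the dose level")
  i <- below[1]
  if (i == 1) stop("profile maximum already below the dose level")
  z1 <- distal_z[i - 1]; z2 <- distal_z[i]
  d1 <- distal_d[i - 1]; d2 <- distal_d[i]
  pdr <- z1 + (target - d1) * (z2 - z1) / (d2 - d1)
  structure(list(spot_id = spot_id, PDR_mm = pdr, level = level,
                 method = "80% distal, linear interpolation"),
            class = "pdr_result")
}

#' Range shift between two sigmoid fits
#'
#' @param fit_a,fit_b `sigmoid_fit` objects (e.g. nominal and shifted
#'   scenario of the same spot).  The shift is `PAR_a - PAR_b` with the two
#'   fit uncertainties combined in quadrature.
#' @param quantity Label for the shifted quantity.
#' @return A `shift_result`: list with `quantity`, `shift_mm`, `sigma_mm`,
#'   `n_spots` and `flagged`.
#' @export
par_shift <- function(fit_a, fit_b, quantity = "PAR") {
  flagged <- !fit_a$converged || !fit_b$converged ||
    length(fit_a$flags) > 0 || length(fit_b$flags) > 0
  structure(list(
    quantity = quantity,
    shift_mm = fit_a$PAR - fit_b$PAR,
    sigma_mm = sqrt(unname(fit_a$se["PAR"])^2 + unname(fit_b$se["PAR"])^2),
    n_spots = 1L,
    flagged = flagged),
    class = "shift_result")
}

#' Aggregate per-spot range shifts
#'
#' Inverse-variance-weighted mean of several per-spot shifts; the combined
#' uncertainty is `(sum sigma_k^-2)^-1/2`, always smaller than the smallest
#' individual uncertainty.
#'
#' @param shifts List of `shift_result` objects (>= 2 unflagged).
#' @return A `shift_result` with `n_spots` the number of shifts combined.
#' @export
aggregate_shifts <- function(shifts) {
  if (!length(shifts)) stop("no shifts to aggregate")
  ok <- !vapply(shifts, `[[`, logical(1), "flagged")
  shifts <- shifts[ok]
  if (length(shifts) < 2) stop("need at least 2 converged shifts")
  s <- vapply(shifts, `[[`, numeric(1), "shift_mm")
  sig <- vapply(shifts, `[[`, numeric(1), "sigma_mm")
  w <- 1 / sig^2
  structure(list(
    quantity = shifts[[1]]$quantity,
    shift_mm = sum(w * s) / sum(w),
    sigma_mm = 1 / sqrt(sum(w)),
    n_spots = length(shifts),
    flagged = FALSE),
    class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("<shift_result> %s shift = %.2f +/- %.2f mm (n = %d)%s\n",
              x$quantity, x$shift_mm, x$sigma_mm, x$n_spots,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Per-spot activity-range vs dose-range offset table
#'
#' The measured positron activity range sits at a systematic offset from the
#' proton dose range (production thresholds cut the activity short of the
#' proton range, and the large 12N positron range broadens the fall-off).
#' This tabulates `offset = PAR - PDR` per spot with the mean and standard
#' deviation across spots.  Offsets more than 3 standard deviations from the
#' mean of the remaining spots (leave-one-out, so a single aberrant spot
#' cannot mask itself) are flagged as outliers but not excluded.
#' Non-converged fits enter the table with `NA` and are left out of the
#' summary.
#'
#' @param fits Named list of `sigmoid_fit` objects (names = spot ids).
#' @param pdrs Named list of `pdr_result` objects (same spot ids).
#' @param exclude Optional spot ids to leave out of the summary (e.g. a spot
#'   with a suspected systematic error).
#' @return Tibble with `spot_id`, `PAR_mm`, `sigma_PAR_mm`, `PDR_mm`,
#'   `offset_mm`, `outlier`; the mean and sd over the non-excluded spots are
#'   attached as attributes `mean_offset_mm` / `sd_offset_mm`.
#' @export
par_pdr_offset_table <- function(fits, pdrs, exclude = character(0)) {
  ids <- names(fits)
  missing_ids <- setdiff(ids, names(pdrs))
  extra_ids <- setdiff(names(pdrs), ids)
  if (length(missing_ids) || length(extra_ids)) {
    stop("unmatched spot ids: ",
         paste(c(missing_ids, extra_ids), collapse = ", "))
  }
  tab <- tibble::tibble(
    spot_id = ids,
    PAR_mm = vapply(fits, `[[`, numeric(1), "PAR"),
    sigma_PAR_mm = vapply(fits, function(f) unname(f$se["PAR"]), numeric(1)),
    PDR_mm = vapply(pdrs[ids], `[[`, numeric(1), "PDR_mm")
  )
  tab$offset_mm <- tab$PAR_mm - tab$PDR_mm
  used <- !(tab$spot_id %in% exclude) & !is.na(tab$offset_mm)
  m <- mean(tab$offset_mm[used])
  s <- stats::sd(tab$offset_mm[used])
  tab$outlier <- vapply(seq_len(nrow(tab)), function(i) {
    rest <- used & seq_len(nrow(tab)) != i
    if (is.na(tab$offset_mm[i]) || sum(rest) < 2) return(FALSE)
    m_i <- mean(tab$offset_mm[rest])
    s_i <- stats::sd(tab$offset_mm[rest])
    is.finite(s_i) && s_i > 0 && abs(tab$offset_mm[i] - m_i) > 3 * s_i
  }, logical(1))
  attr(tab, "mean_offset_mm") <- m
  attr(tab, "sd_offset_mm") <- s
  attr(tab, "excluded") <- exclude
  tab
}
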