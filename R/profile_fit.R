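#' 1D longitudinal activity profile
#'
#' Projects a reconstructed 2D image along the lateral (x) direction, giving
#' counts per longitudinal pixel column with Poisson uncertainties.  Zero
#' count columns get a 1-count error floor so that weighted fits remain
#' defined.
#'
#' @param image An `image2d` from [reconstruct()].
#' @param sigma_floor Error floor for empty columns (counts).
#' @return An `activity_profile`: tibble with `z_mm` (bin centers), `counts`
#'   and `sigma`.
#' @export
longitudinal_profile <- function(image, sigma_floor = 1) {
  counts <- colSums(image$counts)
  z <- (image$z_edges[-1] + image$z_edges[-length(image$z_edges)]) / 2
  out <- tibble::tibble(z_mm = z, counts = counts,
                        sigma = sqrt(pmax(counts, sigma_floor)))
  class(out) <- c("activity_profile", class(out))
  out
}

#' Sigmoid fit of the distal activity fall-off
#'
#' Weighted least-squares fit of
#' \deqn{A(z) = A_0 / (1 + \exp((z - PAR)/r))}
#' to the longitudinal activity profile over `[z_start, z_end]`.  `PAR` is
#' the z position of the 50% distal fall-off of the positron activity; its
#' 1-sigma uncertainty is taken from the covariance reported by the fitting
#' algorithm.  Initial values: `A0` = mean of the proximal third of the
#' points in range, `PAR` = linearly interpolated 50% crossing, `r` = 2 mm.
#'
#' @param profile An [longitudinal_profile()] result (or any data frame with
#'   `z_mm`, `counts`, `sigma`).
#' @param z_start,z_end Fit range in mm.
#' @return A `sigmoid_fit`: list with `A0`, `PAR`, `r`, their standard
#'   errors (`se`), the 3x3 `covariance`, `chi2`, `dof`, `p_value` (from
#'   [goodness_of_fit()]), `fit_range`, `n_points`, `converged` and `flags`.
#'   Non-convergence or a PAR outside the fit range is flagged, not thrown.
#' @export
fit_sigmoid <- function(profile, z_start, z_end) {
  sel <- profile$z_mm >= z_start & profile$z_mm <= z_end
  z <- profile$z_mm[sel]
  y <- profile$counts[sel]
  s <- profile$sigma[sel]
  if (length(z) < 5) stop("need at least 5 points in the fit range")
  half <- max(y) / 2
  if (!any(y > half) || !any(y < half)) {
    stop("fit range must contain points above and below half-maximum")
  }
  n_prox <- max(1L, floor(length(y) / 3))
  a0_init <- mean(y[seq_len(n_prox)])
  # most distal downward crossing of half-max, linearly interpolated
  above <- y >= half
  ix <- which(above[-length(above)] & !above[-1])
  par_init <- if (length(ix)) {
    i <- max(ix)
    z[i] + (half - y[i]) * (z[i + 1] - z[i]) / (y[i + 1] - y[i])
  } else {
    stats::median(z)
  }
  df <- data.frame(z = z, y = y)
  w <- 1 / s^2
  flags <- character(0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A0 / (1 + exp((z - PAR) / r)), data = df,
      start = list(A0 = a0_init, PAR = par_init, r = 2),
      weights = w, lower = c(A0 = 0, PAR = -Inf, r = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 300,
                                           ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(
      A0 = NA_real_, PAR = NA_real_, r = NA_real_,
      se = c(A0 = NA_real_, PAR = NA_real_, r = NA_real_),
      covariance = matrix(NA_real_, 3, 3), chi2 = NA_real_,
      dof = length(y) - 3L, p_value = NA_real_,
      fit_range = c(z_start, z_end), n_points = length(y),
      n_counts = sum(y), converged = FALSE,
      flags = "no_convergence", data = df),
      class = "sigmoid_fit"))
  }
  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  chi2 <- sum((y - stats::fitted(fit))^2 * w)
  dof <- length(y) - 3L
  if (est["PAR"] < z_start || est["PAR"] > z_end) {
    flags <- c(flags, "PAR_outside_range")
  }
  out <- structure(list(
    A0 = unname(est["A0"]), PAR = unname(est["PAR"]), r = unname(est["r"]),
    se = se, covariance = stats::vcov(fit), chi2 = chi2, dof = dof,
    p_value = NA_real_, fit_range = c(z_start, z_end),
    n_points = length(y), n_counts = sum(y), converged = TRUE,
    flags = flags, data = df, fitted = stats::fitted(fit)),
    class = "sigmoid_fit")
  out$p_value <- goodness_of_fit(out)
  out
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sigmoid_fit> NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<sigmoid_fit> PAR = %.2f +/- %.2f mm, A0 = %.1f, r = %.2f mm\n",
    x$PAR, x$se["PAR"], x$A0, x$r))
  cat(sprintf("  chi2/dof = %.2f/%d (p = %.3f), range [%g, %g] mm\n",
              x$chi2, x$dof, x$p_value, x$fit_range[1], x$fit_range[2]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Two-tailed chi-square goodness of fit
#'
#' @param fit A `sigmoid_fit`, or a chi-square value (then `dof` must be
#'   given).
#' @param dof Degrees of freedom when `fit` is numeric.
#' @return Two-tailed p-value `2 * min(F(chi2), 1 - F(chi2))`.
#' @export
goodness_of_fit <- function(fit, dof = NULL) {
  if (inherits(fit, "sigmoid_fit")) {
    chi2 <- fit$chi2
    dof <- fit$dof
  } else {
    chi2 <- fit
  }
  if (is.null(dof) || is.na(dof) || dof < 1) stop("dof must be >= 1")
  f <- stats::pchisq(chi2, df = dof)
  2 * min(f, 1 - f)
}

#' Fit-range stability scan for the sigmoid start point
#'
#' Fits the sigmoid at every candidate start of the fitting range and selects
#' the most proximal candidate from which the fitted activity range is
#' stable: the spread (max - min) of PAR across that candidate and all
#' candidates distal to it must be smaller than the PAR fit uncertainty at
#' that candidate.  If no candidate is stable the most distal one is
#' returned with an instability flag.  The full parameter table is returned
#' so the variation of `A0` and `r` can be inspected as well.
#'
#' @param profile An activity profile.
#' @param candidate_starts Vector of candidate `z_start` values (mm), at
#'   least 2.
#' @param z_end Fixed end of the fitting range (mm).
#' @return List with `z_start` (chosen), `stable` (logical), `fits` (one per
#'   candidate) and `table` (tibble of parameters and uncertainties per
#'   candidate).
#' @export
select_fit_start <- function(profile, candidate_starts, z_end) {
  stopifnot(length(candidate_starts) >= 2)
  candidate_starts <- sort(candidate_starts)
  fits <- lapply(candidate_starts, function(zs) {
    tryCatch(fit_sigmoid(profile, zs, z_end), error = function(e) NULL)
  })
  ok <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  tab <- tibble::tibble(
    z_start = candidate_starts,
    converged = ok,
    A0 = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$A0,
                numeric(1)),
    PAR = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$PAR,
                 numeric(1)),
    r = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$r,
               numeric(1)),
    se_A0 = vapply(fits, function(f) if (is.null(f)) NA_real_ else
      unname(f$se["A0"]), numeric(1)),
    se_PAR = vapply(fits, function(f) if (is.null(f)) NA_real_ else
      unname(f$se["PAR"]), numeric(1)),
    se_r = vapply(fits, function(f) if (is.null(f)) NA_real_ else
      unname(f$se["r"]), numeric(1))
  )
  stable_at <- function(k) {
    idx <- which(ok & seq_along(fits) >= k)
    if (!(k %in% idx) || length(idx) < 2) return(FALSE)
    spread <- diff(range(tab$PAR[idx]))
    spread < tab$se_PAR[k] + 1e-6
  }
  stable <- vapply(seq_along(fits), stable_at, logical(1))
  if (any(stable)) {
    k <- which(stable)[1]
    list(z_start = candidate_starts[k], stable = TRUE, fits = fits,
         table = tab)
  } else {
    k <- max(which(ok))
    list(z_start = candidate_starts[k], stable = FALSE, fits = fits,
         table = tab)
  }
}

#' Per-spot sigmoid fit report
#'
#' @param fits Named list of `sigmoid_fit` objects (names = spot ids).
#' @return Tibble with one row per spot: the fitted parameters,
#'   uncertainties, goodness of fit and fit range.
#' @export
fit_report <- function(fits) {
  tibble::tibble(
    spot_id = names(fits),
    A0 = vapply(fits, `[[`, numeric(1), "A0"),
    PAR_mm = vapply(fits, `[[`, numeric(1), "PAR"),
    sigma_PAR_mm = vapply(fits, function(f) unname(f$se["PAR"]), numeric(1)),
    r_mm = vapply(fits, `[[`, numeric(1), "r"),
    chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
    dof = vapply(fits, function(f) as.numeric(f$dof), numeric(1)),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    z_start_mm = vapply(fits, function(f) f$fit_range[1], numeric(1)),
    z_end_mm = vapply(fits, function(f) f$fit_range[2], numeric(1)),
    n_counts = vapply(fits, function(f) as.numeric(f$n_counts), numeric(1)),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
}
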