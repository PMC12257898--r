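#' Time histogram of list-mode counts
#'
#' Exact count-preserving binning of event time stamps into uniform bins.
#'
#' @param stream A `listmode_stream` (or a data frame with a `t_ms` column).
#' @param bin_width_ms Bin width in ms; should not be below the time-stamp
#'   resolution.
#' @return A `time_histogram`: list with `bin_edges_ms` (length n+1) and
#'   `counts` (length n).
#' @export
time_histogram <- function(stream, bin_width_ms = 1) {
  stopifnot(bin_width_ms > 0)
  ev <- if (inherits(stream, "listmode_stream")) stream$events else stream
  t <- ev$t_ms
  t_max <- if (inherits(stream, "listmode_stream")) {
    stream$total_duration_s * 1000
  } else if (length(t)) max(t) + bin_width_ms else 0
  n_bins <- max(1L, ceiling(t_max / bin_width_ms))
  edges <- seq(0, n_bins * bin_width_ms, by = bin_width_ms)
  counts <- if (length(t)) {
    tabulate(pmin(floor(t / bin_width_ms) + 1L, n_bins), nbins = n_bins)
  } else {
    integer(n_bins)
  }
  structure(list(bin_edges_ms = edges, counts = counts),
            class = "time_histogram")
}

#' Rebin a time histogram to a coarser bin width
#'
#' @param hist A `time_histogram`.
#' @param factor Integer number of old bins per new bin.
#' @return A `time_histogram`; total counts are preserved.
#' @export
rebin_histogram <- function(hist, factor) {
  stopifnot(inherits(hist, "time_histogram"), factor >= 1,
            factor == round(factor))
  n <- length(hist$counts)
  grp <- (seq_len(n) - 1L) %/% factor
  counts <- as.vector(tapply(hist$counts, grp, sum))
  bw <- diff(hist$bin_edges_ms[1:2]) * factor
  edges <- seq(hist$bin_edges_ms[1], by = bw, length.out = length(counts) + 1L)
  structure(list(bin_edges_ms = edges, counts = counts),
            class = "time_histogram")
}

#' Restrict a time histogram to a time window
#'
#' @param hist A `time_histogram`.
#' @param t_start_ms,t_end_ms Window limits in ms (bins fully inside are kept).
#' @return A `time_histogram`.
#' @export
subset_histogram <- function(hist, t_start_ms, t_end_ms) {
  lo <- hist$bin_edges_ms[-length(hist$bin_edges_ms)]
  hi <- hist$bin_edges_ms[-1]
  keep <- lo >= t_start_ms & hi <= t_end_ms
  structure(list(bin_edges_ms = c(lo[keep], hi[keep][sum(keep)]),
                 counts = hist$counts[keep]),
            class = "time_histogram")
}

#' Segmentation settings
#'
#' @param low_fraction For the fractional saturation model, beam-on bins are
#'   those below `low_fraction` times the median nonzero count rate.
#' @param min_spot_ms,max_spot_ms Plausible beam-spot duration range (ms).
#' @param switch_min_ms Beam-off gaps at least this long are classified as
#'   layer switches rather than inter-spot gaps.
#' @param onset_counts Absolute floor: a candidate spot-on run must be
#'   followed by at least this many counts in the next two bins (the count
#'   rate recovery when the beam switches off).
#' @param onset_strong A recovery at least this large is accepted on its
#'   own, whatever the rate before the run.
#' @param chance_level A low run weaker than `onset_strong` is accepted only
#'   if `run length x pre-run rate` is at least this large, i.e. an all-low
#'   run of that length could not plausibly be a chance fluctuation of the
#'   local count rate.
#' @param saturation `"hard_off"` or `"fractional"`, matching the acquisition.
#' @return A `segmentation_config`.
#' @export
segmentation_config <- function(low_fraction = 0.2, min_spot_ms = 4,
                                max_spot_ms = 100, switch_min_ms = 300,
                                onset_counts = 8, onset_strong = 18,
                                chance_level = 12,
                                saturation = c("hard_off", "fractional")) {
  saturation <- match.arg(saturation)
  structure(list(low_fraction = low_fraction, min_spot_ms = min_spot_ms,
                 max_spot_ms = max_spot_ms, switch_min_ms = switch_min_ms,
                 onset_counts = onset_counts, onset_strong = onset_strong,
                 chance_level = chance_level, saturation = saturation),
            class = "segmentation_config")
}

#' Segment the acquisition into beam intervals
#'
#' Identifies beam-spot periods from the count-rate collapse caused by
#' detector saturation: a spot-on period is a low-count run of plausible spot
#' duration immediately followed by the sharp count-rate recovery at beam-off.
#' The quiet lead-in of a layer switch (or the beam-free pre-beam phase) can
#' merge with the following spot-on run; such runs are truncated to the
#' median detected spot duration and flagged as having an inferred start.
#' Beam-off gaps between spots are classified `inter_spot` or `layer_switch`
#' by duration; the leading and trailing quiet spans become `pre_beam` /
#' `post_beam`.
#'
#' @param hist A 1-ms [time_histogram()] spanning the acquisition.
#' @param config A [segmentation_config()].
#' @param log Optional [simulate_delivery()] log; when given, the detected
#'   spots are matched (in order) to the log records, which are authoritative
#'   for `spot_id` assignment.
#' @return A tibble of intervals: `kind`, `t_start_ms`, `t_end_ms`,
#'   `spot_id`, `start_inferred`; non-overlapping and contiguous over the
#'   histogram span.
#' @export
segment_intervals <- function(hist, config = segmentation_config(),
                              log = NULL) {
  stopifnot(inherits(hist, "time_histogram"))
  c0 <- hist$counts
  bw <- diff(hist$bin_edges_ms[1:2])
  t0 <- hist$bin_edges_ms[1]
  n <- length(c0)
  span <- function(i0, i1) c(t0 + (i0 - 1) * bw, t0 + i1 * bw)

  low_level <- if (config$saturation == "hard_off") {
    0
  } else {
    pos <- c0[c0 > 0]
    if (!length(pos)) 0 else
      max(1, config$low_fraction * stats::median(pos))
  }
  low <- c0 <= low_level
  if (!any(!low)) {
    warning("no beam structure found in the histogram")
    return(tibble::tibble(kind = character(0), t_start_ms = numeric(0),
                          t_end_ms = numeric(0), spot_id = character(0),
                          start_inferred = logical(0)))
  }

  r <- rle(low)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  is_low <- r$values
  # onset check: the recovery after the run must clear the absolute floor,
  # and the run itself must be a credible beam-on period -- either the
  # recovery is strong, or the run is far too long to be a chance gap in
  # the pre-run count rate (which kills rare false positives in the
  # decaying tails of acquisition windows)
  is_onset <- function(k) {
    idx <- pmin(c(run_end[k] + 1L, run_end[k] + 2L), n)
    nxt <- sum(c0[idx])
    if (nxt < config$onset_counts) return(FALSE)
    if (nxt >= config$onset_strong) return(TRUE)
    pre <- max(run_start[k] - 8L, 1L):max(run_start[k] - 1L, 1L)
    pre_rate <- if (run_start[k] > 1L) mean(c0[pre]) else 0
    r$lengths[k] * pre_rate >= config$chance_level
  }
  cand <- which(is_low &
                  r$lengths * bw >= config$min_spot_ms &
                  run_end < n)
  cand <- cand[vapply(cand, is_onset, logical(1))]
  plausible <- cand[r$lengths[cand] * bw <= config$max_spot_ms]
  med_dur <- if (length(plausible)) {
    stats::median(r$lengths[plausible]) * bw
  } else {
    config$max_spot_ms
  }

  spots <- list()
  for (k in cand) {
    len_ms <- r$lengths[k] * bw
    if (len_ms <= config$max_spot_ms) {
      s <- span(run_start[k], run_end[k])
      spots[[length(spots) + 1L]] <- c(s, inferred = 0)
    } else {
      # quiet lead-in merged with the spot-on run: keep the trailing part
      s_end <- span(run_end[k], run_end[k])[2]
      spots[[length(spots) + 1L]] <- c(s_end - med_dur, s_end, inferred = 1)
    }
  }
  if (!length(spots)) {
    warning("no beam structure found in the histogram")
    return(tibble::tibble(kind = character(0), t_start_ms = numeric(0),
                          t_end_ms = numeric(0), spot_id = character(0),
                          start_inferred = logical(0)))
  }
  sp <- do.call(rbind, spots)
  sp <- sp[order(sp[, 1]), , drop = FALSE]

  spot_ids <- rep(NA_character_, nrow(sp))
  if (!is.null(log)) {
    if (nrow(log) != nrow(sp)) {
      warning(sprintf(
        "detected %d spots but the delivery log has %d records",
        nrow(sp), nrow(log)))
    }
    m <- min(nrow(log), nrow(sp))
    spot_ids[seq_len(m)] <- log$spot_id[seq_len(m)]
  }

  rows <- list()
  add <- function(kind, a, b, id = NA_character_, inf = FALSE) {
    if (b > a) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        kind = kind, t_start_ms = unname(a), t_end_ms = unname(b),
        spot_id = unname(id), start_inferred = unname(inf))
    }
  }
  t_total <- t0 + n * bw
  add("pre_beam", t0, sp[1, 1])
  for (i in seq_len(nrow(sp))) {
    add("spot_on", sp[i, 1], sp[i, 2], spot_ids[i], sp[i, 3] == 1)
    gap_end <- if (i < nrow(sp)) sp[i + 1, 1] else t_total
    kind <- if (i == nrow(sp)) {
      "post_beam"
    } else if (gap_end - sp[i, 2] >= config$switch_min_ms) {
      "layer_switch"
    } else {
      "inter_spot"
    }
    add(kind, sp[i, 2], gap_end)
  }
  do.call(rbind, rows)
}

#' Extract the events of one per-spot analysis window
#'
#' Returns the events with time stamps in `[t_end(spot), t_end(spot) +
#' window)`, i.e. the first `window_ms` of PET acquisition after the spot.
#'
#' @param stream A `listmode_stream`.
#' @param intervals Interval table from [segment_intervals()].
#' @param spot_id Spot label to extract.
#' @param window_ms Window length in ms.
#' @return Events tibble with attributes `n`, `t_start_ms`, `t_end_ms`.
#' @export
extract_spot_window_events <- function(stream, intervals, spot_id,
                                       window_ms = 60) {
  row <- intervals[intervals$kind == "spot_on" &
                     !is.na(intervals$spot_id) &
                     intervals$spot_id == spot_id, ]
  if (nrow(row) != 1L) stop("spot_id not found in intervals: ", spot_id)
  t0 <- row$t_end_ms
  ev <- stream$events
  out <- ev[ev$t_ms >= t0 & ev$t_ms < t0 + window_ms, , drop = FALSE]
  attr(out, "n") <- nrow(out)
  attr(out, "t_start_ms") <- t0
  attr(out, "t_end_ms") <- t0 + window_ms
  out
}

#' Decompose a beam-off window into decay components
#'
#' Weighted least-squares fit of one or two exponential decay components
#' (parameterised by half-life) plus an optional flat background to the
#' counts of a beam-off time histogram.  Weights are Poisson:
#' variance = max(counts, 1) per bin.
#'
#' @param hist A `time_histogram` restricted to the beam-off window.
#' @param n_components 1 or 2 decay components.
#' @param include_flat Add a constant background term.
#' @param half_life_init_ms Optional vector of initial half-life guesses
#'   (ms), one per component.
#' @return A `decay_fit`: list with `components` (data frame with
#'   `half_life_ms`, `half_life_se_ms`, `amplitude`, `amplitude_se`),
#'   `flat`, `flat_se`, `chi2`, `dof`, `converged` and `message`.
#'   Non-convergence is reported through `converged = FALSE`, not an error.
#' @export
decay_component_fit <- function(hist, n_components = 1, include_flat = TRUE,
                                half_life_init_ms = NULL) {
  stopifnot(inherits(hist, "time_histogram"),
            n_components %in% c(1L, 2L))
  y <- hist$counts
  lo <- hist$bin_edges_ms[-length(hist$bin_edges_ms)]
  bw <- diff(hist$bin_edges_ms[1:2])
  t <- lo - lo[1] + bw / 2
  if (sum(y > 0) < 10) stop("window must have at least 10 bins with counts")
  w <- 1 / pmax(y, 1)
  span <- max(t) - min(t)
  if (is.null(half_life_init_ms)) {
    half_life_init_ms <- if (n_components == 1) span / 8 else
      c(span / 20, span)
  }
  df <- data.frame(t = t, y = y)
  fail <- function(msg) {
    comp <- data.frame(half_life_ms = rep(NA_real_, n_components),
                       half_life_se_ms = NA_real_, amplitude = NA_real_,
                       amplitude_se = NA_real_)
    structure(list(components = comp, flat = NA_real_, flat_se = NA_real_,
                   chi2 = NA_real_, dof = NA_integer_, converged = FALSE,
                   message = msg),
              class = "decay_fit")
  }
  form <- if (n_components == 1) {
    if (include_flat) y ~ A1 * 2^(-t / T1) + B else y ~ A1 * 2^(-t / T1)
  } else {
    if (include_flat) y ~ A1 * 2^(-t / T1) + A2 * 2^(-t / T2) + B else
      y ~ A1 * 2^(-t / T1) + A2 * 2^(-t / T2)
  }
  start <- list(A1 = max(y), T1 = half_life_init_ms[1])
  lower <- c(A1 = 0, T1 = bw / 10)
  if (n_components == 2) {
    start$A2 <- max(stats::median(y[t > span / 2]), 1)
    start$T2 <- half_life_init_ms[2]
    lower <- c(lower, A2 = 0, T2 = bw / 10)
  }
  if (include_flat) {
    start$B <- max(min(y), 0)
    lower <- c(lower, B = 0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start, weights = w,
                      lower = lower,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("fit did not converge"))
  cf <- summary(fit)$coefficients
  res <- y - stats::fitted(fit)
  chi2 <- sum(res^2 * w)
  dof <- length(y) - nrow(cf)
  comp_names <- paste0(c("A", "T"), rep(seq_len(n_components), each = 2))
  comp <- data.frame(
    half_life_ms = cf[paste0("T", seq_len(n_components)), "Estimate"],
    half_life_se_ms = cf[paste0("T", seq_len(n_components)), "Std. Error"],
    amplitude = cf[paste0("A", seq_len(n_components)), "Estimate"],
    amplitude_se = cf[paste0("A", seq_len(n_components)), "Std. Error"]
  )
  # order components by half-life for stable reporting
  comp <- comp[order(comp$half_life_ms), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(
    components = comp,
    flat = if (include_flat) cf["B", "Estimate"] else 0,
    flat_se = if (include_flat) cf["B", "Std. Error"] else 0,
    chi2 = chi2, dof = dof, converged = TRUE, message = "ok"),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit>", if (x$converged) "converged" else "NOT converged", "\n")
  if (x$converged) {
    for (i in seq_len(nrow(x$components))) {
      cat(sprintf("  T1/2 = %.3g +/- %.2g ms (A = %.3g)\n",
                  x$components$half_life_ms[i],
                  x$components$half_life_se_ms[i],
                  x$components$amplitude[i]))
    }
    cat(sprintf("  flat = %.3g, chi2/dof = %.3g/%d\n",
                x$flat, x$chi2, x$dof))
  }
  invisible(x)
}

#' Write a segmentation interval table as CSV
#'
#' @param intervals Interval tibble from [segment_intervals()].
#' @param path File path.
#' @export
write_intervals_csv <- function(intervals, path) {
  utils::write.csv(as.data.frame(intervals), path, row.names = FALSE)
  invisible(path)
}
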