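# Shared fixtures: simulations are expensive enough to cache across files.
# All test simulations use a 1-s pre-beam phase (the default 60 s mirrors the
# background-measurement phase of a real acquisition and adds nothing here).
.spotpet_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.spotpet_cache[[key]])) .spotpet_cache[[key]] <- force(expr)
  .spotpet_cache[[key]]
}

test_head_sim <- function(seed = 42, wet = 0) {
  cached(sprintf("sim_%d_%g", seed, wet),
         simulate_listmode(head_like_plan(pre_beam_s = 1),
                           phantom_model(shifter_wet_mm = wet),
                           seed = seed))
}

test_head_analysis <- function(seed = 42, wet = 0) {
  cached(sprintf("ana_%d_%g", seed, wet),
         analyze_spots(test_head_sim(seed, wet)))
}

test_pdrs <- function(sim) {
  pd <- lapply(seq_len(nrow(sim$log)), function(k) {
    pdr_from_dose(depth_dose_profile(as.list(sim$log[k, ]), sim$phantom),
                  spot_id = sim$log$spot_id[k])
  })
  names(pd) <- sim$log$spot_id
  pd
}

# production cutoff depth of the default 12N channel (water, no shifter)
n12_cutoff <- function(energy_mev, wet = 0) {
  -85.2 + proton_range_water(energy_mev) - proton_range_water(20) - wet
}

# minimal hand-built image2d for projection tests
make_image <- function(counts, x_edges, z_edges) {
  structure(list(x_edges = x_edges, z_edges = z_edges, counts = counts,
                 plane_y_mm = 0, n_events = sum(counts),
                 n_accepted = sum(counts), n_rejected_no_crossing = 0L,
                 n_rejected_fov = 0L, n_rejected_degenerate = 0L),
            class = "image2d")
}

# minimal sigmoid_fit stand-in for shift arithmetic tests
fake_fit <- function(par, se) {
  structure(list(A0 = 100, PAR = par, r = 3,
                 se = c(A0 = 1, PAR = se, r = 0.5),
                 covariance = diag(3), chi2 = 8, dof = 8, p_value = 0.5,
                 fit_range = c(8, 96), n_points = 11, n_counts = 500,
                 converged = TRUE, flags = character(0)),
            class = "sigmoid_fit")
}

# Poisson realisation of an ideal sigmoid profile on 8-mm pixels; `bg` adds
# the kind of flat long-lived pedestal real windows carry
sigmoid_profile <- function(a0 = 100, par = 50, r = 3, noise = TRUE,
                            z = seq(4, 116, by = 8), bg = 0) {
  mu <- a0 / (1 + exp((z - par) / r)) + bg
  counts <- if (noise) stats::rpois(length(z), mu) else mu
  structure(tibble::tibble(z_mm = z, counts = counts,
                           sigma = sqrt(pmax(counts, 1))),
            class = c("activity_profile", "tbl_df", "tbl", "data.frame"))
}
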