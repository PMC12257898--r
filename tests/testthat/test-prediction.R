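test_that("the 12N decay weight matches its closed form and limits", {
  lam <- 63.01
  # Np = 5.28e8 protons, 20-ms spot, 60-ms window
  w <- n12_weight(5.28e8, 0.020, 0.060, lam)
  expect_equal(w, 2.933e8, tolerance = 1e-3)
  # instantaneous-spot limit
  expect_equal(n12_weight(1e8, 0, 0.060, lam),
               1e8 * -expm1(-lam * 0.060), tolerance = 1e-12)
  # bounded by Np (every created nucleus decays at most once)
  for (t0 in c(0.001, 0.01, 0.05)) {
    expect_lt(n12_weight(1e8, t0, 10, lam), 1e8)
  }
  expect_error(n12_weight(-1, 0.01, 0.06, lam))
})

test_that("long-lived weights accumulate over prior spots with decay", {
  log <- simulate_delivery(head_like_plan(pre_beam_s = 1), seed = 9)
  lam_o15 <- decay_constant(122.24)
  w1 <- long_lived_weight(log, "01/01", lam_o15, 0.060)
  expect_equal(nrow(w1), 1)
  expect_equal(w1$multiplier, log$n_protons[1] * lam_o15 * 0.060)

  w8 <- long_lived_weight(log, "02/07", lam_o15, 0.060)
  expect_equal(nrow(w8), 8)
  expect_equal(w8$source_spot_id, log$spot_id)
  # a spot delayed by 1/lambda contributes 1/e of its prompt weight
  te <- log$t_end_us / 1e6
  j <- 3
  expect_equal(w8$multiplier[j] / (log$n_protons[j] * lam_o15 * 0.060),
               exp(-lam_o15 * (te[8] - te[j])), tolerance = 1e-12)
  expect_error(long_lived_weight(log, "99/99", lam_o15, 0.060), "not found")
})

test_that("the long-lived fraction grows along the delivery", {
  sim <- test_head_sim()
  preds <- lapply(sim$log$spot_id, function(id) predict_spot_image(sim, id))
  rep <- prediction_report(setNames(preds, sim$log$spot_id))
  frac_long <- rep$frac_O15 + rep$frac_C11
  # individual steps can dip when a short spot boosts its own 12N share,
  # but the long-lived share must climb over the delivery
  expect_gt(stats::cor(frac_long, seq_along(frac_long),
                       method = "spearman"), 0.8)
  expect_gt(frac_long[8], 2 * frac_long[1])
  expect_gt(rep$frac_N12[1], 0.9)  # first spot is 12N-dominated
})

test_that("total-image composition normalises exactly and flags zeros", {
  a <- matrix(1:4, 2)
  b <- matrix(c(0, 1, 0, 1), 2)
  p <- compose_total_image(list("N-12" = a, "O-15" = b),
                           measured_total_counts = 123)
  expect_equal(sum(p$total), 123, tolerance = 1e-9)
  expect_equal(p$M, 123 / (sum(a) + sum(b)))
  expect_equal(unname(p$fractions["N-12"]), sum(a) / (sum(a) + sum(b)))

  p1 <- compose_total_image(list("N-12" = a))
  expect_equal(p1$M, 1)
  # linearity: doubling the weighted images doubles the unnormalised total
  p2 <- compose_total_image(list("N-12" = 2 * a))
  expect_equal(sum(p2$total), 2 * sum(p1$total))

  z <- compose_total_image(list("N-12" = matrix(0, 2, 2)))
  expect_true("zero_prediction" %in% z$flags)
  expect_true(is.na(z$M))
  expect_error(compose_total_image(list(a = a, b = matrix(0, 3, 3))),
               "common grid")
})

test_that("Eq-style 12N weights reproduce the generator's detections", {
  # near-4pi geometry so that the acceptance factor is the efficiency alone
  plan <- irradiation_plan(
    layers = list(list(energy_mev = 146.5, n_protons = 2e7)),
    pre_beam_s = 0.2, spot_duration_range_ms = c(15, 15))
  geom <- panel_geometry(panel_half_width_x_mm = 1e5,
                         panel_half_length_z_mm = 1e5,
                         detection_efficiency_per_photon = 0.5)
  prod <- production_model(n12_q = 1e-5, o15_q = 0, c11_q = 0)
  lam <- decay_constant(0.0110)
  ratio <- vapply(1:6, function(s) {
    sim <- simulate_listmode(plan, geometry = geom, production = prod,
                             seed = 40 + s, include_truth_images = FALSE,
                             grid = recon_grid())
    t0 <- (sim$log$t_end_us - sim$log$t_start_us) / 1e6
    expected <- n12_weight(2e7, t0, 0.060, lam) * 1e-5 *
      (proton_range_water(146.5) - proton_range_water(20)) * 0.25
    te_ms <- sim$log$t_end_us / 1000
    got <- sum(sim$stream$events$t_ms >= te_ms &
                 sim$stream$events$t_ms < te_ms + 60)
    got / expected
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("the distal part of the prediction is 12N-dominated", {
  sim <- test_head_sim()
  p <- predict_spot_image(sim, "01/01")
  expect_gt(distal_isotope_fraction(p, "N-12", 0.1), 0.9)
})

test_that("predicted and measured activity ranges agree spot by spot", {
  sim <- test_head_sim()
  ana <- test_head_analysis()
  grid <- recon_grid(sim$geometry)
  diffs <- vapply(sim$log$spot_id, function(id) {
    pred <- predict_spot_image(sim, id,
                               measured_total_counts = ana$window_counts[[id]])
    fp <- fit_sigmoid(prediction_profile(pred, grid$z_edges), 8, 96)
    fp$PAR - ana$fits[[id]]$PAR
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.5)
})
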