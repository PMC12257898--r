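test_that("range-energy law is monotone and gives ~150 mm at 146.5 MeV", {
  expect_equal(proton_range_water(146.5), 150.24, tolerance = 0.01)
  e <- seq(5, 245, by = 10)
  expect_true(all(diff(proton_range_water(e)) > 0))
  expect_error(proton_range_water(0.5))
  expect_error(proton_range_water(300))
})

test_that("production profile ends at the threshold depth, short of the range", {
  ph <- phantom_model()
  grid <- recon_grid()
  spot <- list(energy_mev = 146.5, lateral_x_mm = 0)
  img <- production_depth_profile(spot, ph, "N-12", 20, grid,
                                  q_per_proton_mm = 1e-6)
  # oracle: invert the range law numerically for the residual energy
  resid_energy <- function(depth) {
    stats::uniroot(function(e) {
      proton_range_water(146.5) - proton_range_water(e) - depth
    }, c(1, 146.4))$root
  }
  depth <- img$z_cutoff_mm - ph$entry_z_mm
  expect_equal(resid_energy(depth), 20, tolerance = 1e-4)
  expect_lt(img$z_cutoff_mm, ph$entry_z_mm + proton_range_water(146.5))
  # no yield beyond the cutoff
  z_hi <- grid$z_edges[-1]
  beyond <- z_hi > img$z_cutoff_mm + 8
  expect_true(all(colSums(img$yield_density)[beyond] == 0))
  expect_true(all(img$yield_density >= 0))
  # total yield per proton equals rate x production length
  expect_equal(sum(img$yield_density),
               1e-6 * (img$z_cutoff_mm - ph$entry_z_mm), tolerance = 1e-6)
  expect_warning(
    production_depth_profile(spot, ph, "N-12", 150, grid),
    "threshold")
})

test_that("a range shifter translates cutoffs and the dose curve exactly", {
  spot <- list(energy_mev = 146.5, lateral_x_mm = 0)
  grid <- recon_grid()
  img0 <- production_depth_profile(spot, phantom_model(), "N-12", 20, grid)
  img5 <- production_depth_profile(spot,
                                   phantom_model(shifter_wet_mm = 5),
                                   "N-12", 20, grid)
  expect_equal(img0$z_cutoff_mm - img5$z_cutoff_mm, 5)

  d0 <- depth_dose_profile(spot, phantom_model())
  d5 <- depth_dose_profile(spot, phantom_model(shifter_wet_mm = 5))
  expect_true(all(d0$dose >= 0))
  expect_equal(d0$z_mm[which.max(d0$dose)] - d5$z_mm[which.max(d5$dose)], 5,
               tolerance = 0.2)
  # single distal 80% crossing
  p0 <- pdr_from_dose(d0)
  above <- d0$dose >= 0.8 * max(d0$dose)
  expect_equal(sum(above[-length(above)] & !above[-1]), 1)
  # PDR sits between the Bragg peak and the far tail
  z_peak <- -85.2 + proton_range_water(146.5)
  expect_gt(p0$PDR_mm, z_peak)
  expect_lt(p0$PDR_mm, z_peak + 4)
})

test_that("delivery logs respect the plan timing and the log resolution", {
  plan <- head_like_plan(pre_beam_s = 1)
  log <- simulate_delivery(plan, seed = 3)
  expect_identical(log, simulate_delivery(plan, seed = 3))
  expect_false(identical(log, simulate_delivery(plan, seed = 4)))
  expect_true(all(c(log$t_start_us, log$t_end_us) %% 200 == 0))
  dur <- log$t_end_us - log$t_start_us
  expect_true(all(dur >= 10000 & dur <= 25000))
  gaps <- log$t_start_us[-1] - log$t_end_us[-nrow(log)]
  same_layer <- diff(log$layer_index) == 0
  expect_true(all(gaps[same_layer] == 60000))
  expect_true(all(gaps[!same_layer] >= 700000 & gaps[!same_layer] <= 800000))
  expect_true(all(dur > 0))
  expect_true(all(diff(log$t_start_us) > 0))
})

test_that("list-mode generation is seeded, and empty at zero efficiency", {
  plan <- single_spot_plan(pre_beam_s = 0.2)
  a <- simulate_listmode(plan, seed = 5)
  b <- simulate_listmode(plan, seed = 5)
  expect_identical(a$stream$events, b$stream$events)
  expect_error(simulate_listmode(plan), "seed")

  g0 <- panel_geometry(detection_efficiency_per_photon = 0)
  empty <- simulate_listmode(plan, geometry = g0, seed = 5)
  expect_equal(nrow(empty$stream$events), 0)
  expect_error(panel_geometry(panel_half_width_x_mm = 0), "acceptance")
})

test_that("12N window counts match the closed-form expectation", {
  # near-4pi panels make the geometric acceptance ~1, so the expectation
  # reduces to Np q L x spot-survival x window-decay x efficiency^2
  plan <- irradiation_plan(
    layers = list(list(energy_mev = 146.5, n_protons = 1e7)),
    pre_beam_s = 0.2, spot_duration_range_ms = c(20, 20))
  geom <- panel_geometry(panel_half_width_x_mm = 1e5,
                         panel_half_length_z_mm = 1e5,
                         detection_efficiency_per_photon = 0.5)
  prod <- production_model(n12_q = 1e-5, o15_q = 0, c11_q = 0)
  sim <- simulate_listmode(plan, geometry = geom, production = prod,
                           seed = 11, include_truth_images = FALSE,
                           grid = recon_grid())
  lam <- decay_constant(0.0110)
  t0 <- (sim$log$t_end_us - sim$log$t_start_us) / 1e6
  l_prod <- proton_range_water(146.5) - proton_range_water(20)
  expected <- 1e7 * 1e-5 * l_prod *
    -expm1(-lam * t0) / (lam * t0) * -expm1(-lam * 0.060) * 0.25
  te_ms <- sim$log$t_end_us / 1000
  got <- sum(sim$stream$events$t_ms >= te_ms &
               sim$stream$events$t_ms < te_ms + 60)
  expect_lt(abs(got - expected) / sqrt(expected), 5)
})

test_that("events never carry beam-on time stamps under hard_off saturation", {
  sim <- test_head_sim()
  t <- sim$stream$events$t_ms
  for (k in seq_len(nrow(sim$log))) {
    expect_equal(sum(t >= sim$log$t_start_us[k] / 1000 &
                       t < sim$log$t_end_us[k] / 1000 - 1), 0)
  }
  expect_true(all(diff(sim$stream$events$t_ms) >= 0))
})

test_that("list-mode and delivery-log CSV round-trips preserve the data", {
  sim <- test_head_sim()
  lm_path <- withr::local_tempfile(fileext = ".csv")
  lg_path <- withr::local_tempfile(fileext = ".csv")
  write_listmode_csv(sim$stream, lm_path)
  write_delivery_log_csv(sim$log, lg_path)
  back <- read_listmode_csv(lm_path, sim$stream$total_duration_s)
  expect_equal(as.data.frame(back$events), as.data.frame(sim$stream$events))
  log2 <- read_delivery_log_csv(lg_path)
  expect_equal(as.data.frame(log2), as.data.frame(sim$log))
})
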