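test_that("time histograms are exact count-preserving binnings", {
  ev <- data.frame(t_ms = c(0.5, 1.5, 1.6))
  h <- time_histogram(ev, 1)
  expect_equal(h$counts[1:2], c(1, 2))
  expect_equal(sum(h$counts), 3)

  sim <- test_head_sim()
  h1 <- time_histogram(sim$stream, 1)
  expect_equal(sum(h1$counts), nrow(sim$stream$events))
  h10 <- rebin_histogram(h1, 10)
  expect_equal(sum(h10$counts), sum(h1$counts))
  expect_equal(diff(h10$bin_edges_ms[1:2]), 10)

  h0 <- time_histogram(data.frame(t_ms = numeric(0)), 1)
  expect_equal(sum(h0$counts), 0)
})

test_that("segmentation recovers the delivery structure from the rate drops", {
  sim <- test_head_sim()
  h <- time_histogram(sim$stream)
  iv <- segment_intervals(h, segmentation_config(), log = sim$log)

  sp <- iv[iv$kind == "spot_on", ]
  expect_equal(nrow(sp), nrow(sim$log))
  expect_equal(sp$spot_id, sim$log$spot_id)

  # spot end = count-rate recovery: sharp, recovered within 2 bins
  expect_true(all(abs(sp$t_end_ms - sim$log$t_end_us / 1000) <= 2))
  # spot starts are detectable within 2 bins when the preceding gap still
  # carries 12N counts, i.e. for every spot but the first of each layer
  mid <- which(c(FALSE, diff(sim$log$layer_index) == 0))
  expect_true(all(abs(sp$t_start_ms[mid] - sim$log$t_start_us[mid] / 1000)
                  <= 2))

  # gap classification: 60-ms gaps are inter_spot, ~750-ms gaps layer_switch
  expect_equal(sum(iv$kind == "inter_spot"), 6)
  expect_equal(sum(iv$kind == "layer_switch"), 1)
  sw <- iv[iv$kind == "layer_switch", ]
  expect_gte(sw$t_end_ms - sw$t_start_ms, 300)
  expect_equal(iv$kind[1], "pre_beam")
  expect_equal(iv$kind[nrow(iv)], "post_beam")

  # lossless tiling of the acquisition: contiguous intervals, every event in
  # exactly one of them
  expect_equal(iv$t_start_ms[-1], iv$t_end_ms[-nrow(iv)])
  expect_equal(iv$t_start_ms[1], 0)
  t <- sim$stream$events$t_ms
  per_interval <- vapply(seq_len(nrow(iv)), function(k) {
    sum(t >= iv$t_start_ms[k] & t < iv$t_end_ms[k])
  }, numeric(1))
  expect_equal(sum(per_interval), length(t))
})

test_that("boundary recovery holds across seeds", {
  n_ok <- 0; n_tot <- 0
  for (s in c(11, 12, 13, 14, 15)) {
    sim <- test_head_sim(seed = s)
    iv <- segment_intervals(time_histogram(sim$stream),
                            segmentation_config(), log = sim$log)
    sp <- iv[iv$kind == "spot_on", ]
    expect_equal(nrow(sp), nrow(sim$log))
    mid <- which(c(FALSE, diff(sim$log$layer_index) == 0))
    err <- c(abs(sp$t_end_ms - sim$log$t_end_us / 1000),
             abs(sp$t_start_ms[mid] - sim$log$t_start_us[mid] / 1000))
    n_ok <- n_ok + sum(err <= 2)
    n_tot <- n_tot + length(err)
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("a constructed stream without tails segments trivially", {
  # three 20-ms spots separated by 60-ms gaps; uniform counts in the gaps
  # only, so the structure is unambiguous
  spot_ends <- c(220, 300, 380)
  t <- unlist(lapply(spot_ends, function(e) seq(e + 0.05, e + 59.95, by = 0.1)))
  h <- time_histogram(data.frame(t_ms = t), 1)
  iv <- segment_intervals(h, segmentation_config())
  expect_equal(sum(iv$kind == "spot_on"), 3)
  expect_equal(sum(iv$kind == "inter_spot"), 2)  # the last gap is post_beam
  expect_equal(iv$kind[1], "pre_beam")
  sp <- iv[iv$kind == "spot_on", ]
  expect_equal(sp$t_end_ms, spot_ends)
})

test_that("window extraction is windowed, disjoint and spot-addressed", {
  sim <- test_head_sim()
  ana <- test_head_analysis()
  iv <- ana$intervals
  w1 <- extract_spot_window_events(sim$stream, iv, "01/01", 60)
  expect_gte(attr(w1, "n"), 570)
  expect_lte(attr(w1, "n"), 1237)
  expect_true(all(w1$t_ms >= attr(w1, "t_start_ms") &
                    w1$t_ms < attr(w1, "t_end_ms")))

  w0 <- extract_spot_window_events(sim$stream, iv, "01/01", 0)
  expect_equal(attr(w0, "n"), 0)

  w2 <- extract_spot_window_events(sim$stream, iv, "02/01", 60)
  expect_equal(length(intersect(w1$t_ms, w2$t_ms)) > 0 &&
                 max(w1$t_ms) >= min(w2$t_ms), FALSE)
  expect_error(extract_spot_window_events(sim$stream, iv, "09/99"),
               "not found")
})

test_that("decay component fits recover half-lives", {
  # noiseless single exponential is recovered essentially exactly
  t_edges <- seq(0, 60, by = 1)
  counts <- 1000 * 2^(-(t_edges[-61] + 0.5) / 11)
  h <- structure(list(bin_edges_ms = t_edges, counts = counts),
                 class = "time_histogram")
  f <- decay_component_fit(h, 1, include_flat = FALSE)
  expect_true(f$converged)
  expect_equal(f$components$half_life_ms, 11, tolerance = 1e-6)
  expect_equal(f$components$amplitude, 1000, tolerance = 1e-6)

  # seeded post-spot window: 12N half-life within 3 sigma
  sim <- test_head_sim()
  h1 <- time_histogram(sim$stream)
  iv <- segment_intervals(h1, segmentation_config(), log = sim$log)
  sp1 <- iv[iv$kind == "spot_on" & !is.na(iv$spot_id) &
              iv$spot_id == "01/01", ]
  win <- subset_histogram(h1, sp1$t_end_ms, sp1$t_end_ms + 60)
  fw <- decay_component_fit(win, 1, include_flat = TRUE)
  expect_true(fw$converged)
  expect_lt(abs(fw$components$half_life_ms - 11.0),
            3 * fw$components$half_life_se_ms)

  expect_error(decay_component_fit(
    structure(list(bin_edges_ms = 0:5, counts = c(1, 0, 0, 2, 0)),
              class = "time_histogram"), 1), "10 bins")
})

test_that("8B appears in long beam-off windows when enabled", {
  sim <- cached("sim_b8", simulate_listmode(
    head_like_plan(pre_beam_s = 1),
    acquisition = acquisition_config(post_beam_s = 3),
    production = production_model(include_b8 = TRUE), seed = 7))
  h <- time_histogram(sim$stream)
  t_last <- max(sim$log$t_end_us) / 1000
  win <- rebin_histogram(subset_histogram(h, t_last, t_last + 3000), 10)
  f <- decay_component_fit(win, 2, include_flat = TRUE,
                           half_life_init_ms = c(11, 770))
  expect_true(f$converged)
  # components ordered by half-life: 12N first, 8B second
  expect_lt(abs(f$components$half_life_ms[2] - 770),
            3 * f$components$half_life_se_ms[2])
  expect_lt(f$components$half_life_se_ms[2], 200)
})
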