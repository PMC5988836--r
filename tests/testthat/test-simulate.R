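test_that("pulse trains respect rate, refractory period and determinism", {
  spec <- pulse_train_spec(rate = 0)
  expect_equal(nrow(generate_pulse_train(spec, 90, seed = 1)), 0L)

  spec <- pulse_train_spec(rate = 4, refractory = 12)
  a <- generate_pulse_train(spec, 90, seed = 5)
  b <- generate_pulse_train(spec, 90, seed = 5)
  expect_identical(a, b)
  if (nrow(a) > 1) expect_true(all(diff(a$center) >= 12))
  expect_true(all(a$center >= 0 & a$center <= 90))
  expect_true(all(a$amplitude >= 0))

  expect_error(pulse_train_spec(rate = -1), "rate")
  expect_error(pulse_train_spec(duration_mean = 0), "duration_mean")
})

test_that("pulse count matches the Poisson mean without refractory thinning", {
  spec <- pulse_train_spec(rate = 2, refractory = 0)
  counts <- vapply(1:1000, function(s) {
    nrow(generate_pulse_train(spec, 90, seed = s))
  }, numeric(1))
  # mean 3 with SE sqrt(3/1000); allow 3 SE
  expect_lt(abs(mean(counts) - 3), 3 * sqrt(3 / 1000))
})

test_that("trace generation is the model plus calibrated noise", {
  ts <- trace_spec(basal = 1, noise_sd = 0)
  tr <- generate_trace(pulse_params(), ts, seed = 1)
  expect_true(all(tr$value == 1))
  expect_equal(nrow(tr), 61L)

  tr <- generate_trace(pulse_params(0.1, 45, 2 * pi / 20), ts, seed = 1)
  expect_equal(tr$value[tr$time_min == 45], 1.2)   # basal + 2A

  ts <- trace_spec(noise_sd = 0.01, duration = 88.5, interval = 1.5)
  clean <- generate_trace(pulse_params(), trace_spec(noise_sd = 0,
                                                     duration = 88.5),
                          seed = 2)
  noisy <- generate_trace(pulse_params(), ts, seed = 3)
  resid <- noisy$value - clean$value
  expect_lt(abs(sd(resid) - 0.01), 0.004)          # 60 frames, plug-in noise
  expect_identical(generate_trace(pulse_params(), ts, seed = 9),
                   generate_trace(pulse_params(), ts, seed = 9))
})

test_that("condition multipliers scale rate and basal as advertised", {
  pop <- generate_population(
    5, pulse_train_spec(rate = 2), trace_spec(noise_sd = 0),
    effects = list(condition_effect("nopulse", rate_multiplier = 0),
                   condition_effect("lowbasal", basal_multiplier = 0.8)),
    seed = 3)
  truth <- pop$truth$cells
  expect_true(all(truth$n_pulses[truth$condition == "nopulse"] == 0))
  expect_equal(unique(truth$basal[truth$condition == "lowbasal"]), 0.8)
  expect_equal(unique(truth$basal[truth$condition == "control"]), 1)
  # noiseless pulse-free traces sit exactly at the scaled basal
  v <- pop$traces$value[pop$traces$condition == "nopulse"]
  expect_true(all(v == 1))
  expect_error(condition_effect("x", rate_multiplier = -1), "multipliers")
})

test_that("detected pulse frequency tracks the generative rate end to end", {
  pop <- generate_population(
    50, pulse_train_spec(rate = 2), trace_spec(),
    effects = list(condition_effect("suppressed", rate_multiplier = 0.2)),
    seed = 21)
  fits <- fit_population(pop$traces, fit_config(), smooth_window_min = 6)
  cells <- fits_to_df(fits)$cells
  truth <- pop$truth$cells
  det <- vapply(c("control", "suppressed"), function(cc) {
    mean(cells$frequency_per_h[cells$condition == cc])
  }, numeric(1))
  tru <- vapply(c("control", "suppressed"), function(cc) {
    mean(truth$n_pulses[truth$condition == cc]) / 1.5
  }, numeric(1))
  # the detected suppression must track the generated suppression; some
  # drift is expected because overlapping pulses merge under the
  # max-composition model and noise-level bumps occasionally fit
  expect_lt(abs(det[2] / det[1] - tru[2] / tru[1]), 0.12)
  expect_lt(det[2] / det[1], 0.5)
  # per-condition detection efficiency stays high
  expect_gt(det[1] / tru[1], 0.8)
})

test_that("wave scenes put sources and recruits where the spec says", {
  ts <- trace_spec(noise_sd = 0, duration = 88.5)
  # trigger_prob = 0: only the source fires
  sc <- scene_spec(rows = 3, cols = 3, wave_sources = 5L, trigger_prob = 0)
  scn <- generate_propagating_scene(sc, ts, seed = 4)
  expect_equal(nrow(scn$truth$onsets), 1L)
  expect_equal(scn$truth$onsets$cell_id, "cell_005")

  # trigger_prob = 1 on a 3x3 grid: all 9 cells fire
  sc <- scene_spec(rows = 3, cols = 3, wave_sources = 1L, trigger_prob = 1)
  scn <- generate_propagating_scene(sc, ts, seed = 4)
  expect_equal(nrow(scn$truth$onsets), 9L)
  # onsets increase by hop_lag per hop
  on <- scn$truth$onsets
  expect_equal(on$onset_min - on$onset_min[on$hops == 0],
               on$hops * sc$hop_lag)

  # 1x5 chain at 20 um spacing, 2-min hop: ground-truth velocity 10 um/min
  sc <- scene_spec(rows = 1, cols = 5, spacing = 20, hop_lag = 2)
  scn <- generate_propagating_scene(sc, ts, seed = 4)
  expect_equal(scn$truth$velocity, 10)
  expect_error(scene_spec(1, 5, trigger_prob = 1.2), "trigger_prob")
})

test_that("rendered movies invert exactly through ratio imaging", {
  sc <- scene_spec(rows = 2, cols = 2, spacing = 20)
  ts <- trace_spec(noise_sd = 0, duration = 30, interval = 1.5)
  scn <- generate_propagating_scene(sc, ts, seed = 6)
  movie <- render_movie(scn$traces, scn$positions, pixel_size = 2,
                        radius_um = 6)
  ratio <- compute_ratio_stack(movie$stack, cfp_floor = 1)
  got <- extract_cell_traces(ratio, movie$mask)
  for (id in unique(scn$traces$cell_id)) {
    a <- got$value[got$cell_id == id]
    b <- scn$traces$value[scn$traces$cell_id == id]
    expect_lt(max(abs(a - b) / abs(b)), 1e-6)
  }
  # overlapping nuclei are rejected to keep ROI truth unambiguous
  expect_error(render_movie(scn$traces, scn$positions, radius_um = 15),
               "overlap")
  # zero cells: a background-only stack
  empty <- render_movie(scn$traces[0, ], scn$positions[0, ],
                        background = 5, interval = 1.5)
  expect_true(all(empty$stack$cfp == 5))
})

test_that("uncorrected background biases the ratio toward 1 at low signal", {
  # closed form: observed ratio = (R * I + b) / (I + b)
  sc <- scene_spec(rows = 1, cols = 2, spacing = 25)
  ts <- trace_spec(basal = 2, noise_sd = 0, duration = 30, interval = 1.5)
  scn <- generate_propagating_scene(sc, ts, seed = 8, wave_amplitude = 0)
  b <- 500; I <- 1000; R <- 2
  movie <- render_movie(scn$traces, scn$positions, cfp_level = I,
                        background = b, radius_um = 6)
  biased <- compute_ratio_stack(movie$stack, cfp_floor = 1)
  got <- extract_cell_traces(biased, movie$mask)
  expect_equal(mean(got$value), (R * I + b) / (I + b), tolerance = 1e-6)
  # subtracting the true background restores the ratio exactly
  fixed <- compute_ratio_stack(movie$stack, background_cfp = b,
                               background_fret = b, cfp_floor = 1)
  got2 <- extract_cell_traces(fixed, movie$mask)
  expect_equal(mean(got2$value), R, tolerance = 1e-9)
})
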