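test_that("a flat noiseless trace fits as its mean with zero error", {
  tr <- generate_trace(pulse_params(), trace_spec(basal = 1.3, noise_sd = 0),
                       seed = 1)
  f <- fit_trace(tr)
  expect_equal(f$n_pulses, 0L)
  expect_equal(f$basal, 1.3)
  expect_equal(f$sse, 0)
  expect_equal(f$classification, "pulse-")
})

test_that("noiseless pulses are recovered essentially exactly", {
  ts <- trace_spec(noise_sd = 0)
  one <- generate_trace(pulse_params(0.1, 45, 2 * pi / 20), ts, seed = 1)
  f <- fit_trace(one)
  expect_equal(f$n_pulses, 1L)
  expect_equal(f$pulses$amplitude, 0.1, tolerance = 1e-3)
  expect_equal(f$pulses$center, 45, tolerance = 1e-3)
  expect_equal(f$pulses$duration, 20, tolerance = 1e-3)
  expect_equal(f$basal, 1, tolerance = 1e-3)

  two <- generate_trace(pulse_params(c(0.1, 0.15), c(25, 65),
                                     2 * pi / c(20, 15)), ts, seed = 1)
  f2 <- fit_trace(two)
  expect_equal(f2$n_pulses, 2L)
  expect_equal(sort(f2$pulses$center), c(25, 65), tolerance = 1.5 / 25)
})

test_that("pulse counts never buy a worse squared error", {
  # nestedness: compare each fit against fits with the count forced lower
  set.seed(31)
  for (rep in 1:5) {
    pt <- generate_pulse_train(pulse_train_spec(rate = 2, refractory = 15),
                               90)
    tr <- generate_trace(pt, trace_spec(noise_sd = 0.02))
    full <- fit_trace(tr)
    if (full$n_pulses == 0) next
    for (k in 0:(full$n_pulses - 1)) {
      capped <- fit_trace(tr, fit_config(max_pulses = k))
      expect_lte(full$sse, capped$sse + 1e-9)
    }
  }
})

test_that("classification follows the amplitude threshold rule", {
  flat <- structure(list(n_pulses = 0L, basal = 1, pulses = pulse_params(),
                         sse = 0, threshold = 0.05), class = "pulse_fit")
  expect_equal(classify_cell(flat, 0.03), "pulse-")
  hit <- structure(list(n_pulses = 1L, basal = 1,
                        pulses = pulse_params(0.05, 45, pi / 10),
                        sse = 0, threshold = 0.03), class = "pulse_fit")
  expect_equal(classify_cell(hit, 0.03), "pulse+")   # 5 sigma vs 3 sigma
  expect_equal(classify_cell(hit, 0.05), "pulse-")   # strictly greater only
  expect_error(classify_cell(hit, -1), "nonnegative")
})

test_that("the robust noise estimator recovers sigma raw and smoothed", {
  set.seed(12)
  sigma <- 0.02
  raw <- replicate(200, estimate_noise_sd(rnorm(61, 1, sigma), 1))
  expect_lt(abs(median(raw) - sigma) / sigma, 0.1)
  sm <- replicate(200, {
    tr <- trace((0:60) * 1.5, rnorm(61, 1, sigma))
    estimate_noise_sd(moving_average(tr, 6)$value, 5)
  })
  # the estimator reports the noise sd on the smoothed trace: sigma/sqrt(5)
  expect_lt(abs(median(sm) - sigma / sqrt(5)) / (sigma / sqrt(5)), 0.15)
  # and it must ignore pulses riding on the noise
  withpulse <- replicate(50, {
    v <- rnorm(61, 1, sigma) +
      0.2 * pulse_basis((0:60) * 1.5 - 45, 2 * pi / 20)
    estimate_noise_sd(v, 1)
  })
  expect_lt(abs(median(withpulse) - sigma) / sigma, 0.25)
})

test_that("pulse metrics are plain arithmetic on the fit", {
  f <- structure(list(n_pulses = 3L, basal = 1,
                      pulses = pulse_params(c(0.1, 0.2, 0.3), c(10, 40, 70),
                                            c(pi / 10, pi / 5, pi / 15)),
                      sse = 0, recording_duration = 90), class = "pulse_fit")
  m <- pulse_metrics(f)
  expect_equal(m$frequency_per_h, 2)           # 3 pulses / 90 min
  expect_equal(sort(m$durations_min), c(10, 20, 30))
  expect_equal(m$peak_heights, 2 * m$amplitudes)
  f0 <- structure(list(n_pulses = 0L, basal = 1, pulses = pulse_params(),
                       sse = 0, recording_duration = 90),
                  class = "pulse_fit")
  m0 <- pulse_metrics(f0)
  expect_equal(m0$frequency_per_h, 0)
  expect_equal(length(m0$durations_min), 0L)
})

test_that("degenerate inputs are rejected with clear errors", {
  short <- trace(c(0, 1.5, 3, 4.5), c(1, 1.1, 1, 1))
  expect_error(fit_trace(short), "shorter")
  tr <- generate_trace(pulse_params(), trace_spec(), seed = 2)
  tr$value[5] <- NA
  expect_error(fit_trace(tr), "complete")
  expect_error(fit_config(duration_bounds = c(10, 5)), "duration_bounds")
})
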