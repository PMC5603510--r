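flat_trace <- function(level = 100, n = 401, well = "B2") {
  structure(list(well_id = well, samples = rep(level, n), dt = 0.1,
                 duration = (n - 1) * 0.1, ground_truth = NULL),
            class = "calcium_trace")
}

noise_trace <- function(sd = 1, n = 2001, seed = 1) {
  set.seed(seed)
  structure(list(well_id = "N1", samples = rnorm(n, 100, sd), dt = 0.1,
                 duration = (n - 1) * 0.1, ground_truth = NULL),
            class = "calcium_trace")
}

test_that("noise floor is the scaled pooled SD of detrended controls", {
  expect_equal(estimate_noise_floor(list(flat_trace())), 0)
  # white noise sd 1, multiplier 3 -> about 3
  f <- estimate_noise_floor(list(noise_trace(sd = 1, seed = 2)),
                            multiplier = 3)
  expect_lt(abs(f - 3) / 3, 0.10)
  # pooled over two traces of equal sd stays at that sd
  f2 <- estimate_noise_floor(list(noise_trace(sd = 1, seed = 3),
                                  noise_trace(sd = 1, seed = 4)),
                             multiplier = 1)
  expect_lt(abs(f2 - 1), 0.10)
  # a linear drift is removed before pooling
  drift <- flat_trace()
  drift$samples <- drift$samples + seq(0, 50, length.out = 401)
  expect_lt(estimate_noise_floor(list(drift)), 1e-8)
  expect_error(estimate_noise_floor(list()), "at least one")
})

test_that("peak detection recovers planted amplitude and frequency exactly", {
  tr <- synthesize_trace(baseline = 100, amplitude = 50, frequency = 1,
                         noise_sd = 0)
  pf <- detect_peaks(tr, noise_floor = 1)
  expect_equal(pf$peak_count, 40)
  expect_equal(pf$mean_peak_magnitude, 50)
  expect_equal(pf$peak_magnitudes, rep(50, 40))

  flat <- flat_trace()
  pf0 <- detect_peaks(flat, noise_floor = 1)
  expect_equal(pf0$peak_count, 0)
  expect_true(is.na(pf0$mean_peak_magnitude))

  # single triangular peak of height 5 on baseline 1
  tri <- flat_trace(level = 1, n = 21)
  tri$samples[8:12] <- c(3.5, 6, 3.5, 1, 1)
  pf1 <- detect_peaks(tri, noise_floor = 0.5)
  expect_equal(pf1$peak_count, 1)
  expect_equal(pf1$mean_peak_magnitude, 5)
})

test_that("peak detection is robust to noise and monotone in the floor", {
  for (seed in 1:5) {
    tr <- synthesize_trace(baseline = 100, amplitude = 50, frequency = 1,
                           noise_sd = 2.5, seed = seed)  # 5% of amplitude
    pf <- detect_peaks(tr, noise_floor = 7.5)
    expect_equal(pf$peak_count, 40)
    expect_lt(abs(pf$mean_peak_magnitude - 50) / 50, 0.10)
    # raising the floor never increases the count
    floors <- c(1, 5, 15, 30, 45, 60)
    counts <- vapply(floors, function(f) detect_peaks(tr, f)$peak_count,
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("peak magnitudes scale with the trace, counts do not", {
  tr <- synthesize_trace(baseline = 100, amplitude = 40, frequency = 0.5,
                         noise_sd = 1, seed = 3)
  pf <- detect_peaks(tr, noise_floor = 5)
  tr2 <- tr
  tr2$samples <- tr$samples * 2.5
  pf2 <- detect_peaks(tr2, noise_floor = 5 * 2.5)
  expect_equal(pf2$peak_count, pf$peak_count)
  expect_equal(pf2$mean_peak_magnitude, 2.5 * pf$mean_peak_magnitude)
})

test_that("screen-level trace analysis uses the lethal-control floor", {
  scr <- tiny_screen(seed = 19)
  feats <- analyze_screen_traces(scr)
  expect_equal(nrow(feats), nrow(scr$plate_map))
  # floor should be close to 3 x the additive trace noise (sd 1)
  expect_lt(abs(feats$noise_floor[1] - 3) / 3, 0.15)
  # beating wells recover their planted peak counts exactly
  gt <- scr$ground_truth
  beating <- gt$role %in% c("blank", "vehicle", "test")
  expect_equal(feats$peak_count[beating], gt$true_peak_count[beating])
  lethal <- feats[scr$plate_map$role == "lethal_control", ]
  expect_true(all(lethal$peak_count == 0))
})

test_that("contractility metrics recover planted beat geometry", {
  ft <- synthesize_force_trace(amplitude = 10, pacing_hz = 1,
                               contraction_slope = 100,
                               relaxation_slope = 50, duration = 10,
                               dt = 0.01)
  cm <- contraction_metrics(ft)
  expect_equal(cm$active_tension, 10)
  expect_equal(cm$contraction_slope, 100)
  expect_equal(cm$relaxation_slope, 50)
  expect_equal(cm$n_beats, 10)
  # 10%-threshold duration of an ideal triangle beat: 0.9 * (rise + fall)
  expect_equal(cm$beat_duration, 0.9 * 0.3, tolerance = 1e-6)
  expect_lte(cm$beat_duration, 1 / ft$pacing_hz)

  expect_error(contraction_metrics(synthesize_force_trace(amplitude = 0)),
               "no beats")

  # two identical beats average to the single-beat metrics
  two <- synthesize_force_trace(amplitude = 10, pacing_hz = 1,
                                contraction_slope = 100,
                                relaxation_slope = 50, duration = 2,
                                dt = 0.01)
  cm2 <- contraction_metrics(two)
  expect_equal(cm2$active_tension, cm$active_tension)
  expect_equal(cm2$contraction_slope, cm$contraction_slope)

  # scale equivariance: force units scale tension and slopes, not durations
  sc <- ft
  sc$samples <- ft$samples * 3
  cms <- contraction_metrics(sc)
  expect_equal(cms$active_tension, 30)
  expect_equal(cms$contraction_slope, 300)
  expect_equal(cms$beat_duration, cm$beat_duration)

  # secant slopes agree with planted slopes up to threshold geometry
  cmsec <- contraction_metrics(ft, method = "secant")
  expect_equal(cmsec$active_tension, 10)
  expect_lt(abs(cmsec$contraction_slope - 100) / 100, 0.15)
})
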