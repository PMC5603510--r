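test_that("registry covers every target and is reproducible", {
  reg <- make_registry(80, 23, seed = 7)
  expect_equal(nrow(reg), 80)
  expect_equal(sort(unique(reg$kinase_target)), 1:23)
  expect_false(anyDuplicated(reg$compound_id) > 0)
  expect_identical(reg, make_registry(80, 23, seed = 7))
  expect_false(identical(reg$kinase_target,
                         make_registry(80, 23, seed = 8)$kinase_target))

  one <- make_registry(1, 1, seed = 0)
  expect_equal(nrow(one), 1)
  bij <- make_registry(5, 5, seed = 3)
  expect_equal(sort(bij$kinase_target), 1:5)
  expect_error(make_registry(3, 5), "exceed")
})

test_that("plate maps hold the screen geometry and reference roles", {
  reg <- make_registry(80, 23, seed = 7)
  pm <- make_plate_maps(reg, c(0.1, 1, 10), replicates = 3)
  test_wells <- pm[pm$role == "test", ]
  expect_equal(nrow(test_wells), 720)
  # each compound: 3 concentrations x 3 replicates
  per <- dplyr::count(test_wells, compound_id, concentration_uM)
  expect_true(all(per$n == 3))
  expect_equal(sort(unique(test_wells$concentration_uM)), c(0.1, 1, 10))
  # every plate carries all five reference roles and >= 3 blanks
  roles <- dplyr::count(pm, plate_id, role)
  ref_roles <- c("blank", "vehicle", "positive_chronotrope",
                 "negative_chronotrope", "lethal_control")
  for (p in unique(pm$plate_id)) {
    have <- roles[roles$plate_id == p, ]
    expect_true(all(ref_roles %in% have$role))
    expect_gte(have$n[have$role == "blank"], 3)
  }
  # wells unique within plate and inside the 384-well grid
  expect_false(any(duplicated(pm[, c("plate_id", "well_id")])))
  expect_true(all(pm$well_id %in% cardioscreen:::well_grid_384()))
  expect_true(all(table(pm$plate_id) <= 384))
  # conservation: every test (compound, concentration) exists in the registry
  expect_true(all(test_wells$compound_id %in% reg$compound_id))
  expect_equal(
    reg$kinase_target[match(test_wells$compound_id, reg$compound_id)],
    test_wells$kinase_target)
})

test_that("plate maps split automatically and validate arguments", {
  reg <- make_registry(1, 1, seed = 0)
  pm1 <- make_plate_maps(reg, 1, replicates = 1)
  expect_equal(sum(pm1$role == "test"), 1)
  expect_equal(length(unique(pm1$plate_id)), 1)

  big <- make_registry(80, 23, seed = 7)
  pm <- make_plate_maps(big, c(0.1, 1, 10), replicates = 3)
  expect_gt(length(unique(pm$plate_id)), 1)

  expect_error(make_plate_maps(big, numeric(0)), "nonempty")
  expect_error(make_plate_maps(big, c(0.1, 1, 10), replicates = 0), ">= 1")
})

test_that("synthetic calcium traces honour the planted ground truth", {
  tr <- synthesize_trace(baseline = 100, amplitude = 50, frequency = 1,
                         noise_sd = 0)
  expect_length(tr$samples, 401)
  expect_equal(tr$ground_truth$peak_count, 40)
  expect_equal(max(tr$samples), 150)
  expect_equal(min(tr$samples), 100)

  flat <- synthesize_trace(amplitude = 50, frequency = 0, noise_sd = 0)
  expect_true(all(flat$samples == flat$samples[1]))
  dead <- synthesize_trace(amplitude = 0, frequency = 1, noise_sd = 0)
  expect_true(all(dead$samples == 100))

  expect_error(synthesize_trace(amplitude = -1), "amplitude")
  expect_error(synthesize_trace(noise_sd = -1), "noise_sd")
  expect_error(synthesize_trace(dt = 0.3, duration = 40), "divide")

  a <- synthesize_trace(noise_sd = 2, seed = 5)
  b <- synthesize_trace(noise_sd = 2, seed = 5)
  expect_identical(a$samples, b$samples)
})

test_that("synthetic counts follow the closed-form viability model", {
  cc <- synthesize_counts(baseline_total = 8000, count_mult = 1,
                          viability_mult = 1, control_viability = 0.9,
                          count_cv = 0, viability_cv = 0)
  expect_equal(cc$total_cells, 8000L)
  expect_equal(cc$dead_cells, 800L)

  dead <- synthesize_counts(baseline_total = 100, viability_mult = 0)
  expect_equal(dead$dead_cells, dead$total_cells)
  expect_error(synthesize_counts(baseline_total = 0), "baseline_total")

  noisy <- synthesize_counts(baseline_total = 5000, count_cv = 0.1,
                             viability_cv = 0.05, seed = 9)
  expect_lte(noisy$dead_cells, noisy$total_cells)
  expect_identical(noisy,
                   synthesize_counts(baseline_total = 5000, count_cv = 0.1,
                                     viability_cv = 0.05, seed = 9))
})

test_that("synthetic force traces are piecewise-linear beat trains", {
  ft <- synthesize_force_trace(amplitude = 10, pacing_hz = 1,
                               contraction_slope = 100,
                               relaxation_slope = 50, duration = 10)
  expect_equal(ft$ground_truth$beat_duration, 0.3)  # 0.1 rise + 0.2 fall
  expect_equal(ft$ground_truth$n_beats, 10)
  expect_equal(max(ft$samples), 10)

  flat <- synthesize_force_trace(amplitude = 0)
  expect_true(all(flat$samples == 0))

  # a beat longer than the pacing period cannot be laid down
  expect_error(
    synthesize_force_trace(amplitude = 10, pacing_hz = 2,
                           contraction_slope = 20, relaxation_slope = 20),
    "pacing period")
  expect_error(synthesize_force_trace(contraction_slope = 0), "> 0")
})

test_that("screen generation is bit-reproducible and closed over the registry", {
  s1 <- tiny_screen(seed = 11)
  s2 <- tiny_screen(seed = 11)
  expect_identical(s1$counts, s2$counts)
  expect_identical(lapply(s1$traces, `[[`, "samples"),
                   lapply(s2$traces, `[[`, "samples"))
  tw <- s1$plate_map[s1$plate_map$role == "test", ]
  expect_true(all(paste(tw$compound_id, tw$concentration_uM) %in%
                    paste(s1$model$effects$compound_id,
                          s1$model$effects$concentration_uM)))
  # lethal-control wells are flat at baseline (plus noise only)
  gt <- s1$ground_truth
  expect_true(all(gt$true_amplitude[gt$role == "lethal_control"] == 0))
})
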