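#' Synthesize a calcium-flux trace
#'
#' Builds a fluorescence trace sampled every `dt` seconds for `duration`
#' seconds (default 0.1 s for 40 s, i.e. 401 samples including t = 0) from a
#' planted transient model: compact Gaussian-shaped peaks of height
#' `amplitude` above `baseline`, one per beat at `frequency` Hz, plus
#' additive Gaussian noise.  Peak bumps are truncated so that the inter-peak
#' valley returns exactly to baseline; with zero noise and peak centres on
#' the sample grid, each peak's maximum-minus-valley magnitude equals the
#' planted amplitude exactly, which is what makes downstream recovery
#' testable.
#'
#' The number of planted peaks is `floor(duration * frequency)`, with peak
#' centres at `(k - 1/2) / frequency`.
#'
#' @param baseline Resting fluorescence level (arbitrary units).
#' @param amplitude Peak height above baseline; 0 gives a flat (non-beating)
#'   trace such as a lethal-control well.
#' @param frequency Beat frequency in Hz; 0 gives a flat trace.
#' @param width Gaussian peak width (SD) in seconds.
#' @param noise_sd SD of additive Gaussian noise (arbitrary units).
#' @param dt Sampling interval in seconds; must divide `duration`.
#' @param duration Trace length in seconds.
#' @param seed Integer seed for the noise draw.
#' @param well_id Label attached to the trace.
#' @return An object of class `calcium_trace`: a list with `well_id`,
#'   `samples`, `dt`, `duration`, and a `ground_truth` list recording the
#'   planted amplitude, frequency and peak count.
#' @export
synthesize_trace <- function(baseline = 100, amplitude = 50, frequency = 1,
                             width = 0.08, noise_sd = 0, dt = 0.1,
                             duration = 40, seed = 1L, well_id = "A1") {
  assert_scalar_number(amplitude, "amplitude", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(frequency, "frequency", min = 0)
  assert_scalar_number(dt, "dt", min = 0, strict_min = TRUE)
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stopf("`dt` must divide `duration`")
  }
  t <- seq(0, duration, by = dt)
  x <- rep(baseline, length(t))
  n_peaks <- 0L
  if (frequency > 0 && amplitude > 0) {
    n_peaks <- as.integer(floor(duration * frequency))
    period <- 1 / frequency
    cutoff <- min(4 * width, period / 2)
    centres <- (seq_len(n_peaks) - 0.5) * period
    for (ck in centres) {
      idx <- which(abs(t - ck) <= cutoff)
      x[idx] <- x[idx] + amplitude * exp(-0.5 * ((t[idx] - ck) / width)^2)
    }
  }
  if (noise_sd > 0) {
    x <- x + with_seed(seed, rnorm(length(t), 0, noise_sd))
  }
  structure(
    list(well_id = well_id, samples = x, dt = dt, duration = duration,
         ground_truth = list(amplitude = amplitude, frequency = frequency,
                             peak_count = n_peaks, baseline = baseline)),
    class = "calcium_trace"
  )
}

#' Synthesize per-well cell counts
#'
#' Draws the 24-hour total and dead cell counts for one well from the planted
#' effect model: the total is the seeded baseline times the count multiplier,
#' and the dead fraction follows from a control viability scaled by the
#' viability multiplier, both with optional lognormal well noise.
#'
#' @param baseline_total Expected total cells in an unperturbed well; must be
#'   positive.
#' @param count_mult,viability_mult Planted multiplicative effects.
#' @param control_viability Live fraction in control wells (default 0.9).
#' @param count_cv,viability_cv Lognormal coefficients of variation.
#' @param seed Integer seed.
#' @param well_id Label attached to the counts.
#' @return A list of class `cell_counts` with `well_id`, `total_cells`,
#'   `dead_cells` and a `ground_truth` viability.
#' @export
synthesize_counts <- function(baseline_total = 8000, count_mult = 1,
                              viability_mult = 1, control_viability = 0.9,
                              count_cv = 0, viability_cv = 0, seed = 1L,
                              well_id = "A1") {
  assert_scalar_number(baseline_total, "baseline_total", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(count_mult, "count_mult", min = 0)
  assert_scalar_number(viability_mult, "viability_mult", min = 0)
  noise <- with_seed(seed, rnorm(2))
  total <- baseline_total * count_mult *
    if (count_cv > 0) exp(noise[1] * count_cv) else 1
  viab <- control_viability * viability_mult *
    if (viability_cv > 0) exp(noise[2] * viability_cv) else 1
  viab <- min(max(viab, 0), 1)
  total <- as.integer(max(0, round(total)))
  dead <- as.integer(round(total * (1 - viab)))
  structure(
    list(well_id = well_id, total_cells = total, dead_cells = dead,
         ground_truth = list(viability = viab)),
    class = "cell_counts"
  )
}

#' Synthesize an engineered-tissue force trace
#'
#' Generates a paced contraction force trace as a train of piecewise-linear
#' beats: from each pacing onset the force rises at `contraction_slope` to
#' `amplitude`, then falls at `relaxation_slope` back to the resting
#' baseline.  The implied beat duration `amplitude / contraction_slope +
#' amplitude / relaxation_slope` must fit inside one pacing period.
#'
#' @param amplitude Active tension in microNewtons; 0 gives a flat trace.
#' @param pacing_hz Pacing frequency in Hz.
#' @param contraction_slope,relaxation_slope Rise and fall rates in
#'   microNewtons per second; both must be positive.
#' @param duration Trace length in seconds.
#' @param dt Sampling interval in seconds.
#' @param baseline Resting force (default 0).
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed Integer seed.
#' @param tissue_id Label attached to the trace.
#' @return An object of class `force_trace`: a list with `tissue_id`,
#'   `samples`, `dt`, `pacing_hz`, and a `ground_truth` list with the planted
#'   active tension, beat duration and slopes.
#' @export
synthesize_force_trace <- function(amplitude = 10, pacing_hz = 1,
                                   contraction_slope = 100,
                                   relaxation_slope = 50,
                                   duration = 10, dt = 0.01, baseline = 0,
                                   noise_sd = 0, seed = 1L,
                                   tissue_id = "T1") {
  assert_scalar_number(amplitude, "amplitude", min = 0)
  assert_scalar_number(contraction_slope, "contraction_slope", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(relaxation_slope, "relaxation_slope", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(pacing_hz, "pacing_hz", min = 0, strict_min = TRUE)
  rise <- amplitude / contraction_slope
  fall <- amplitude / relaxation_slope
  if (amplitude > 0 && rise + fall > 1 / pacing_hz) {
    stopf("beat duration %.3f s exceeds the pacing period %.3f s",
          rise + fall, 1 / pacing_hz)
  }
  t <- seq(0, duration, by = dt)
  x <- rep(baseline, length(t))
  n_beats <- as.integer(floor(duration * pacing_hz))
  if (amplitude > 0) {
    for (k in seq_len(n_beats) - 1L) {
      s <- k / pacing_hz
      phase <- t - s
      on_rise <- phase >= 0 & phase <= rise
      on_fall <- phase > rise & phase <= rise + fall
      x[on_rise] <- baseline + contraction_slope * phase[on_rise]
      x[on_fall] <- baseline + amplitude -
        relaxation_slope * (phase[on_fall] - rise)
    }
  }
  if (noise_sd > 0) {
    x <- x + with_seed(seed, rnorm(length(t), 0, noise_sd))
  }
  structure(
    list(tissue_id = tissue_id, samples = x, dt = dt, pacing_hz = pacing_hz,
         duration = duration,
         ground_truth = list(active_tension = amplitude,
                             beat_duration = if (amplitude > 0) rise + fall else 0,
                             contraction_slope = contraction_slope,
                             relaxation_slope = relaxation_slope,
                             n_beats = n_beats)),
    class = "force_trace"
  )
}

#' Generate a complete synthetic screen
#'
#' Produces every artifact of one monolayer screening campaign from a planted
#' effect model: plate maps, a calcium-flux trace per well and 24-hour cell
#' counts per well, with per-well noise drawn from a single seeded stream so
#' the whole screen is bit-reproducible.
#'
#' @param registry A `compound_registry`.
#' @param model An `effect_model` built on the same registry.
#' @param plate_map Optional pre-built `plate_map`; defaults to
#'   [make_plate_maps()] on the registry.
#' @param trace_params List of control-level trace parameters: `baseline`,
#'   `amplitude`, `frequency` (Hz), `width` (s), `noise_sd`.
#' @param count_params List with `baseline_total` and `control_viability`.
#' @param seed Integer seed for all well-level noise.
#' @return A list of class `synthetic_screen` with elements `registry`,
#'   `model`, `plate_map`, `traces` (named list of `calcium_trace`, keyed
#'   `plate:well`), `counts` (tibble) and `ground_truth` (tibble of per-well
#'   planted values).
#' @export
generate_screen <- function(registry, model, plate_map = NULL,
                            trace_params = list(baseline = 100, amplitude = 50,
                                                frequency = 1, width = 0.08,
                                                noise_sd = 1),
                            count_params = list(baseline_total = 8000,
                                                control_viability = 0.9),
                            seed = 1L) {
  stopifnot(inherits(registry, "compound_registry"),
            inherits(model, "effect_model"))
  if (is.null(plate_map)) plate_map <- make_plate_maps(registry)
  cv <- model$noise_cv

  traces <- vector("list", nrow(plate_map))
  counts <- vector("list", nrow(plate_map))
  truth <- vector("list", nrow(plate_map))

  for (i in seq_len(nrow(plate_map))) {
    w <- plate_map[i, ]
    mult <- effect_multipliers(model, w$role, w$compound_id,
                               w$concentration_uM)
    wseed <- derive_seed(seed, i)
    # lognormal well-to-well variation on amplitude and frequency
    jit <- with_seed(derive_seed(wseed, 1L), rnorm(2))
    amp_eff <- trace_params$amplitude * mult$magnitude *
      if (cv[["magnitude"]] > 0) exp(jit[1] * cv[["magnitude"]]) else 1
    freq_eff <- trace_params$frequency * mult$frequency *
      if (cv[["frequency"]] > 0) exp(jit[2] * cv[["frequency"]]) else 1
    if (mult$magnitude == 0) amp_eff <- 0
    if (mult$frequency == 0) freq_eff <- 0

    key <- paste(w$plate_id, w$well_id, sep = ":")
    tr <- synthesize_trace(
      baseline = trace_params$baseline, amplitude = amp_eff,
      frequency = freq_eff, width = trace_params$width,
      noise_sd = trace_params$noise_sd, seed = derive_seed(wseed, 2L),
      well_id = w$well_id
    )
    cc <- synthesize_counts(
      baseline_total = count_params$baseline_total,
      count_mult = mult$count, viability_mult = mult$viability,
      control_viability = count_params$control_viability,
      count_cv = cv[["counts"]], viability_cv = cv[["viability"]],
      seed = derive_seed(wseed, 3L), well_id = w$well_id
    )
    traces[[i]] <- tr
    names(traces)[i] <- key
    counts[[i]] <- tibble::tibble(
      plate_id = w$plate_id, well_id = w$well_id,
      total_cells = cc$total_cells, dead_cells = cc$dead_cells
    )
    truth[[i]] <- tibble::tibble(
      plate_id = w$plate_id, well_id = w$well_id, role = w$role,
      compound_id = w$compound_id, concentration_uM = w$concentration_uM,
      true_amplitude = amp_eff, true_frequency = freq_eff,
      true_peak_count = tr$ground_truth$peak_count,
      true_viability = cc$ground_truth$viability
    )
  }

  structure(
    list(registry = registry, model = model, plate_map = plate_map,
         traces = traces, counts = dplyr::bind_rows(counts),
         ground_truth = dplyr::bind_rows(truth), seed = as.integer(seed),
         trace_params = trace_params, count_params = count_params),
    class = "synthetic_screen"
  )
}
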