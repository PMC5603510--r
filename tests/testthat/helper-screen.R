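# Small screen fixtures built in code.

tiny_screen <- function(n_compounds = 5, n_targets = 2, seed = 42,
                        noise = TRUE) {
  reg <- make_registry(n_compounds, n_targets, seed = seed)
  em <- make_effect_model(
    reg, seed = seed + 1,
    noise_cv = if (noise) {
      c(magnitude = 0.05, frequency = 0.02, viability = 0.02, counts = 0.05)
    } else {
      c(magnitude = 0, frequency = 0, viability = 0, counts = 0)
    }
  )
  trace_noise <- if (noise) 1 else 0
  generate_screen(reg, em,
                  trace_params = list(baseline = 100, amplitude = 50,
                                      frequency = 1, width = 0.08,
                                      noise_sd = trace_noise),
                  seed = seed + 2)
}

screen_records <- function(screen, ...) {
  feats <- analyze_screen_traces(screen, ...)
  wells <- well_endpoints(screen$plate_map, feats, screen$counts)
  model_records(summarize_screen(wells)$screen)
}

with_seed_helper <- function(seed, code) {
  set.seed(seed)
  code
}

random_net <- function(seed, sizes = NULL, transfer = NULL) {
  set.seed(seed)
  if (is.null(sizes)) {
    n_in <- sample(1:4, 1)
    hidden <- sample(1:5, sample(1:2, 1), replace = TRUE)
    sizes <- c(n_in, hidden, 1L)
  }
  if (is.null(transfer)) {
    transfer <- c(sample(c("tansig", "logsig"), length(sizes) - 2L,
                         replace = TRUE), "purelin")
  }
  mlp_network(sizes, transfer, seed = seed)
}
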