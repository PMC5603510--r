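#' Build a blinded compound registry
#'
#' Creates the compound library for a screen: each compound carries a blinded
#' integer label and is assigned to exactly one kinase target.  The default
#' screen geometry is 80 blinded inhibitors spanning 23 kinase targets.
#' Every target receives at least one compound; targets beyond the first
#' `n_targets` compounds are assigned at random under `seed`.
#'
#' @param n_compounds Number of compounds (default 80).
#' @param n_targets Number of distinct kinase targets (default 23); must not
#'   exceed `n_compounds`.
#' @param seed Integer seed controlling the compound-to-target assignment.
#' @return A tibble of class `compound_registry` with columns `compound_id`
#'   (blinded integer label), `kinase_target` (integer code) and
#'   `target_name`.
#' @examples
#' reg <- make_registry(80, 23, seed = 7)
#' length(unique(reg$kinase_target))
#' @export
make_registry <- function(n_compounds = 80L, n_targets = 23L, seed = 1L) {
  assert_scalar_number(n_compounds, "n_compounds", min = 1)
  assert_scalar_number(n_targets, "n_targets", min = 1)
  n_compounds <- as.integer(n_compounds)
  n_targets <- as.integer(n_targets)
  if (n_targets > n_compounds) {
    stopf("`n_targets` (%d) must not exceed `n_compounds` (%d)",
          n_targets, n_compounds)
  }
  targets <- with_seed(seed, {
    base <- seq_len(n_targets)
    extra <- if (n_compounds > n_targets) {
      sample(seq_len(n_targets), n_compounds - n_targets, replace = TRUE)
    } else {
      integer(0)
    }
    c(base, extra)
  })
  out <- tibble::tibble(
    compound_id = seq_len(n_compounds),
    kinase_target = as.integer(targets),
    target_name = sprintf("KT%02d", targets)
  )
  class(out) <- c("compound_registry", class(out))
  out
}

#' Plant a ground-truth compound-effect model
#'
#' Defines multiplicative per-endpoint effects for every compound at every
#' concentration, the hidden truth the synthetic screen is generated from and
#' downstream analysis must recover.  The calcium-peak-magnitude effect is a
#' smooth surface: a per-target base effect spanning `effect_range`
#' (from strong suppression to a profound, up-to-3-fold increase) scaled by a
#' saturating dose response `d(c) = c / (c + 1)` in micromolar, plus a small
#' per-compound jitter.  Viability, live-cell and beat-frequency effects are
#' drawn small and mostly neutral-to-negative, matching the effect classes a
#' monolayer kinase-inhibitor screen typically shows.
#'
#' @param registry A `compound_registry`.
#' @param concentrations Test concentrations in micromolar.
#' @param effect_range Range of the per-target magnitude effect (added to a
#'   multiplier of 1 at full dose response).
#' @param jitter_sd SD of the per-compound deviation from its target's base
#'   magnitude effect.
#' @param frequency_effect Mean and SD of the per-compound beat-frequency
#'   effect at full dose response.
#' @param viability_effect Mean and SD of the per-compound viability and
#'   live-cell-count effects at full dose response.
#' @param noise_cv Named per-endpoint lognormal coefficients of variation for
#'   well-to-well noise (names `magnitude`, `frequency`, `viability`,
#'   `counts`).
#' @param seed Integer seed; identical seeds give bit-identical models.
#' @return An object of class `effect_model`: a list with `effects` (tibble of
#'   per compound x concentration multipliers), `noise_cv`, `planted` (the
#'   per-compound planted mean normalized magnitude effect, the ground truth
#'   for ranking recovery) and `seed`.
#' @export
make_effect_model <- function(registry,
                              concentrations = c(0.1, 1, 10),
                              effect_range = c(-0.8, 2),
                              jitter_sd = 0.05,
                              frequency_effect = c(mean = -0.03, sd = 0.02),
                              viability_effect = c(mean = -0.05, sd = 0.03),
                              noise_cv = c(magnitude = 0.05, frequency = 0.02,
                                           viability = 0.02, counts = 0.05),
                              seed = 1L) {
  stopifnot(inherits(registry, "compound_registry"))
  if (length(concentrations) == 0 || any(concentrations <= 0)) {
    stopf("`concentrations` must be a nonempty vector of positive values")
  }
  n_targets <- max(registry$kinase_target)
  base_effect <- if (n_targets > 1) {
    seq(effect_range[1], effect_range[2], length.out = n_targets)
  } else {
    mean(effect_range)
  }
  dose <- concentrations / (concentrations + 1)

  draws <- with_seed(seed, {
    n <- nrow(registry)
    list(
      mag = base_effect[registry$kinase_target] + rnorm(n, 0, jitter_sd),
      freq = rnorm(n, frequency_effect[["mean"]], frequency_effect[["sd"]]),
      viab = rnorm(n, viability_effect[["mean"]], viability_effect[["sd"]]),
      count = rnorm(n, viability_effect[["mean"]], viability_effect[["sd"]])
    )
  })

  effects <- tidyr::expand_grid(
    compound_id = registry$compound_id,
    concentration_uM = concentrations
  )
  i <- match(effects$compound_id, registry$compound_id)
  d <- dose[match(effects$concentration_uM, concentrations)]
  effects$magnitude_mult <- pmax(0.01, 1 + draws$mag[i] * d)
  effects$frequency_mult <- pmax(0, 1 + draws$freq[i] * d)
  effects$viability_mult <- pmax(0, 1 + draws$viab[i] * d)
  effects$count_mult <- pmax(0.01, 1 + draws$count[i] * d)

  planted <- effects |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(planted_effect = mean(.data$magnitude_mult - 1),
                     .groups = "drop")

  structure(
    list(effects = effects, noise_cv = noise_cv, planted = planted,
         registry = registry, seed = as.integer(seed)),
    class = "effect_model"
  )
}

# Look up the effect multipliers for one well. Reference roles override the
# compound effects: blanks and vehicle wells sit at control levels, the
# positive chronotrope speeds beating, the negative chronotrope suppresses
# both magnitude and rate, and the lethal control abolishes beating and kills
# the monolayer.
effect_multipliers <- function(model, role, compound_id = NA,
                               concentration = NA) {
  if (role == "test") {
    row <- model$effects[model$effects$compound_id == compound_id &
                           model$effects$concentration_uM == concentration, ]
    if (nrow(row) != 1L) {
      stopf("no effect entry for compound %s at %s uM",
            compound_id, concentration)
    }
    return(list(magnitude = row$magnitude_mult, frequency = row$frequency_mult,
                viability = row$viability_mult, count = row$count_mult))
  }
  switch(role,
    blank = ,
    vehicle = list(magnitude = 1, frequency = 1, viability = 1, count = 1),
    positive_chronotrope =
      list(magnitude = 1, frequency = 1.5, viability = 1, count = 1),
    negative_chronotrope =
      list(magnitude = 0.1, frequency = 0.3, viability = 1, count = 1),
    lethal_control =
      list(magnitude = 0, frequency = 0, viability = 0, count = 1),
    stopf("unknown well role '%s'", role)
  )
}
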