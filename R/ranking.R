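#' Default design-grid levels
#'
#' The constrained prediction grid factorizes as 13 x 11 x 11 = 1,573 rows
#' per compound: 13 log-spaced concentrations spanning the tested 0.1-10
#' micromolar range, 11 normalized-frequency levels confined to \[-0.05,
#' 0.05\] (essentially unchanged beating rate) and 11 normalized-viability
#' levels confined to \[0, 0.1\] (no viability loss), with normalized live
#' cells tied equal to normalized viability.  Over the default 80-compound
#' registry this gives 125,840 prediction points.  All ranges and level
#' counts are configuration.
#'
#' @param n_concentration,n_frequency,n_viability Level counts.
#' @param concentration_range Micromolar range (log-spaced levels).
#' @param frequency_range,viability_range Normalized-effect intervals.
#' @return A list of level vectors plus the `tie_live_to_viability` flag.
#' @export
default_grid_levels <- function(n_concentration = 13L, n_frequency = 11L,
                                n_viability = 11L,
                                concentration_range = c(0.1, 10),
                                frequency_range = c(-0.05, 0.05),
                                viability_range = c(0, 0.1)) {
  list(
    concentration_uM = 10^seq(log10(concentration_range[1]),
                              log10(concentration_range[2]),
                              length.out = n_concentration),
    norm_frequency = seq(frequency_range[1], frequency_range[2],
                         length.out = n_frequency),
    norm_viability = seq(viability_range[1], viability_range[2],
                         length.out = n_viability),
    tie_live_to_viability = TRUE
  )
}

#' Build the constrained prediction design grid
#'
#' The Cartesian product of the level sets, replicated for every compound in
#' the registry with the kinase-target code fixed to that compound's target.
#' Row count is exactly `n_compounds` times the product of the level counts.
#'
#' @param registry A `compound_registry`.
#' @param levels Level specification from [default_grid_levels()].
#' @return A tibble of class `design_grid` with columns `compound_id`,
#'   `kinase_target`, `concentration_uM`, `norm_frequency`,
#'   `norm_viability`, `norm_live_cells`.
#' @examples
#' g <- build_grid(make_registry(80, 23, seed = 7))
#' nrow(g)  # 125840
#' @export
build_grid <- function(registry, levels = default_grid_levels()) {
  stopifnot(inherits(registry, "compound_registry"))
  if (nrow(registry) == 0) stopf("registry must contain at least one compound")
  if (any(lengths(levels[c("concentration_uM", "norm_frequency",
                           "norm_viability")]) < 1)) {
    stopf("every grid dimension needs at least one level")
  }
  cell <- tidyr::expand_grid(
    concentration_uM = levels$concentration_uM,
    norm_frequency = levels$norm_frequency,
    norm_viability = levels$norm_viability
  )
  cell$norm_live_cells <- if (isTRUE(levels$tie_live_to_viability)) {
    cell$norm_viability
  } else {
    levels$norm_live_cells
  }
  grid <- tidyr::expand_grid(
    registry[, c("compound_id", "kinase_target")],
    cell
  )
  attr(grid, "rows_per_compound") <- nrow(cell)
  attr(grid, "levels") <- levels
  class(grid) <- c("design_grid", class(grid))
  grid
}

#' Predict over a design grid
#'
#' Evaluates a trained network at every grid row.
#'
#' @param net A trained single-output `mlp_net` (or an `mlp_fit`).
#' @param grid A `design_grid`.
#' @return The grid with a `predicted` column (normalized calcium peak
#'   magnitude).
#' @export
predict_grid <- function(net, grid) {
  if (inherits(net, "mlp_fit")) net <- net$net
  stopifnot(inherits(net, "mlp_net"))
  x <- prepare_inputs(grid, MODEL_INPUTS)
  out <- grid
  out$predicted <- mlp_forward(net, x)
  out
}

#' Rank compounds by mean predicted effect on calcium peak magnitude
#'
#' Averages the predicted normalized peak magnitude over each compound's
#' design-grid block and ranks compounds from least detrimental (highest
#' mean prediction, rank 1) to most detrimental (lowest mean).  Ties break
#' by ascending compound id.
#'
#' @param predictions Output of [predict_grid()], or any tibble with
#'   `compound_id`, `kinase_target` and `predicted`.
#' @return A tibble of class `compound_ranking`, ordered by rank, with
#'   columns `compound_id`, `kinase_target`, `mean_prediction`, `rank`;
#'   attributes `least_detrimental` and `most_detrimental` name the extreme
#'   compounds.
#' @export
rank_compounds <- function(predictions) {
  if (is.null(predictions) || nrow(predictions) == 0) {
    stopf("predictions must contain at least one compound")
  }
  ranking <- predictions |>
    dplyr::group_by(.data$compound_id, .data$kinase_target) |>
    dplyr::summarise(mean_prediction = mean(.data$predicted),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_prediction), .data$compound_id)
  ranking$rank <- seq_len(nrow(ranking))
  attr(ranking, "least_detrimental") <- ranking$compound_id[1]
  attr(ranking, "most_detrimental") <- ranking$compound_id[nrow(ranking)]
  class(ranking) <- c("compound_ranking", class(ranking))
  ranking
}
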