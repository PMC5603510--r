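#' Cell viability from total and dead counts
#'
#' Live cells are the total minus the dead; viability is the live fraction of
#' the total.
#'
#' @param total_cells Total cells per well (positive).
#' @param dead_cells Dead cells per well (0 to `total_cells`).
#' @return A list with `viability` (fraction in 0..1) and `live_cell_count`.
#'   Vectorized over wells.
#' @examples
#' viability(100, 10)  # 0.9, 90
#' @export
viability <- function(total_cells, dead_cells) {
  if (any(!is.finite(total_cells)) || any(total_cells <= 0)) {
    stopf("`total_cells` must be positive")
  }
  if (any(!is.finite(dead_cells)) || any(dead_cells < 0)) {
    stopf("`dead_cells` must be nonnegative")
  }
  if (any(dead_cells > total_cells)) {
    stopf("`dead_cells` cannot exceed `total_cells`")
  }
  live <- total_cells - dead_cells
  list(viability = live / total_cells, live_cell_count = live)
}

#' Normalize an endpoint against the blank-well mean
#'
#' The screen's dimensionless effect scale:
#' `normalized = (raw - blank_mean) / blank_mean`, so a well at control level
#' scores 0 and a doubling scores +1.
#'
#' @param raw Raw endpoint value(s).
#' @param blank_mean Mean of the same endpoint over the plate's blank wells;
#'   must be nonzero.
#' @return Normalized value(s), same length as `raw`.
#' @export
normalize_blank <- function(raw, blank_mean) {
  assert_scalar_number(blank_mean, "blank_mean")
  if (blank_mean == 0) stopf("degenerate blank: `blank_mean` is zero")
  (raw - blank_mean) / blank_mean
}

#' Invert blank normalization
#'
#' @param normalized Normalized value(s).
#' @param blank_mean Blank-well mean used in [normalize_blank()].
#' @return Raw value(s): `blank_mean * (normalized + 1)`.
#' @export
denormalize_blank <- function(normalized, blank_mean) {
  blank_mean * (normalized + 1)
}

#' Signed standard-deviation band code
#'
#' Codes a triplicate mean relative to the control distribution as a signed
#' integer band: `z = (mean - control_mean) / control_sd`, band =
#' `sign(z) * min(ceiling(|z|), 3)`.  Band 0 means the mean equals the
#' control; bands of magnitude 1, 2 and 3 mean the effect lies within 1, 2,
#' or at least 2 control SDs (capped at 3).  This is the coding behind the
#' screen heat map.
#'
#' @param triplicate_mean Mean(s) of the replicate wells.
#' @param control_mean,control_sd Control distribution parameters;
#'   `control_sd` must be positive.
#' @return Integer band(s) in -3..3.
#' @examples
#' sd_band(1.25, 1, 0.1)  # z = 2.5 -> +3
#' @export
sd_band <- function(triplicate_mean, control_mean, control_sd) {
  assert_scalar_number(control_sd, "control_sd", min = 0, strict_min = TRUE)
  z <- (triplicate_mean - control_mean) / control_sd
  as.integer(sign(z) * pmin(ceiling(abs(z)), 3))
}

#' One-way ANOVA with Fisher LSD comparisons against a control group
#'
#' Fits a one-way ANOVA over the replicate groups (via [stats::aov()]) and
#' performs Fisher's least-significant-difference t-tests of every group
#' against the control group, using the ANOVA residual mean square and its
#' degrees of freedom.  Degenerate tables with zero variance everywhere are
#' reported as non-significant with an undefined F.
#'
#' @param groups A named or unnamed list of numeric replicate vectors, each
#'   of length >= 2; at least two groups.
#' @param control_index Index of the control group (default 1).
#' @param alpha Significance level for the LSD flag (default 0.05).
#' @return A list with `f_statistic`, `p_value`, `df` (between, within), and
#'   `lsd`: a tibble with one row per non-control group (`group`, `diff`,
#'   `t`, `p`, `significant`).
#' @export
anova_lsd <- function(groups, control_index = 1L, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stopf("`groups` must be a list of at least two replicate sets")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stopf("every group needs at least two replicates")
  if (control_index < 1L || control_index > length(groups)) {
    stopf("`control_index` out of range")
  }
  if (is.null(names(groups))) {
    names(groups) <- sprintf("g%d", seq_along(groups))
  }
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = dat)
  tab <- suppressWarnings(stats::anova(fit))
  ms_within <- tab["Residuals", "Mean Sq"]
  df_within <- tab["Residuals", "Df"]
  f_stat <- tab["group", "F value"]
  p_val <- tab["group", "Pr(>F)"]
  # a numerically-zero residual mean square makes the F ratio meaningless:
  # significant only if the group means actually differ
  degenerate <- !is.finite(ms_within) ||
    ms_within <= .Machine$double.eps * max(abs(dat$value)^2, 1)
  if (degenerate) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) - min(means) > 0) {
      f_stat <- Inf
      p_val <- 0
    } else {
      f_stat <- NA_real_
      p_val <- NA_real_
    }
  }

  ctrl <- names(groups)[control_index]
  means <- vapply(groups, mean, numeric(1))
  others <- setdiff(seq_along(groups), control_index)
  lsd <- tibble::tibble(
    group = names(groups)[others],
    diff = unname(means[others] - means[control_index]),
    t = NA_real_, p = NA_real_, significant = FALSE
  )
  if (!degenerate) {
    se <- unname(sqrt(ms_within *
                        (1 / sizes[others] + 1 / sizes[control_index])))
    lsd$t <- lsd$diff / se
    lsd$p <- 2 * stats::pt(abs(lsd$t), df_within, lower.tail = FALSE)
    lsd$significant <- lsd$p < alpha
  } else if (isTRUE(is.infinite(f_stat))) {
    lsd$significant <- lsd$diff != 0
    lsd$p <- ifelse(lsd$diff != 0, 0, NA_real_)
  }
  list(f_statistic = f_stat, p_value = p_val,
       df = c(between = tab["group", "Df"], within = df_within),
       control = ctrl, lsd = lsd)
}

SCREEN_ENDPOINTS <- c("cell_viability", "live_cell_count",
                      "peak_magnitude", "frequency")

#' Per-well endpoint table for a screen
#'
#' Joins the plate map with peak features and cell counts to give one row per
#' well carrying all four endpoints: cell viability, live cell count,
#' calcium peak magnitude and transient frequency (peaks per recording
#' window).  Wells with no detected peaks contribute frequency 0 and an
#' undefined (NA) peak magnitude.
#'
#' @param plate_map A `plate_map`.
#' @param features Tibble from [analyze_screen_traces()].
#' @param counts Tibble with `plate_id`, `well_id`, `total_cells`,
#'   `dead_cells`.
#' @return A tibble, one row per well, with raw endpoint columns.
#' @export
well_endpoints <- function(plate_map, features, counts) {
  v <- viability(counts$total_cells, counts$dead_cells)
  counts <- dplyr::mutate(counts, cell_viability = v$viability,
                          live_cell_count = v$live_cell_count)
  plate_map |>
    dplyr::left_join(features, by = c("plate_id", "well_id")) |>
    dplyr::left_join(counts, by = c("plate_id", "well_id")) |>
    dplyr::mutate(peak_magnitude = .data$mean_peak_magnitude,
                  frequency = as.numeric(.data$peak_count))
}

#' Summarize a screen: normalize, average triplicates, band-code
#'
#' Normalizes every well's endpoints against the blank wells of its own
#' plate, averages replicates per compound x concentration, and codes each
#' triplicate mean into a signed SD band relative to the pooled blank
#' distribution.  Peak magnitude averages skip wells with no detected peaks.
#'
#' @param wells Tibble from [well_endpoints()].
#' @param control_role Role used as the normalization control (default
#'   `"blank"`; `"vehicle"` is the DMSO alternative).
#' @return A list with `screen` (tidy tibble: one row per compound x
#'   concentration x endpoint with `raw_mean`, `norm_mean`, `band`,
#'   `n_wells`), `wells_normalized` (per-well normalized values) and
#'   `blank_stats` (per plate x endpoint mean and SD of the control wells).
#' @export
summarize_screen <- function(wells, control_role = "blank") {
  long <- wells |>
    dplyr::select(dplyr::all_of(c("plate_id", "well_id", "role",
                                  "compound_id", "kinase_target",
                                  "concentration_uM", "replicate",
                                  SCREEN_ENDPOINTS))) |>
    tidyr::pivot_longer(dplyr::all_of(SCREEN_ENDPOINTS),
                        names_to = "endpoint", values_to = "raw")

  blank_stats <- long |>
    dplyr::filter(.data$role == control_role) |>
    dplyr::group_by(.data$plate_id, .data$endpoint) |>
    dplyr::summarise(blank_mean = mean(.data$raw, na.rm = TRUE),
                     blank_sd = sd(.data$raw, na.rm = TRUE),
                     .groups = "drop")
  if (any(!is.finite(blank_stats$blank_mean) | blank_stats$blank_mean == 0)) {
    stopf("degenerate blank: a plate has zero or undefined blank mean")
  }

  long <- long |>
    dplyr::left_join(blank_stats, by = c("plate_id", "endpoint")) |>
    dplyr::mutate(norm = (.data$raw - .data$blank_mean) / .data$blank_mean)

  # control distribution on the normalized scale, pooled across plates
  ctrl <- long |>
    dplyr::filter(.data$role == control_role) |>
    dplyr::group_by(.data$endpoint) |>
    dplyr::summarise(ctrl_mean = mean(.data$norm, na.rm = TRUE),
                     ctrl_sd = sd(.data$norm, na.rm = TRUE),
                     .groups = "drop")

  screen <- long |>
    dplyr::filter(.data$role == "test") |>
    dplyr::group_by(.data$compound_id, .data$kinase_target,
                    .data$concentration_uM, .data$endpoint) |>
    dplyr::summarise(raw_mean = mean(.data$raw, na.rm = TRUE),
                     norm_mean = mean(.data$norm, na.rm = TRUE),
                     n_wells = sum(is.finite(.data$norm)),
                     .groups = "drop") |>
    dplyr::left_join(ctrl, by = "endpoint") |>
    dplyr::mutate(band = ifelse(
      is.finite(.data$norm_mean) & .data$ctrl_sd > 0,
      sd_band_vec(.data$norm_mean, .data$ctrl_mean, .data$ctrl_sd),
      NA_integer_
    )) |>
    dplyr::select(-dplyr::all_of(c("ctrl_mean", "ctrl_sd")))

  list(screen = screen, wells_normalized = long, blank_stats = blank_stats)
}

# vectorized over control parameters too (internal)
sd_band_vec <- function(m, cm, cs) {
  z <- (m - cm) / cs
  as.integer(sign(z) * pmin(ceiling(abs(z)), 3))
}

#' Heat-map band matrix
#'
#' Pivots the tidy screen summary into the screen heat-map layout: one row
#' per compound (ordered by kinase target), one column per
#' endpoint x concentration, entries the signed SD band codes.
#'
#' @param screen Tidy tibble from [summarize_screen()]`$screen`.
#' @return An integer matrix with compound ids as row names.
#' @export
heatmap_matrix <- function(screen) {
  wide <- screen |>
    dplyr::mutate(col = paste0(.data$endpoint, "_",
                               .data$concentration_uM, "uM")) |>
    dplyr::arrange(.data$kinase_target, .data$compound_id) |>
    dplyr::select(dplyr::all_of(c("compound_id", "col", "band"))) |>
    tidyr::pivot_wider(names_from = "col", values_from = "band")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$compound_id
  m
}

#' Build neural-network training records from a screen summary
#'
#' One record per compound x concentration: inputs are the inhibitor
#' concentration, the kinase-target code and the normalized triplicate means
#' of frequency, viability and live cells; the output is the normalized
#' triplicate mean of calcium peak magnitude.  Records with any undefined
#' value are dropped.
#'
#' @param screen Tidy tibble from [summarize_screen()]`$screen`.
#' @return A tibble of class `model_records` with columns `compound_id`,
#'   `concentration_uM`, `kinase_target`, `norm_frequency`,
#'   `norm_viability`, `norm_live_cells`, `norm_magnitude`.
#' @export
model_records <- function(screen) {
  wide <- screen |>
    dplyr::select(dplyr::all_of(c("compound_id", "kinase_target",
                                  "concentration_uM", "endpoint",
                                  "norm_mean"))) |>
    tidyr::pivot_wider(names_from = "endpoint", values_from = "norm_mean") |>
    dplyr::rename(norm_frequency = "frequency",
                  norm_viability = "cell_viability",
                  norm_live_cells = "live_cell_count",
                  norm_magnitude = "peak_magnitude") |>
    dplyr::select(dplyr::all_of(c("compound_id", "concentration_uM",
                                  "kinase_target", "norm_frequency",
                                  "norm_viability", "norm_live_cells",
                                  "norm_magnitude")))
  wide <- wide[stats::complete.cases(wide) &
                 is.finite(wide$norm_magnitude), ]
  class(wide) <- c("model_records", class(wide))
  wide
}

#' Build control-network records from a screen summary
#'
#' The control (sanity-check) networks predict normalized viability from
#' normalized live cells and the kinase-target code, one network per
#' concentration stratum (three strata for the default screen).
#'
#' @param screen Tidy tibble from [summarize_screen()]`$screen`.
#' @return A tibble with columns `stratum` (concentration), `kinase_target`,
#'   `norm_live_cells`, `norm_viability`.
#' @export
control_records <- function(screen) {
  screen |>
    dplyr::filter(.data$endpoint %in% c("cell_viability",
                                        "live_cell_count")) |>
    dplyr::select(dplyr::all_of(c("compound_id", "kinase_target",
                                  "concentration_uM", "endpoint",
                                  "norm_mean"))) |>
    tidyr::pivot_wider(names_from = "endpoint", values_from = "norm_mean") |>
    dplyr::rename(stratum = "concentration_uM",
                  norm_viability = "cell_viability",
                  norm_live_cells = "live_cell_count") |>
    dplyr::select(dplyr::all_of(c("stratum", "compound_id", "kinase_target",
                                  "norm_live_cells", "norm_viability")))
}
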