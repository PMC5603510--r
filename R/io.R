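# All artifact CSVs are UTF-8, '.' decimal, exact headers; numeric columns
# are rounded to 10 significant digits so reruns are checksum-identical.
write_artifact_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 10)
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write / read a plate map CSV
#'
#' Columns: `plate_id`, `well_id`, `role`, `compound_id`, `kinase_target`,
#' `concentration_uM`, `replicate`.
#'
#' @param plate_map A `plate_map` tibble.
#' @param path Output file.
#' @return `path`, invisibly (writer); a `plate_map` tibble (reader).
#' @export
write_plate_map_csv <- function(plate_map, path) {
  cols <- c("plate_id", "well_id", "role", "compound_id", "kinase_target",
            "concentration_uM", "replicate")
  write_artifact_csv(plate_map[, cols], path)
}

#' @rdname write_plate_map_csv
#' @export
read_plate_map_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  out$compound_id <- as.integer(out$compound_id)
  out$kinase_target <- as.integer(out$kinase_target)
  out$replicate <- as.integer(out$replicate)
  class(out) <- c("plate_map", class(out))
  out
}

#' Write / read calcium traces as long-format CSV
#'
#' Columns: `well_id`, `t_s`, `value`; one file per plate.
#'
#' @param traces A named list of `calcium_trace` objects.
#' @param path Output file.
#' @return `path`, invisibly (writer); a named list of `calcium_trace`
#'   (reader).
#' @export
write_traces_csv <- function(traces, path) {
  long <- dplyr::bind_rows(lapply(traces, function(tr) {
    tibble::tibble(
      well_id = tr$well_id,
      t_s = seq(0, tr$duration, by = tr$dt),
      value = tr$samples
    )
  }))
  write_artifact_csv(long, path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_df <- split(df, factor(df$well_id, levels = unique(df$well_id)))
  out <- lapply(split_df, function(d) {
    dt <- d$t_s[2] - d$t_s[1]
    structure(
      list(well_id = d$well_id[1], samples = d$value, dt = dt,
           duration = d$t_s[length(d$t_s)], ground_truth = NULL),
      class = "calcium_trace"
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "well_id")
  out
}

#' Write / read cell counts CSV
#'
#' Columns: `well_id`, `total_cells`, `dead_cells`; one file per plate.
#'
#' @param counts Tibble with at least those columns.
#' @param path Output file.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_counts_csv <- function(counts, path) {
  write_artifact_csv(counts[, c("well_id", "total_cells", "dead_cells")],
                     path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write peak-feature and tissue-metric CSVs
#'
#' Feature columns: `well_id`, `peak_count`, `mean_peak_magnitude`,
#' `noise_floor`.  Tissue columns: `tissue_id`, `active_tension`,
#' `beat_duration_s`, `contraction_slope`, `relaxation_slope`.
#'
#' @param features Tibble from [analyze_screen_traces()].
#' @param metrics A list of `contraction_metrics` (or a single one).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  write_artifact_csv(
    features[, c("well_id", "peak_count", "mean_peak_magnitude",
                 "noise_floor")], path)
}

#' @rdname write_features_csv
#' @export
write_tissue_metrics_csv <- function(metrics, path) {
  if (inherits(metrics, "contraction_metrics")) metrics <- list(metrics)
  df <- dplyr::bind_rows(lapply(metrics, function(m) {
    tibble::tibble(tissue_id = m$tissue_id, active_tension = m$active_tension,
                   beat_duration_s = m$beat_duration,
                   contraction_slope = m$contraction_slope,
                   relaxation_slope = m$relaxation_slope)
  }))
  write_artifact_csv(df, path)
}

#' Serialize / restore a trained network as JSON
#'
#' Stores the architecture, weights, biases, scaling parameters and (for
#' fits) the RMSE and R-squared metrics.
#'
#' @param fit An `mlp_fit` or `mlp_net`.
#' @param path Output file.
#' @return `path`, invisibly (writer); an `mlp_fit`-like list with a
#'   restored `net` (reader).
#' @export
write_model_json <- function(fit, path) {
  net <- if (inherits(fit, "mlp_fit")) fit$net else fit
  obj <- list(
    sizes = net$sizes,
    transfer = net$transfer,
    weights = lapply(net$W, function(w) signif(as.numeric(w), 12)),
    biases = lapply(net$b, signif, 12),
    in_center = signif(net$in_center, 12),
    in_half = signif(net$in_half, 12),
    out_center = signif(net$out_center, 12),
    out_half = signif(net$out_half, 12),
    seed = net$seed
  )
  if (inherits(fit, "mlp_fit")) {
    obj$metrics <- list(train_rmse = fit$train_rmse,
                        test_rmse = fit$test_rmse, test_r2 = fit$test_r2,
                        epochs = fit$epochs,
                        architecture = fit$architecture)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$sizes)
  net <- mlp_network(sizes, obj$transfer, seed = obj$seed %||% 1L)
  net$W <- lapply(seq_along(net$W), function(l) {
    matrix(as.numeric(unlist(obj$weights[[l]])), sizes[l + 1], sizes[l])
  })
  net$b <- lapply(obj$biases, as.numeric)
  net$in_center <- as.numeric(obj$in_center)
  net$in_half <- as.numeric(obj$in_half)
  net$out_center <- as.numeric(obj$out_center)
  net$out_half <- as.numeric(obj$out_half)
  list(net = net, metrics = obj$metrics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
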