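#' Default pipeline configuration
#'
#' One nested list holds every knob of an end-to-end run: the generator
#' geometry (80 compounds, 23 targets, 0.1/1/10 micromolar in triplicate),
#' control-level trace and count parameters, the trace-analysis noise-floor
#' multiplier, the Levenberg-Marquardt and architecture-search settings, the
#' design-grid levels and the engineered-tissue (biowire) trace parameters.
#' A persisted config plus the same code version reproduces every output
#' byte for byte.
#'
#' @param seed Global integer seed; per-stage seeds are derived from it by
#'   fixed offsets.
#' @param out_dir Output directory for artifacts.
#' @return A nested configuration list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = "cardioscreen_run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    generator = list(
      n_compounds = 80L, n_targets = 23L,
      concentrations = c(0.1, 1, 10), replicates = 3L,
      n_blank = 6L, n_reference = 3L,
      trace = list(baseline = 100, amplitude = 50, frequency = 1,
                   width = 0.08, noise_sd = 1),
      counts = list(baseline_total = 8000, control_viability = 0.9)
    ),
    trace_analysis = list(floor_multiplier = 3),
    ann = list(train_fraction = 0.9, restarts = 3L, max_epochs = 1000L,
               lambda_init = 1e-3, lambda_up = 10, lambda_down = 0.1,
               min_gradient = 1e-7, candidates = "default"),
    grid = list(n_concentration = 13L, n_frequency = 11L, n_viability = 11L,
                concentration_range = c(0.1, 10),
                frequency_range = c(-0.05, 0.05),
                viability_range = c(0, 0.1)),
    biowire = list(n_tissues = 3L, amplitude = 10, pacing_hz = 1,
                   contraction_slope = 100, relaxation_slope = 50,
                   duration = 10, dt = 0.01, noise_sd = 0)
  ), class = "run_config")
}

#' Read a YAML configuration file
#'
#' Values in the file override the matching entries of [default_config()];
#' anything omitted keeps its default.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding both default and file.
#' @return A `run_config`.
#' @export
read_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- modify_config(default_config(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

modify_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
          !is.null(names(user[[nm]]))) {
      base[[nm]] <- modify_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

stage_path <- function(out_dir, ...) file.path(out_dir, ...)

candidate_grid_from_config <- function(ann) {
  if (identical(ann$candidates, "default")) return(default_candidates())
  if (is.data.frame(ann$candidates)) return(ann$candidates)
  # list form: list(list(hidden = c(5), transfer = "tansig"), ...)
  tibble::tibble(
    hidden = lapply(ann$candidates, function(c) as.integer(c$hidden)),
    transfer = vapply(ann$candidates, `[[`, character(1), "transfer")
  )
}

require_inputs <- function(stage, paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stopf("stage '%s' is missing inputs: %s (run the earlier stages first)",
          stage, paste(missing, collapse = ", "))
  }
}

#' Pipeline stages
#'
#' Each stage reads its inputs from `out_dir`, writes its artifacts back
#' there, and returns the artifact paths.  `stage_generate` synthesizes the
#' screen; `stage_traces` extracts peak features; `stage_screen` normalizes,
#' averages and band-codes; `stage_train` runs the architecture search and
#' fits the three per-concentration control networks; `stage_predict`
#' evaluates the winning network over the design grid; `stage_rank` orders
#' compounds by mean prediction; `stage_biowire` synthesizes force traces
#' and measures contractility.
#'
#' @param config A `run_config`.
#' @return Character vector of file paths written, invisibly.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_generate <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  g <- config$generator
  seed <- derive_seed(config$seed, 1L)
  registry <- make_registry(g$n_compounds, g$n_targets, seed = seed)
  model <- make_effect_model(registry, concentrations = g$concentrations,
                             seed = derive_seed(seed, 1L))
  pm <- make_plate_maps(registry, concentrations = g$concentrations,
                        replicates = g$replicates, n_blank = g$n_blank,
                        n_reference = g$n_reference)
  screen <- generate_screen(registry, model, plate_map = pm,
                            trace_params = g$trace, count_params = g$counts,
                            seed = derive_seed(seed, 2L))
  paths <- character(0)
  paths["registry"] <- stage_path(out, "registry.csv")
  write_artifact_csv(registry, paths["registry"])
  paths["plate_map"] <- stage_path(out, "plate_map.csv")
  write_plate_map_csv(pm, paths["plate_map"])
  for (p in unique(pm$plate_id)) {
    keys <- paste(p, pm$well_id[pm$plate_id == p], sep = ":")
    tp <- stage_path(out, sprintf("traces_%s.csv", p))
    write_traces_csv(screen$traces[keys], tp)
    paths[sprintf("traces_%s", p)] <- tp
    cp <- stage_path(out, sprintf("counts_%s.csv", p))
    write_counts_csv(screen$counts[screen$counts$plate_id == p, ], cp)
    paths[sprintf("counts_%s", p)] <- cp
  }
  paths["planted_effects"] <- stage_path(out, "planted_effects.csv")
  write_artifact_csv(model$planted, paths["planted_effects"])
  log_stage("generate", "%d wells over %d plate(s), %d compounds",
            nrow(pm), length(unique(pm$plate_id)), nrow(registry))
  invisible(paths)
}

#' @rdname pipeline-stages
#' @export
stage_traces <- function(config) {
  out <- config$out_dir
  require_inputs("traces", stage_path(out, "plate_map.csv"))
  pm <- read_plate_map_csv(stage_path(out, "plate_map.csv"))
  traces <- list()
  for (p in unique(pm$plate_id)) {
    tp <- stage_path(out, sprintf("traces_%s.csv", p))
    require_inputs("traces", tp)
    tr <- read_traces_csv(tp)
    names(tr) <- paste(p, names(tr), sep = ":")
    traces <- c(traces, tr)
  }
  screen <- list(plate_map = pm, traces = traces)
  feats <- analyze_screen_traces(
    screen, floor_multiplier = config$trace_analysis$floor_multiplier)
  path <- stage_path(out, "features.csv")
  write_features_csv(feats, path)
  log_stage("traces", "noise floor %.4g; %d wells analyzed",
            feats$noise_floor[1], nrow(feats))
  invisible(c(features = path))
}

#' @rdname pipeline-stages
#' @export
stage_screen <- function(config) {
  out <- config$out_dir
  require_inputs("screen", stage_path(out, c("plate_map.csv",
                                             "features.csv")))
  pm <- read_plate_map_csv(stage_path(out, "plate_map.csv"))
  feats <- tibble::as_tibble(
    utils::read.csv(stage_path(out, "features.csv")))
  # features.csv is per well in plate-map order; restore plate ids
  feats$plate_id <- pm$plate_id
  counts <- dplyr::bind_rows(lapply(unique(pm$plate_id), function(p) {
    cp <- stage_path(out, sprintf("counts_%s.csv", p))
    require_inputs("screen", cp)
    dplyr::mutate(read_counts_csv(cp), plate_id = p)
  }))
  wells <- well_endpoints(pm, feats, counts)
  summ <- summarize_screen(wells)
  paths <- c(screen = stage_path(out, "screen.csv"),
             heatmap = stage_path(out, "heatmap.csv"),
             records = stage_path(out, "records.csv"))
  write_artifact_csv(summ$screen, paths["screen"])
  hm <- heatmap_matrix(summ$screen)
  write_artifact_csv(cbind(compound_id = as.integer(rownames(hm)),
                           as.data.frame(hm)), paths["heatmap"])
  write_artifact_csv(model_records(summ$screen), paths["records"])
  log_stage("screen", "%d compound x concentration x endpoint rows",
            nrow(summ$screen))
  invisible(paths)
}

#' @rdname pipeline-stages
#' @export
stage_train <- function(config) {
  out <- config$out_dir
  require_inputs("train", stage_path(out, c("records.csv", "screen.csv")))
  records <- tibble::as_tibble(utils::read.csv(stage_path(out,
                                                          "records.csv")))
  ann <- config$ann
  candidates <- candidate_grid_from_config(ann)
  if (nrow(candidates) == 0) stopf("ANN candidate grid must be nonempty")
  seed <- derive_seed(config$seed, 4L)
  search <- architecture_search(
    records, candidates = candidates, train_fraction = ann$train_fraction,
    seed = seed, restarts = ann$restarts, max_epochs = ann$max_epochs,
    lambda_init = ann$lambda_init, lambda_up = ann$lambda_up,
    lambda_down = ann$lambda_down, min_gradient = ann$min_gradient)
  paths <- c(model = stage_path(out, "model.json"),
             search_report = stage_path(out, "search_report.csv"))
  write_model_json(search$best, paths["model"])
  write_artifact_csv(search$results, paths["search_report"])

  # per-concentration control networks: live cells + target -> viability
  screen_tbl <- tibble::as_tibble(utils::read.csv(stage_path(out,
                                                             "screen.csv")))
  ctl <- control_records(screen_tbl)
  for (s in unique(ctl$stratum)) {
    recs <- ctl[ctl$stratum == s, ]
    fit <- fit_mlp(recs, hidden = 3L, transfer = "tansig",
                   seed = derive_seed(seed, 7L),
                   restarts = ann$restarts,
                   inputs = c("norm_live_cells", "kinase_target"),
                   output = "norm_viability",
                   max_epochs = ann$max_epochs)
    cp <- stage_path(out, sprintf("control_model_%guM.json", s))
    write_model_json(fit, cp)
    paths[sprintf("control_%g", s)] <- cp
  }
  log_stage("train", "best architecture %s: test RMSE %.4f, test R2 %.4f",
            search$best$architecture, search$best$test_rmse,
            search$best$test_r2)
  invisible(paths)
}

#' @rdname pipeline-stages
#' @export
stage_predict <- function(config) {
  out <- config$out_dir
  require_inputs("predict", stage_path(out, c("model.json",
                                              "registry.csv")))
  model <- read_model_json(stage_path(out, "model.json"))
  registry <- tibble::as_tibble(utils::read.csv(stage_path(out,
                                                           "registry.csv")))
  class(registry) <- c("compound_registry", class(registry))
  gl <- config$grid
  levels <- default_grid_levels(
    n_concentration = gl$n_concentration, n_frequency = gl$n_frequency,
    n_viability = gl$n_viability,
    concentration_range = gl$concentration_range,
    frequency_range = gl$frequency_range,
    viability_range = gl$viability_range)
  grid <- build_grid(registry, levels)
  preds <- predict_grid(model$net, grid)
  path <- stage_path(out, "predictions.csv")
  write_artifact_csv(preds, path)
  log_stage("predict", "%d predictions (%d per compound)", nrow(preds),
            attr(grid, "rows_per_compound"))
  invisible(c(predictions = path))
}

#' @rdname pipeline-stages
#' @export
stage_rank <- function(config) {
  out <- config$out_dir
  require_inputs("rank", stage_path(out, "predictions.csv"))
  preds <- tibble::as_tibble(utils::read.csv(stage_path(out,
                                                        "predictions.csv")))
  ranking <- rank_compounds(preds)
  path <- stage_path(out, "ranking.csv")
  write_artifact_csv(ranking, path)
  log_stage("rank",
            "least detrimental compound #%d, most detrimental #%d",
            attr(ranking, "least_detrimental"),
            attr(ranking, "most_detrimental"))
  invisible(c(ranking = path))
}

#' @rdname pipeline-stages
#' @export
stage_biowire <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  b <- config$biowire
  seed <- derive_seed(config$seed, 6L)
  metrics <- lapply(seq_len(b$n_tissues), function(i) {
    tr <- synthesize_force_trace(
      amplitude = b$amplitude, pacing_hz = b$pacing_hz,
      contraction_slope = b$contraction_slope,
      relaxation_slope = b$relaxation_slope, duration = b$duration,
      dt = b$dt, noise_sd = b$noise_sd, seed = derive_seed(seed, i),
      tissue_id = sprintf("T%d", i))
    contraction_metrics(tr)
  })
  path <- stage_path(out, "tissue_metrics.csv")
  write_tissue_metrics_csv(metrics, path)
  log_stage("biowire", "%d tissues; mean active tension %.3f uN",
            length(metrics),
            mean(vapply(metrics, `[[`, numeric(1), "active_tension")))
  invisible(c(tissue_metrics = path))
}

PIPELINE_STAGES <- c("generate", "traces", "screen", "train", "predict",
                     "rank", "biowire")

#' Run the full screening pipeline
#'
#' Executes generate, traces, screen, train, predict, rank and biowire in
#' order, collecting every artifact path and its MD5 checksum into a
#' manifest written to `manifest.json` in the output directory.  A failure
#' stops the run with the failing stage named.
#'
#' @param config A `run_config` (default [default_config()]).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  manifest <- list(seed = config$seed, out_dir = config$out_dir,
                   package_version =
                     as.character(utils::packageVersion("cardioscreen")),
                   stages = list())
  for (stage in PIPELINE_STAGES) {
    fn <- get(paste0("stage_", stage), mode = "function")
    paths <- tryCatch(fn(config), error = function(e) {
      stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
    })
    manifest$stages[[stage]] <- list(
      files = as.list(paths),
      md5 = as.list(unname(tools::md5sum(unlist(paths))))
    )
  }
  jsonlite::write_json(manifest,
                       stage_path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
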