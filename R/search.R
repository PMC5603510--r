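MODEL_INPUTS <- c("concentration_uM", "kinase_target", "norm_frequency",
                  "norm_viability", "norm_live_cells")
MODEL_OUTPUT <- "norm_magnitude"

# Assemble the input matrix for training or prediction.  Concentration
# enters the network on a log10 scale: doses are tested and predicted on a
# log-spaced axis, and feeding raw micromolar values would collapse all
# sub-micromolar doses onto one end of the scaled input range, leaving the
# network unconstrained over most of the design grid.
prepare_inputs <- function(records, inputs = MODEL_INPUTS) {
  x <- as.matrix(records[, inputs])
  if ("concentration_uM" %in% inputs) {
    j <- match("concentration_uM", inputs)
    if (any(x[, j] <= 0)) stopf("concentrations must be positive")
    x[, j] <- log10(x[, j])
    colnames(x)[j] <- "log10_concentration_uM"
  }
  x
}

records_xy <- function(records, inputs = MODEL_INPUTS,
                       output = MODEL_OUTPUT) {
  missing <- setdiff(c(inputs, output), names(records))
  if (length(missing)) {
    stopf("records are missing columns: %s", paste(missing, collapse = ", "))
  }
  list(x = prepare_inputs(records, inputs), y = records[[output]])
}

#' Fit a network to screen records with multi-restart training
#'
#' Trains `restarts` randomly re-initialized networks of the given
#' architecture on the training split and keeps the one with the best
#' test-set R-squared (ties to the lower test RMSE).
#'
#' @param records A `model_records` tibble (or any data frame with the same
#'   columns).
#' @param hidden Integer vector of hidden-layer sizes; `integer(0)` gives a
#'   purely linear network.
#' @param transfer Hidden-layer transfer tag (`"tansig"` or `"logsig"`).
#' @param split A partition from [split_records()]; built from
#'   `train_fraction` and `seed` when NULL.
#' @param train_fraction,seed Used when `split` is NULL, and to seed restarts.
#' @param restarts Number of random initializations (default 3).
#' @param inputs,output Column names of the inputs and the output.
#' @param ... Optimizer controls passed to [train_lm()].
#' @return An `mlp_fit` augmented with `test_rmse`, `test_r2`,
#'   `architecture` tag and `restarts`.
#' @export
fit_mlp <- function(records, hidden = 8L, transfer = "tansig", split = NULL,
                    train_fraction = 0.9, seed = 1L, restarts = 3L,
                    inputs = MODEL_INPUTS, output = MODEL_OUTPUT, ...) {
  if (is.null(split)) {
    split <- split_records(records, train_fraction, seed = seed)
  }
  xy_train <- records_xy(split$train, inputs, output)
  xy_test <- records_xy(split$test, inputs, output)
  sizes <- c(ncol(xy_train$x), hidden, 1L)
  tags <- if (length(hidden)) c(rep(transfer, length(hidden)), "purelin")
          else "purelin"

  best <- NULL
  for (r in seq_len(restarts)) {
    net <- mlp_network(sizes, tags, seed = derive_seed(seed, 100L + r))
    fit <- tryCatch(
      train_lm(net, xy_train$x, xy_train$y, ...),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "mlp_fit_failed")
    )
    if (inherits(fit, "mlp_fit_failed")) {
      cand <- list(status = "diverged", test_r2 = NA_real_,
                   test_rmse = Inf, error = fit$error)
    } else {
      ev <- evaluate_net(fit$net, xy_test$x, xy_test$y)
      cand <- fit
      cand$status <- "ok"
      cand$test_rmse <- ev$rmse
      cand$test_r2 <- ev$r2
    }
    if (is.null(best) || better_fit(cand, best)) best <- cand
  }
  best$architecture <- arch_tag(hidden, transfer)
  best$hidden <- hidden
  best$transfer <- transfer
  best$restarts <- restarts
  best$split <- split
  best
}

arch_tag <- function(hidden, transfer) {
  if (length(hidden) == 0) return("linear")
  paste0(paste(hidden, collapse = "-"), "/", transfer)
}

# ranking order: higher test R2 wins, ties to lower test RMSE; NA/diverged last
better_fit <- function(a, b) {
  ra <- if (is.null(a$test_r2) || is.na(a$test_r2)) -Inf else a$test_r2
  rb <- if (is.null(b$test_r2) || is.na(b$test_r2)) -Inf else b$test_r2
  if (ra != rb) return(ra > rb)
  ea <- if (is.null(a$test_rmse) || is.na(a$test_rmse)) Inf else a$test_rmse
  eb <- if (is.null(b$test_rmse) || is.na(b$test_rmse)) Inf else b$test_rmse
  ea < eb
}

#' Default architecture-search candidates
#'
#' One and two hidden layers with 3, 5, 8 or 12 neurons per layer, hidden
#' transfer `tansig` or `logsig`, linear output.
#'
#' @return A tibble with list-column `hidden` and column `transfer`.
#' @export
default_candidates <- function() {
  sizes <- c(3L, 5L, 8L, 12L)
  one <- lapply(sizes, identity)
  two <- unlist(lapply(sizes, function(a) lapply(sizes, function(b) c(a, b))),
                recursive = FALSE)
  hidden <- c(one, two)
  tidyr::expand_grid(
    hidden = hidden,
    transfer = c("tansig", "logsig")
  )
}

#' Exhaustive architecture search
#'
#' Trains every candidate architecture on the same train/test split (with
#' multi-restart initialization) and ranks candidates by test R-squared
#' descending, ties broken by lower test RMSE; failed fits rank last with a
#' `diverged` status.
#'
#' @param records A `model_records` tibble.
#' @param candidates Tibble with list-column `hidden` and column `transfer`
#'   (default [default_candidates()]).
#' @param train_fraction,seed,restarts As in [fit_mlp()].
#' @param inputs,output Record column roles.
#' @param ... Optimizer controls passed to [train_lm()].
#' @return A list of class `arch_search`: `results` (tibble, one row per
#'   candidate in rank order: `rank`, `architecture`, `transfer`, `status`,
#'   `train_rmse`, `test_rmse`, `test_r2`, `epochs`), `best` (the winning
#'   `mlp_fit`) and `split`.
#' @export
architecture_search <- function(records, candidates = default_candidates(),
                                train_fraction = 0.9, seed = 1L,
                                restarts = 3L, inputs = MODEL_INPUTS,
                                output = MODEL_OUTPUT, ...) {
  if (nrow(candidates) == 0) stopf("candidate grid must be nonempty")
  split <- split_records(records, train_fraction, seed = seed)
  fits <- lapply(seq_len(nrow(candidates)), function(i) {
    fit_mlp(records, hidden = candidates$hidden[[i]],
            transfer = candidates$transfer[i], split = split,
            seed = derive_seed(seed, i), restarts = restarts,
            inputs = inputs, output = output, ...)
  })
  results <- tibble::tibble(
    architecture = vapply(fits, `[[`, character(1), "architecture"),
    transfer = candidates$transfer,
    status = vapply(fits, `[[`, character(1), "status"),
    train_rmse = vapply(fits, function(f)
      if (is.null(f$train_rmse)) NA_real_ else f$train_rmse, numeric(1)),
    test_rmse = vapply(fits, `[[`, numeric(1), "test_rmse"),
    test_r2 = vapply(fits, `[[`, numeric(1), "test_r2"),
    epochs = vapply(fits, function(f)
      if (is.null(f$epochs)) NA_integer_ else f$epochs, integer(1))
  )
  ord <- order(-ifelse(is.na(results$test_r2), -Inf, results$test_r2),
               ifelse(is.na(results$test_rmse), Inf, results$test_rmse))
  results <- results[ord, ]
  results$rank <- seq_len(nrow(results))
  structure(
    list(results = results, best = fits[[ord[1]]], split = split),
    class = "arch_search"
  )
}
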