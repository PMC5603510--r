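transfer_fun <- function(tag) {
  switch(tag,
    tansig = tanh,
    logsig = function(z) 1 / (1 + exp(-z)),
    purelin = identity,
    stopf("unknown transfer function '%s'", tag)
  )
}

transfer_deriv <- function(tag, a) {
  # derivative expressed through the activation a = f(z)
  switch(tag,
    tansig = 1 - a^2,
    logsig = a * (1 - a),
    purelin = rep(1, length(a)),
    stopf("unknown transfer function '%s'", tag)
  )
}

#' Construct a multilayer perceptron
#'
#' A feedforward network with per-layer weight matrices, bias vectors and
#' transfer functions (`tansig`, `logsig` or `purelin`), plus affine
#' input/output scaling to \[-1, 1\] fitted from training data.  Weights are
#' initialized uniformly in \[-0.5, 0.5\] under `seed`.
#'
#' @param layer_sizes Integer vector from input dimension through hidden
#'   sizes to output dimension, e.g. `c(5, 8, 1)`.
#' @param transfer Character vector of transfer tags, one per non-input
#'   layer; a single tag is recycled for the hidden layers with a `purelin`
#'   output.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mlp_net`.
#' @export
mlp_network <- function(layer_sizes, transfer = "tansig", seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stopf("`layer_sizes` must list input, (hidden,) and output sizes >= 1")
  }
  n_layers <- length(layer_sizes) - 1L
  if (length(transfer) == 1L && n_layers > 1L) {
    transfer <- c(rep(transfer, n_layers - 1L), "purelin")
  }
  if (length(transfer) != n_layers) {
    stopf("need one transfer function per layer (%d)", n_layers)
  }
  lapply(transfer, transfer_fun)  # validate tags
  wb <- with_seed(seed, {
    lapply(seq_len(n_layers), function(l) {
      list(W = matrix(runif(layer_sizes[l + 1] * layer_sizes[l], -0.5, 0.5),
                      layer_sizes[l + 1], layer_sizes[l]),
           b = runif(layer_sizes[l + 1], -0.5, 0.5))
    })
  })
  structure(
    list(sizes = layer_sizes,
         W = lapply(wb, `[[`, "W"),
         b = lapply(wb, `[[`, "b"),
         transfer = transfer,
         in_center = rep(0, layer_sizes[1]),
         in_half = rep(1, layer_sizes[1]),
         out_center = 0, out_half = 1,
         seed = as.integer(seed)),
    class = "mlp_net"
  )
}

#' Fit the network's affine input/output scaling to data
#'
#' Stores the centre and half-range of each input column and of the output so
#' training sees values in \[-1, 1\]; constant columns get half-range 1.
#'
#' @param net An `mlp_net`.
#' @param x Input matrix (rows = records).
#' @param y Output vector.
#' @return The network with scaling parameters set.
#' @export
set_scaling <- function(net, x, y) {
  x <- as.matrix(x)
  rng <- apply(x, 2, range)
  net$in_center <- (rng[1, ] + rng[2, ]) / 2
  half <- (rng[2, ] - rng[1, ]) / 2
  net$in_half <- ifelse(half > 0, half, 1)
  yr <- range(y)
  net$out_center <- mean(yr)
  net$out_half <- if (diff(yr) > 0) diff(yr) / 2 else 1
  net
}

scale_inputs <- function(net, x) {
  x <- as.matrix(x)
  if (ncol(x) != net$sizes[1]) {
    stopf("input has %d columns but the network expects %d",
          ncol(x), net$sizes[1])
  }
  sweep(sweep(x, 2, net$in_center), 2, net$in_half, "/")
}

# forward pass in scaled space, keeping per-layer activations for backprop
forward_scaled <- function(net, xs) {
  acts <- vector("list", length(net$W) + 1L)
  acts[[1]] <- xs
  a <- xs
  for (l in seq_along(net$W)) {
    z <- a %*% t(net$W[[l]])
    z <- sweep(z, 2, net$b[[l]], "+")
    a <- transfer_fun(net$transfer[l])(z)
    acts[[l + 1]] <- a
  }
  acts
}

#' Evaluate a network
#'
#' @param net An `mlp_net`.
#' @param x Input matrix or data frame, one row per record, columns in the
#'   network's input order.
#' @return Predicted outputs on the natural (unscaled) output scale; a
#'   vector for single-output networks.
#' @export
mlp_forward <- function(net, x) {
  stopifnot(inherits(net, "mlp_net"))
  acts <- forward_scaled(net, scale_inputs(net, x))
  out <- acts[[length(acts)]] * net$out_half + net$out_center
  if (ncol(out) == 1L) drop(out) else out
}

# pack / unpack parameters (column-major weights then biases, layer by layer)
get_params <- function(net) {
  unlist(lapply(seq_along(net$W), function(l) c(net$W[[l]], net$b[[l]])))
}

set_params <- function(net, p) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    nw <- length(net$W[[l]])
    net$W[[l]][] <- p[pos + seq_len(nw)]
    pos <- pos + nw
    nb <- length(net$b[[l]])
    net$b[[l]] <- p[pos + seq_len(nb)]
    pos <- pos + nb
  }
  net
}

#' Jacobian of network outputs with respect to all parameters
#'
#' Analytic backpropagation Jacobian for a single-output network, evaluated
#' in the scaled input/output space: one row per record, one column per
#' parameter in [get_params()] order.  Also returns the residuals
#' `r = y_scaled - prediction_scaled`, the quantities the Levenberg-Marquardt
#' step is built from.
#'
#' @param net A single-output `mlp_net`.
#' @param x Input matrix (natural units).
#' @param y Target vector (natural units).
#' @return A list with `J` (n x p matrix), `r` (length-n residual vector)
#'   and `pred_scaled`.
#' @export
mlp_jacobian <- function(net, x, y) {
  stopifnot(inherits(net, "mlp_net"))
  if (net$sizes[length(net$sizes)] != 1L) {
    stopf("Jacobian is implemented for single-output networks")
  }
  xs <- scale_inputs(net, x)
  ys <- (y - net$out_center) / net$out_half
  acts <- forward_scaled(net, xs)
  n <- nrow(xs)
  L <- length(net$W)

  # backpropagated sensitivities of the scalar output w.r.t. each layer's
  # pre-activation, as n x n_l matrices
  D <- vector("list", L)
  D[[L]] <- matrix(transfer_deriv(net$transfer[L], acts[[L + 1]]), n, 1)
  if (L > 1) {
    for (l in (L - 1):1) {
      D[[l]] <- (D[[l + 1]] %*% net$W[[l + 1]]) *
        transfer_deriv(net$transfer[l], acts[[l + 1]])
    }
  }

  blocks <- vector("list", L)
  for (l in seq_len(L)) {
    n_out <- net$sizes[l + 1]
    n_in <- net$sizes[l]
    a_prev <- acts[[l]]
    # column-major W: column (j-1)*n_out + i  <->  dW[i, j] = D[, i] * A[, j]
    jw <- D[[l]][, rep(seq_len(n_out), times = n_in), drop = FALSE] *
      a_prev[, rep(seq_len(n_in), each = n_out), drop = FALSE]
    blocks[[l]] <- cbind(jw, D[[l]])
  }
  J <- do.call(cbind, blocks)
  pred <- drop(acts[[L + 1]])
  list(J = J, r = ys - pred, pred_scaled = pred)
}

#' Train a network by Levenberg-Marquardt backpropagation
#'
#' Minimizes the mean squared error in scaled space by damped Gauss-Newton
#' steps: each accepted step solves `(J'J + lambda I) delta = J'r` and must
#' strictly reduce the training RMSE; `lambda` shrinks by `lambda_down` on
#' acceptance and grows by `lambda_up` while a step is rejected.  Training
#' stops at `max_epochs` (default 1000), when the error gradient falls below
#' `min_gradient`, or when `lambda` exceeds `max_lambda` without progress.
#'
#' @param net A single-output `mlp_net` (scaling is fitted from the data if
#'   left at its identity default).
#' @param x Input matrix or data frame (natural units).
#' @param y Target vector (natural units).
#' @param max_epochs,lambda_init,lambda_up,lambda_down,min_gradient,max_lambda
#'   Optimizer controls.
#' @param fit_scaling Refit input/output scaling from this data first
#'   (default TRUE).
#' @return An object of class `mlp_fit`: `net` (trained), `rmse_curve`
#'   (training RMSE per accepted epoch, natural units, nonincreasing),
#'   `train_rmse`, `epochs`, `converged`, `seed`.
#' @export
train_lm <- function(net, x, y, max_epochs = 1000L, lambda_init = 1e-3,
                     lambda_up = 10, lambda_down = 0.1, min_gradient = 1e-7,
                     max_lambda = 1e10, fit_scaling = TRUE) {
  stopifnot(inherits(net, "mlp_net"))
  x <- as.matrix(x)
  if (nrow(x) == 0) stopf("training data must be nonempty")
  if (any(!is.finite(y))) stopf("targets must be finite")
  if (fit_scaling) net <- set_scaling(net, x, y)

  lambda <- lambda_init
  p <- get_params(net)
  jr <- mlp_jacobian(net, x, y)
  loss <- mean(jr$r^2)
  if (!is.finite(loss)) stopf("training diverged: non-finite loss")
  rmse_curve <- sqrt(loss) * net$out_half
  epochs <- 0L
  converged <- FALSE

  for (epoch in seq_len(max_epochs)) {
    g <- crossprod(jr$J, jr$r)
    if (max(abs(g)) < min_gradient) {
      converged <- TRUE
      break
    }
    jtj <- crossprod(jr$J)
    accepted <- FALSE
    while (lambda <= max_lambda) {
      delta <- tryCatch(
        solve(jtj + diag(lambda, ncol(jtj)), g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        trial <- set_params(net, p + drop(delta))
        jr_trial <- mlp_jacobian(trial, x, y)
        loss_trial <- mean(jr_trial$r^2)
        if (is.finite(loss_trial) && loss_trial < loss) {
          net <- trial
          p <- p + drop(delta)
          jr <- jr_trial
          loss <- loss_trial
          lambda <- max(lambda * lambda_down, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * lambda_up
    }
    if (!accepted) break  # no further descent possible at this damping
    epochs <- epoch
    rmse_curve <- c(rmse_curve, sqrt(loss) * net$out_half)
  }

  structure(
    list(net = net, rmse_curve = rmse_curve,
         train_rmse = sqrt(loss) * net$out_half,
         epochs = epochs, converged = converged, seed = net$seed),
    class = "mlp_fit"
  )
}

#' Split records into training and test sets
#'
#' Draws a seeded random partition with `round(train_fraction * n)` training
#' records (the screen's convention is 90/10).
#'
#' @param data A data frame (or matrix) of records, n >= 2.
#' @param train_fraction Fraction assigned to training, strictly between 0
#'   and 1 (default 0.9).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return A list with `train`, `test` (disjoint row subsets whose union is
#'   `data`) and the index vector `train_idx`.
#' @export
split_records <- function(data, train_fraction = 0.9, seed = 1L) {
  n <- nrow(data)
  if (is.null(n) || n < 2L) stopf("need at least two records to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
        train_fraction >= 1) {
    stopf("`train_fraction` must be strictly between 0 and 1")
  }
  n_train <- min(max(round(train_fraction * n), 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_train))
  idx <- sort(idx)
  list(train = data[idx, , drop = FALSE],
       test = data[-idx, , drop = FALSE],
       train_idx = idx)
}

#' Evaluate predictions by RMSE and R-squared
#'
#' RMSE is the root mean squared residual; R-squared defaults to the squared
#' Pearson correlation between predicted and actual values (the trend-line
#' convention), with the coefficient of determination available as
#' `r2 = "cod"`.  Zero-variance actuals or predictions give an undefined
#' (NA) R-squared.
#'
#' @param net An `mlp_net`.
#' @param x Test inputs.
#' @param y Test targets.
#' @param r2 `"pearson"` (default) or `"cod"`.
#' @return A list with `rmse` and `r2`.
#' @export
evaluate_net <- function(net, x, y, r2 = c("pearson", "cod")) {
  r2 <- match.arg(r2)
  if (length(y) == 0) stopf("test set must be nonempty")
  pred <- mlp_forward(net, x)
  rmse <- sqrt(mean((y - pred)^2))
  sd_y <- if (length(y) > 1) sd(y) else 0
  sd_p <- if (length(pred) > 1) sd(pred) else 0
  r2_val <- if (r2 == "pearson") {
    if (!is.finite(sd_y) || !is.finite(sd_p) || sd_y == 0 || sd_p == 0) {
      NA_real_
    } else {
      cor(pred, y)^2
    }
  } else {
    if (!is.finite(sd_y) || sd_y == 0) {
      NA_real_
    } else {
      1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    }
  }
  list(rmse = rmse, r2 = r2_val)
}
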