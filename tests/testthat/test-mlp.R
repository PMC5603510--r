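identity_linear_net <- function(w = 1, b = 0) {
  net <- mlp_network(c(1, 1), "purelin", seed = 1)
  net$W[[1]][] <- w
  net$b[[1]] <- b
  net
}

test_that("forward pass reproduces affine maps and handles dimensions", {
  net <- identity_linear_net(1, 0)
  x <- matrix(c(-2, 0, 3.7), ncol = 1)
  expect_equal(mlp_forward(net, x), c(-2, 0, 3.7))

  biased <- identity_linear_net(0, 4.2)
  expect_equal(mlp_forward(biased, x), rep(4.2, 3))

  tn <- mlp_network(c(2, 3, 1), "tansig", seed = 2)
  tn$b <- lapply(tn$b, function(b) b * 0)
  expect_equal(mlp_forward(tn, matrix(0, 1, 2)), 0)

  expect_error(mlp_forward(net, matrix(0, 1, 2)), "expects")
  expect_error(mlp_network(c(1), "purelin"), "sizes")
})

test_that("analytic Jacobian matches hand results and finite differences", {
  net <- identity_linear_net(2, 1)
  jr <- mlp_jacobian(net, matrix(3), 0)
  expect_equal(drop(jr$J), c(3, 1))  # d(w x + b)/dw = x, /db = 1
  expect_equal(jr$r, 0 - (2 * 3 + 1))

  # brute-force central-difference oracle over seeded random networks
  worst <- 0
  for (seed in 1:20) {
    net <- random_net(seed)
    d <- net$sizes[1]
    set.seed(seed + 1000)
    x <- matrix(rnorm(5 * d), 5, d)
    y <- rnorm(5)
    jr <- mlp_jacobian(net, x, y)
    p <- cardioscreen:::get_params(net)
    h <- 1e-6
    fd <- vapply(seq_along(p), function(k) {
      up <- p; up[k] <- up[k] + h
      dn <- p; dn[k] <- dn[k] - h
      (mlp_forward(cardioscreen:::set_params(net, up), x) -
         mlp_forward(cardioscreen:::set_params(net, dn), x)) / (2 * h)
    }, numeric(5))
    rel <- max(abs(jr$J - fd)) / max(abs(fd), 1)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("LM training on a linear network equals least squares", {
  set.seed(10)
  x <- matrix(rnorm(120 * 3), 120, 3)
  y <- drop(x %*% c(0.5, -1, 2)) + 0.7 + rnorm(120, 0, 0.2)
  fit <- train_lm(mlp_network(c(3, 1), "purelin", seed = 2), x, y)
  ols <- lm(y ~ x)
  expect_lt(max(abs(mlp_forward(fit$net, x) - fitted(ols))), 1e-8)

  # the scalar toy case drives the weight to the planted slope
  x1 <- matrix(seq(-1, 1, length.out = 50))
  fit1 <- train_lm(mlp_network(c(1, 1), "purelin", seed = 4), x1, 0.5 * x1[, 1])
  expect_lt(fit1$train_rmse, 1e-8)

  # accepted-step RMSE curve is strictly decreasing
  expect_true(all(diff(fit$rmse_curve) < 0))
  expect_error(train_lm(mlp_network(c(1, 1), "purelin"), matrix(1), NaN),
               "finite")
})

test_that("LM solves the XOR benchmark with a 2-neuron tanh hidden layer", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- c(0, 1, 1, 0)
  best <- Inf
  for (seed in 1:5) {
    fit <- train_lm(mlp_network(c(2, 2, 1), "tansig", seed = seed), x, y,
                    max_epochs = 1000)
    best <- min(best, fit$train_rmse)
    if (best < 0.05) break
  }
  expect_lt(best, 0.05)
})

test_that("the 90/10 split contract holds", {
  d <- data.frame(x = 1:1000)
  sp <- split_records(d, 0.9, seed = 3)
  expect_equal(nrow(sp$train), 900)
  expect_equal(nrow(sp$test), 100)
  expect_length(intersect(sp$train$x, sp$test$x), 0)
  expect_setequal(c(sp$train$x, sp$test$x), d$x)

  small <- split_records(data.frame(x = 1:10), 0.9, seed = 1)
  expect_equal(nrow(small$train), 9)

  expect_identical(split_records(d, 0.9, seed = 5)$train_idx,
                   split_records(d, 0.9, seed = 5)$train_idx)
  expect_false(identical(split_records(d, 0.9, seed = 5)$train_idx,
                         split_records(d, 0.9, seed = 6)$train_idx))
  expect_error(split_records(data.frame(x = 1), 0.9), "two")
  expect_error(split_records(d, 1.0), "between")
})

test_that("evaluation reports RMSE and R-squared with degenerate guards", {
  net <- identity_linear_net(1, 0)
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  ev <- evaluate_net(net, x, c(1, 2, 3, 4))
  expect_equal(ev$rmse, 0)
  expect_equal(ev$r2, 1)

  # constant predictions: undefined correlation
  const <- identity_linear_net(0, 2.5)
  ev2 <- evaluate_net(const, x, c(1, 2, 3, 4))
  expect_true(is.na(ev2$r2))
  expect_equal(ev2$rmse, sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))

  # four-point hand example: pred = x, actual below by (0, 1, 0, -1)
  y <- c(1, 1, 3, 5)
  ev3 <- evaluate_net(net, x, y)
  expect_equal(ev3$rmse, sqrt(mean(c(0, 1, 0, 1)^2)))
  expect_equal(ev3$r2, cor(c(1, 2, 3, 4), y)^2)
  ev4 <- evaluate_net(net, x, y, r2 = "cod")
  expect_equal(ev4$r2, 1 - 2 / sum((y - mean(y))^2))
})

test_that("architecture search recovers a planted nonlinear surface", {
  # data generated by a known 1-hidden-layer tanh network
  gen <- mlp_network(c(2, 3, 1), "tansig", seed = 40)
  set.seed(41)
  x <- matrix(runif(300 * 2, -2, 2), 300, 2)
  y <- mlp_forward(gen, x) + rnorm(300, 0, 0.01)
  recs <- tibble::tibble(a = x[, 1], b = x[, 2], y = y)
  cands <- tibble::tibble(hidden = list(integer(0), 3L),
                          transfer = c("purelin", "tansig"))
  search <- architecture_search(recs, cands, seed = 42, restarts = 2,
                                inputs = c("a", "b"), output = "y")
  expect_equal(search$results$architecture[1], "3/tansig")
  expect_gt(search$results$test_r2[1], 0.99)

  # single candidate comes back as rank 1; same seed twice is stable
  s1 <- architecture_search(recs, cands[2, ], seed = 7, restarts = 1,
                            inputs = c("a", "b"), output = "y")
  expect_equal(s1$results$rank, 1L)
  s2 <- architecture_search(recs, cands[2, ], seed = 7, restarts = 1,
                            inputs = c("a", "b"), output = "y")
  expect_identical(s1$results, s2$results)

  expect_error(architecture_search(recs, cands[0, ], inputs = c("a", "b"),
                                   output = "y"), "nonempty")
})
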