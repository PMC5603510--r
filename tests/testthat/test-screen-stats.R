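test_that("viability is the live fraction of total cells", {
  expect_equal(viability(100, 10), list(viability = 0.9,
                                        live_cell_count = 90))
  expect_equal(viability(100, 0)$viability, 1)
  expect_equal(viability(100, 100), list(viability = 0,
                                         live_cell_count = 0))
  expect_error(viability(0, 0), "positive")
  expect_error(viability(100, 101), "exceed")
})

test_that("blank normalization and its inverse round-trip exactly", {
  expect_equal(normalize_blank(2, 1), 1)
  expect_equal(normalize_blank(5, 5), 0)
  expect_equal(normalize_blank(0.5, 1), -0.5)
  expect_error(normalize_blank(1, 0), "degenerate")

  set.seed(8)
  raw <- runif(200, 0.1, 100)
  bm <- runif(1, 0.5, 50)
  expect_equal(denormalize_blank(normalize_blank(raw, bm), bm), raw)
})

test_that("SD band codes match z-band arithmetic", {
  # hand-computed table: z and ceil(|z|) capped at 3, signed
  expect_identical(sd_band(1.25, 1, 0.1), 3L)    # z = 2.5
  expect_identical(sd_band(0.85, 1, 0.1), -2L)   # z = -1.5
  expect_identical(sd_band(1, 1, 0.1), 0L)
  expect_identical(sd_band(1.05, 1, 0.1), 1L)    # z = 0.5
  expect_identical(sd_band(0.7, 1, 0.1), -3L)    # z = -3
  expect_identical(sd_band(2.4, 1, 0.1), 3L)     # capped
  expect_error(sd_band(1, 1, 0), "> 0")

  # monotone nondecreasing in the triplicate mean
  means <- seq(0, 2, by = 0.01)
  bands <- sd_band(means, 1, 0.15)
  expect_true(all(diff(bands) >= 0))
  expect_true(all(abs(bands) <= 3))
  expect_identical(sign(bands), sign(means - 1))
})

# independent brute-force one-way ANOVA from the sums of squares
anova_bruteforce <- function(groups) {
  all <- unlist(groups)
  k <- length(groups)
  n <- length(all)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

test_that("ANOVA F matches a brute-force sums-of-squares oracle", {
  set.seed(21)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k),
                     function(j) rnorm(sample(3:7, 1), mean = j * 0.3))
    res <- anova_lsd(groups)
    expect_equal(res$f_statistic, anova_bruteforce(groups),
                 tolerance = 1e-10)
  }
})

test_that("Fisher LSD flags clear separations and not degenerate tables", {
  # identical constant groups: no variance anywhere, non-significant
  res0 <- anova_lsd(list(c(1, 1, 1), c(1, 1, 1)))
  expect_true(is.na(res0$f_statistic))
  expect_false(any(res0$lsd$significant))

  # {0,0,0} vs {10,10,10} with tiny jitter is overwhelmingly significant
  set.seed(4)
  res1 <- anova_lsd(list(rnorm(3, 0, 1e-3), rnorm(3, 10, 1e-3)))
  expect_gt(res1$f_statistic, 1e4)
  expect_true(all(res1$lsd$significant))

  # two-group LSD equals the pooled-variance t-test
  set.seed(5)
  a <- rnorm(6)
  b <- rnorm(6, 1)
  res2 <- anova_lsd(list(ctrl = a, trt = b))
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(res2$lsd$p, tt$p.value, tolerance = 1e-12)

  expect_error(anova_lsd(list(c(1, 2, 3))), "two")
  expect_error(anova_lsd(list(c(1, 2), c(3))), "two replicates")
})

test_that("screen summary normalizes against blanks and bands effects", {
  scr <- tiny_screen(seed = 33)
  feats <- analyze_screen_traces(scr)
  wells <- well_endpoints(scr$plate_map, feats, scr$counts)
  summ <- summarize_screen(wells)
  screen <- summ$screen

  expect_setequal(unique(screen$endpoint),
                  c("cell_viability", "live_cell_count", "peak_magnitude",
                    "frequency"))
  expect_equal(nrow(screen), 5 * 3 * 4)  # compounds x concentrations x endpoints
  expect_true(all(screen$n_wells <= 3))
  expect_true(all(abs(screen$band[!is.na(screen$band)]) <= 3))

  # normalized means recover raw means through the plate blank mean
  j <- summ$wells_normalized
  ok <- is.finite(j$raw)
  expect_equal(j$raw[ok], j$blank_mean[ok] * (j$norm[ok] + 1),
               tolerance = 1e-12)

  # the planted strong positive magnitude effects surface as positive bands
  mag <- screen[screen$endpoint == "peak_magnitude" &
                  screen$concentration_uM == 10, ]
  planted <- scr$model$effects
  strong <- planted$compound_id[planted$concentration_uM == 10 &
                                  planted$magnitude_mult > 1.5]
  expect_true(all(mag$band[mag$compound_id %in% strong] > 0))

  hm <- heatmap_matrix(screen)
  expect_equal(dim(hm), c(5, 12))
  recs <- model_records(screen)
  expect_equal(nrow(recs), 15)
  expect_true(all(is.finite(as.matrix(recs))))

  ctl <- control_records(screen)
  expect_equal(length(unique(ctl$stratum)), 3)
})
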