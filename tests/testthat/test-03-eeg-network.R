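test_that("PLV is 1 for identical and constant-lag signals and ~0 for noise", {
  t <- seq(0, 40, length.out = 20000)
  same <- rbind(sin(2 * pi * 6 * t), sin(2 * pi * 6 * t))
  plv <- plv_matrix(make_epoch_set(list(same), band = "theta"))
  expect_equal(plv$values[1, 2], 1, tolerance = 1e-6)

  lag <- rbind(sin(2 * pi * 6 * t), cos(2 * pi * 6 * t))
  plv <- plv_matrix(make_epoch_set(list(lag), band = "theta"))
  expect_equal(plv$values[1, 2], 1, tolerance = 1e-6)

  set.seed(7)
  noise <- rbind(rnorm(20000), rnorm(20000))
  plv <- plv_matrix(make_epoch_set(list(noise), band = "theta"))
  expect_lt(plv$values[1, 2], 0.05)
})

test_that("PLV matrices are symmetric with unit diagonal and values in [0,1]", {
  set.seed(1)
  eps <- purrr::map(1:4, ~matrix(rnorm(4 * 5000), 4, 5000))
  plv <- plv_matrix(make_epoch_set(eps, band = "delta"))
  expect_true(isSymmetric(plv$values))
  expect_equal(unname(diag(plv$values)), rep(1, 4))
  expect_true(all(plv$values >= 0 & plv$values <= 1))
})

test_that("proportional thresholding keeps the exact rounded edge count", {
  set.seed(2)
  v <- matrix(runif(26 * 26), 26); v <- (v + t(v)) / 2; diag(v) <- 1
  net <- binarize_proportional(v, 0.3)
  expect_equal(net$n_edges, 228L)     # round-half-up of 0.7 * 325 = 227.5
  expect_equal(sum(net$adjacency) / 2, 228)
  expect_true(isSymmetric(net$adjacency))
  expect_equal(unname(diag(net$adjacency)), rep(0L, 26))

  expect_equal(binarize_proportional(v, 0)$n_edges, 325)

  for (thr in seq(0.2, 0.5, by = 0.01)) {
    # exact rational target, free of binary-threshold representation error
    target <- as.integer(floor(round((1 - thr) * 325, 6) + 0.5))
    expect_equal(binarize_proportional(v, thr)$n_edges, target)
  }
})

test_that("thresholding keeps exactly the largest pairs (sort oracle)", {
  set.seed(3)
  v <- matrix(0, 4, 4)
  v[upper.tri(v)] <- sample(seq(0.1, 0.9, length.out = 6))
  v <- v + t(v); diag(v) <- 1
  net <- binarize_proportional(v, 0.5)
  vals <- v[upper.tri(v)]
  kept <- sort(vals, decreasing = TRUE)[1:3]
  picked <- v[upper.tri(v)][net$adjacency[upper.tri(net$adjacency)] == 1]
  expect_setequal(picked, kept)
})

test_that("complete graph and ring metric identities hold", {
  k26 <- matrix(1L, 26, 26); diag(k26) <- 0L
  m <- network_metrics(k26)
  expect_equal(m$C, 1)
  expect_equal(m$L, 1)
  expect_equal(m$GE, 1)
  expect_equal(m$LE, 1)
  expect_equal(m$T, 1)

  ring <- matrix(0L, 6, 6)
  for (i in 1:6) ring[i, i %% 6 + 1] <- 1L
  ring <- ring + t(ring)
  m <- network_metrics(ring)
  expect_equal(m$C, 0)
  expect_equal(m$T, 0)
  expect_equal(m$L, 1.8)
  expect_equal(m$GE, mean(1 / c(1, 1, 2, 2, 3)))
})

test_that("modularity search is deterministic across calls", {
  set.seed(5)
  adj <- random_graph(20, 0.3)
  expect_identical(network_metrics(adj)$M, network_metrics(adj)$M)
})

test_that("metric curves have 31 points and trapezoidal AUC identities hold", {
  curves <- tibble::tibble(
    threshold = rep(seq(0.2, 0.5, by = 0.01), 2),
    metric = rep(c("const", "lin"), each = 31),
    value = c(rep(0.6, 31), seq(0.2, 0.8, length.out = 31))
  )
  class(curves) <- c("metric_curves", class(curves))
  auc <- curve_auc(curves)
  expect_equal(auc$auc[auc$metric == "const"], 0.3 * 0.6, tolerance = 1e-12)
  expect_equal(auc$auc[auc$metric == "lin"], 0.15 * (0.2 + 0.8),
               tolerance = 1e-12)

  set.seed(6)
  v <- matrix(runif(26 * 26, 0.2, 0.9), 26); v <- (v + t(v)) / 2; diag(v) <- 1
  mc <- metric_curves(v)
  expect_equal(nrow(mc), 31 * 6)
  expect_equal(sort(unique(mc$threshold)), seq(0.2, 0.5, by = 0.01))
})

test_that("efficiency never increases and clustering declines across the sweep", {
  # GE is provably non-increasing under edge removal (paths only lengthen);
  # C can tick up locally because a node's degree denominator shrinks, so
  # the sweep-wide decline is asserted instead of strict monotonicity
  set.seed(8)
  for (rep in 1:20) {
    v <- matrix(runif(26 * 26), 26); v <- (v + t(v)) / 2; diag(v) <- 1
    mc <- metric_curves(v)
    cvals <- mc$value[mc$metric == "C"]
    gevals <- mc$value[mc$metric == "GE"]
    expect_true(all(diff(gevals) <= 1e-12))
    expect_lt(cvals[31], cvals[1])
  }
})

test_that("spectral and time-domain band PLV paths agree closely", {
  cfg <- test_cohort_config(n_per_group = 1L, seed = 31L)
  rec <- generate_eeg_cohort(cfg)[[1]]
  es <- segment_and_reject(preprocess_recording(rec))
  fused <- plv_by_band(es, "theta")$theta$values
  composed <- plv_matrix(extract_band(es, "theta"))$values
  expect_lt(max(abs(fused - composed)), 0.01)
})
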