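make_features <- function(x, groups, prefix = "eeg_f") {
  colnames(x) <- paste0(prefix, seq_len(ncol(x)))
  dplyr::mutate(tibble::as_tibble(x),
                subject_id = sprintf("S%02d", seq_len(nrow(x))),
                group = groups, .before = 1)
}

test_that("min-max normalization follows the fitted range", {
  fm <- make_features(cbind(c(2, 4, 10)), c("patient", "control", "patient"))
  out <- minmax_normalize(fm)
  expect_equal(out$eeg_f1, c(0, 0.25, 1))

  # constant feature maps to zero
  fm2 <- make_features(cbind(rep(3, 5), 1:5),
                       rep(c("patient", "control"), c(2, 3)))
  out2 <- minmax_normalize(fm2)
  expect_equal(out2$eeg_f1, rep(0, 5))

  # fitting on a subset leaves held-out rows free to exceed [0, 1]
  fm3 <- make_features(cbind(1:4), rep(c("patient", "control"), 2))
  out3 <- minmax_normalize(fm3, fit_rows = 1:3)
  expect_equal(out3$eeg_f1, c(0, 0.5, 1, 1.5))
})

test_that("LASSO selection shrinks to nothing at huge penalties", {
  set.seed(50)
  x <- matrix(rnorm(40 * 6), 40)
  fm <- make_features(x, rep(c("patient", "control"), 20))
  sel <- lasso_select(fm, lambda_grid = c(1e6, 1e5), seed = 1)
  expect_equal(nrow(sel$selected), 0)
})

test_that("LASSO approaches least squares as the penalty vanishes", {
  set.seed(51)
  q <- qr.Q(qr(matrix(rnorm(60 * 5), 60)))
  beta <- c(2, -1, 0.5, 0, 1.5)
  y <- q %*% beta + rnorm(60, sd = 0.01)
  fit <- glmnet::glmnet(q, y, lambda = c(0.5, 0.1, 0.01, 0), standardize = FALSE)
  ols <- coef(lm(y ~ q))[-1]
  expect_equal(as.numeric(coef(fit, s = 0))[-1], unname(ols), tolerance = 1e-4)
})

test_that("LASSO recovers a planted sparse support", {
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    x <- matrix(rnorm(60 * 20), 60)
    y <- 3 * x[, 1] - 2 * x[, 5] + rnorm(60, sd = 0.1)
    fm <- make_features(x, rep("control", 60))
    sel <- lasso_select(fm, seed = s, response = y)
    got <- sel$selected$feature
    # the CV-minimal penalty keeps the true support on top of the ranking
    # but admits a few small-coefficient false positives
    ok <- setequal(got[1:2], c("eeg_f1", "eeg_f5")) &&
      length(setdiff(got, c("eeg_f1", "eeg_f5"))) <= 5
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})

test_that("LOOCV is perfect on separable clusters and reports sane metrics", {
  set.seed(52)
  n <- 20
  x <- rbind(matrix(rnorm(n / 2 * 4, mean = 0), n / 2),
             matrix(rnorm(n / 2 * 4, mean = 8), n / 2))
  fm <- make_features(x, rep(c("patient", "control"), each = n / 2))
  rep_ <- loocv_classify(fm, seed = 1)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$precision, 1)
  expect_equal(rep_$recall, 1)
  expect_equal(rep_$roc_auc, 1)
})

test_that("confusion-matrix summaries follow from the counts", {
  preds <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:55),
    truth = rep(c("patient", "control"), c(25, 30)),
    predicted = c(rep("patient", 23), rep("control", 2),
                  rep("control", 27), rep("patient", 3)),
    decision = c(rnorm(23, 1), rnorm(2, -1), rnorm(27, -1), rnorm(3, 1))
  )
  rep_ <- classifier_report(preds)
  expect_equal(rep_$accuracy, 50 / 55)
  expect_equal(rep_$precision, 23 / 26)
  expect_equal(rep_$recall, 23 / 25)
  g <- glance(rep_)
  expect_equal(g$accuracy, 50 / 55)
  expect_equal(nrow(tidy(rep_)), 55)
})

test_that("a held-out subject cannot leak into its own fold's training", {
  set.seed(53)
  x <- matrix(rnorm(16 * 5), 16)
  x[, 1] <- x[, 1] + rep(c(1.5, 0), each = 8)
  fm <- make_features(x, rep(c("patient", "control"), each = 8))
  fm2 <- fm
  fm2[4, "eeg_f2"] <- fm2[4, "eeg_f2"] + 1e3   # corrupt the held-out row
  train <- setdiff(1:16, 4)
  n1 <- minmax_normalize(fm, fit_rows = train)
  n2 <- minmax_normalize(fm2, fit_rows = train)
  expect_identical(n1[train, ], n2[train, ])
  s1 <- lasso_select(n1[train, ], seed = 7)
  s2 <- lasso_select(n2[train, ], seed = 7)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$lambda_chosen, s2$lambda_chosen)
})

test_that("LOOCV reports are reproducible under a fixed seed", {
  set.seed(54)
  x <- matrix(rnorm(14 * 6), 14)
  fm <- make_features(x, rep(c("patient", "control"), 7))
  r1 <- loocv_classify(fm, seed = 9)
  r2 <- loocv_classify(fm, seed = 9)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("modality comparison is consistent with direct column subsetting", {
  set.seed(55)
  x <- cbind(matrix(rnorm(20 * 4), 20), matrix(rnorm(20 * 3), 20))
  fm <- make_features(x[, 1:4], rep(c("patient", "control"), 10))
  fn <- make_features(x[, 5:7], rep(c("patient", "control"), 10), "fnirs_g")
  full <- dplyr::bind_cols(fm, fn[, -(1:2)])
  cmp <- compare_modalities(full, seed = 2)
  direct <- loocv_classify(full[c("subject_id", "group",
                                  paste0("eeg_f", 1:4))], seed = 2)
  expect_equal(cmp$eeg$predictions, direct$predictions)
  expect_equal(cmp$accuracy_difference,
               cmp$hybrid$accuracy - cmp$eeg$accuracy)

  # all-zero fNIRS block cannot change the model
  zero <- full
  zero[paste0("fnirs_g", 1:3)] <- 0
  cmp0 <- compare_modalities(zero, seed = 2)
  expect_equal(cmp0$hybrid$accuracy, cmp0$eeg$accuracy)

  no_fnirs <- full[c("subject_id", "group", paste0("eeg_f", 1:4))]
  expect_error(compare_modalities(no_fnirs), "fNIRS")
})
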