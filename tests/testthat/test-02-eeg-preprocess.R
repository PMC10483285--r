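test_that("preprocessing drops T7/T8, trims 10 s and nulls zero input", {
  rec <- make_eeg_recording(function(ch, n, fs) numeric(n))
  out <- preprocess_recording(rec)
  expect_equal(length(out$channel_labels), 26)
  expect_false(any(c("T7", "T8") %in% out$channel_labels))
  expect_equal(ncol(out$data), ncol(rec$data) - 10 * 500)
  expect_equal(max(abs(out$data)), 0)
})

test_that("50 Hz interference is strongly attenuated by the notch", {
  x0 <- 10 * sin(2 * pi * 50 * seq_len(95000) / 500)
  x1 <- neurofuse:::notch_filtfilt(x0, 50, 500, 35)
  expect_lt(20 * log10(sd(x1[1000:94000]) / sd(x0)), -20)
  # and an in-band tone passes essentially unchanged
  x6 <- sin(2 * pi * 6 * seq_len(95000) / 500)
  y6 <- neurofuse:::notch_filtfilt(x6, 50, 500, 35)
  expect_gt(sd(y6) / sd(x6), 0.99)
})

test_that("average reference zeroes the instantaneous channel mean", {
  set.seed(10)
  rec <- make_eeg_recording(function(ch, n, fs) rnorm(n, sd = 5))
  out <- preprocess_recording(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
})

test_that("epoching yields 20000-sample epochs and honours the threshold rule", {
  rec <- make_eeg_recording(function(ch, n, fs) numeric(n), duration = 360)
  pp <- preprocess_recording(rec)
  es <- segment_and_reject(pp)
  expect_equal(length(es$epochs), 4)
  expect_true(all(vapply(es$epochs, ncol, integer(1)) == 20000))

  # a single 150 uV sample in the second epoch drops it; later epochs shift
  x <- pp$data
  x["Cz", 20000 + 500] <- 150
  marked <- recording(x, pp$channel_labels, pp$fs, pp$group, pp$subject_id)
  es2 <- segment_and_reject(marked)
  expect_equal(es2$n_rejected, 1L)
  # the retained set skips the contaminated epoch: epoch 2 of the marked
  # segmentation equals epoch 3 of the underlying signal
  expect_equal(es2$epochs[[2]], x[, 40001:60000, drop = FALSE])

  # amplitudes exactly at 100 uV are retained (strict inequality)
  x2 <- pp$data
  x2["Cz", ] <- 0
  x2["Cz", 100] <- 100
  es3 <- segment_and_reject(recording(x2, pp$channel_labels, pp$fs,
                                      pp$group, pp$subject_id))
  expect_equal(es3$n_rejected, 0L)

  # too few surviving epochs is an explicit per-subject failure
  x3 <- pp$data
  x3["Cz", seq(1, ncol(x3), by = 15000)] <- 200
  expect_error(
    segment_and_reject(recording(x3, pp$channel_labels, pp$fs, pp$group, "S99")),
    "S99"
  )
})

test_that("rejection never alters retained data values", {
  set.seed(11)
  rec <- make_eeg_recording(function(ch, n, fs) rnorm(n, sd = 10))
  pp <- preprocess_recording(rec)
  es <- segment_and_reject(pp)
  expect_identical(es$epochs[[1]], pp$data[, 1:20000])
})

test_that("band extraction passes in-band tones and rejects out-of-band ones", {
  t <- seq_len(20000) / 500
  tone6 <- matrix(sin(2 * pi * 6 * t), 1)
  es <- make_epoch_set(list(tone6))
  theta <- extract_band(es, "theta")$epochs[[1]]
  alpha <- extract_band(es, "alpha")$epochs[[1]]
  mid <- 2000:18000
  expect_gt(sd(theta[1, mid]) / sd(tone6[1, mid]), 0.9)
  expect_lt(20 * log10(sd(alpha[1, mid]) / sd(tone6[1, mid])), -20)

  zero <- make_epoch_set(list(matrix(0, 1, 20000)))
  expect_equal(max(abs(extract_band(zero, "delta")$epochs[[1]])), 0)
  expect_error(extract_band(es, "gamma"), "unknown band")
})

test_that("band filtering is zero-phase (pulse peak is not displaced)", {
  t <- seq_len(20000) / 500
  burst <- exp(-((t - 20)^2) / (2 * 0.5^2)) * cos(2 * pi * 6 * (t - 20))
  es <- make_epoch_set(list(matrix(burst, 1)))
  out <- extract_band(es, "theta")$epochs[[1]][1, ]
  expect_lte(abs(which.max(out) - which.max(burst)), 1)
})

test_that("band-passed white noise concentrates its power in band", {
  set.seed(12)
  es <- make_epoch_set(purrr::map(1:4, ~matrix(rnorm(20000), 1)))
  for (b in c("delta", "theta", "alpha")) {
    be <- extract_band(es, b)
    ps <- welch_psd(be)
    edges <- neurofuse:::band_edges(b)
    inband <- ps$frequencies >= edges[1] - 0.5 & ps$frequencies <= edges[2] + 0.5
    expect_gt(sum(ps$density[1, inband]) / sum(ps$density[1, ]), 0.8)
  }
})
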