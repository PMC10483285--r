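test_that("cohort generation is deterministic and structurally sound", {
  cfg <- test_cohort_config(seed = 77L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)

  expect_length(c1$eeg, 4)
  expect_equal(purrr::map_chr(c1$eeg, "group"),
               rep(c("patient", "control"), each = 2))
  expect_identical(purrr::map_chr(c1$eeg, "subject_id"),
                   purrr::map_chr(c1$fnirs, "subject_id"))
  for (rec in c1$eeg) {
    expect_equal(nrow(rec$data), 28)
    expect_true(all(is.finite(rec$data)))
  }
  for (rec in c1$fnirs) expect_equal(nrow(rec$data), 8)
})

test_that("clean recordings stay inside the rejection threshold, artifacts do not", {
  cfg <- test_cohort_config(n_per_group = 1L, seed = 78L)
  rec <- generate_eeg_cohort(cfg)[[1]]
  pp <- preprocess_recording(rec)
  expect_lt(max(abs(pp$data)), 100)

  cfg2 <- test_cohort_config(n_per_group = 1L, seed = 78L, artifact_rate = 1)
  rec2 <- generate_eeg_cohort(cfg2)[[1]]
  pp2 <- preprocess_recording(rec2)
  expect_gt(max(abs(pp2$data)), 100)
  expect_error(segment_and_reject(pp2), "artifact-free")
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_per_group = 0L), "positive")
  expect_error(test_cohort_config(
    asymmetry_shift = list(patient = c("theta:XX-YY" = 2), control = numeric(0))
  ), "unknown electrode pair")
  expect_error(test_cohort_config(coupling_kappa = flat_band_matrix(-1)))
})

test_that("zero jitter yields complete phase locking in every band", {
  # one band active at a time: with multi-band content the (attenuated)
  # neighbouring-band leakage beats against the band tone and PLV is only
  # near 1, not 1
  for (b in c("delta", "theta", "alpha")) {
    amp <- c(delta = 0, theta = 0, alpha = 0)
    amp[b] <- 20
    cfg <- test_cohort_config(
      n_per_group = 1L, seed = 80L,
      coupling_kappa = flat_band_matrix(0), local_coupling = flat_band_matrix(0),
      asymmetry_shift = no_asym, band_amplitude_uV = amp,
      noise_rms_uV = 1e-9, subject_rho_sd = 0
    )
    rec <- generate_eeg_cohort(cfg)[[1]]
    es <- segment_and_reject(preprocess_recording(rec))
    plv <- plv_by_band(es, b)[[b]]$values
    expect_gt(min(plv), 0.999)
  }
})

test_that("pairwise PLV matches the analytic jitter limit exp(-sigma^2/2)", {
  # single active band isolates the planted coupling from band leakage
  for (sg in c(0.7)) {
    cfg <- test_cohort_config(
      n_per_group = 3L, seed = 81L,
      coupling_kappa = flat_band_matrix(sg), local_coupling = flat_band_matrix(0),
      asymmetry_shift = no_asym,
      band_amplitude_uV = c(delta = 0, theta = 20, alpha = 0),
      noise_rms_uV = 1e-9, subject_rho_sd = 0
    )
    co <- generate_eeg_cohort(cfg)
    plvs <- purrr::map_dbl(co, function(rec) {
      es <- segment_and_reject(preprocess_recording(rec))
      plv_matrix(extract_band(es, "theta"))$values["F7", "O2"]
    })
    se <- sd(plvs) / sqrt(length(plvs))
    expect_lt(abs(mean(plvs) - exp(-sg^2 / 2)), max(3 * se, 0.02))
  }
})

test_that("local coupling raises nearby-pair synchrony over distant pairs", {
  cfg <- test_cohort_config(
    n_per_group = 1L, seed = 82L,
    asymmetry_shift = no_asym
  )
  rec <- generate_eeg_cohort(cfg)[[1]]  # patient: strong local coupling
  es <- segment_and_reject(preprocess_recording(rec))
  plv <- plv_by_band(es, "delta")$delta$values
  near <- plv["FC1", "FC2"]
  far <- plv["F7", "O2"]
  expect_gt(near, far)
})

test_that("a planted theta power-ratio shift dominates the asymmetry scores", {
  cfg <- test_cohort_config(
    n_per_group = 1L, seed = 83L,
    asymmetry_shift = list(patient = c("theta:FC2-FC1" = 2.0),
                           control = numeric(0)),
    subject_asym_sd = 0
  )
  rec <- generate_eeg_cohort(cfg)[[1]]
  es <- segment_and_reject(preprocess_recording(rec))
  af <- asymmetry_features(es, "theta")
  target <- af$score[af$pair == "FC2-FC1"]
  expect_gt(target, 0)
  expect_equal(which.max(af$score), which(af$pair == "FC2-FC1"))
})

test_that("fNIRS noise and imbalance land in the planted directions", {
  # paired construction: the same oscillation realizations with and without
  # irregularity noise, so every subject's noiseless series is the more
  # regular one
  mk <- function(noise) test_cohort_config(
    n_per_group = 2L, seed = 84L,
    entropy_noise_sd = c(patient = noise, control = noise),
    li_imbalance = c(patient = 0, control = 0)
  )
  pure <- generate_fnirs_cohort(mk(1e-12))
  noisy <- generate_fnirs_cohort(mk(1.0))
  se_pure <- purrr::map_dbl(pure, function(rec) {
    sample_entropy(preprocess_hbo2(rec)$data[1, ])
  })
  se_noisy <- purrr::map_dbl(noisy, function(rec) {
    sample_entropy(preprocess_hbo2(rec)$data[1, ])
  })
  expect_true(all(se_noisy > se_pure))

  # symmetric signals give LI ~ 0, planted imbalance makes it positive
  cfg0 <- test_cohort_config(
    n_per_group = 2L, seed = 85L,
    li_imbalance = c(patient = 0.5, control = 0)
  )
  co0 <- generate_fnirs_cohort(cfg0)
  lis <- purrr::map_dbl(co0, function(rec) laterality_index(preprocess_hbo2(rec)))
  expect_gt(min(lis[1:2]), 0)          # every patient right-dominant
  expect_lt(max(abs(lis[3:4])), 0.15)  # controls near symmetric
})

test_that("cohort CSV round trip through the manifest is lossless", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_per_group = 1L, duration_eeg = 2, duration_fnirs = 2,
                       seed = 86L)
  co <- generate_cohort(cfg)
  manifest <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(file.path(dir, "manifest.csv"))
  expect_equal(back$eeg[[1]]$data, co$eeg[[1]]$data, tolerance = 1e-12)
  expect_identical(back$eeg[[1]]$group, "patient")

  # a missing file is reported with the subject id
  file.remove(manifest$fnirs_path[1])
  expect_error(read_cohort(file.path(dir, "manifest.csv")), "S01")
})
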