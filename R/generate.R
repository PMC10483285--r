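#' Generate a synthetic EEG cohort
#'
#' Draws one [recording()] per subject under a [cohort_config()]. Each
#' channel is the sum of three band-limited oscillations (delta, theta,
#' alpha) over a 1/f background. Within a band all channels follow a common
#' driver phase plus a smooth stationary phase-jitter process (Gaussian
#' autocorrelation, correlation time `jitter_T`), built as a mixture of a
#' spatially shared field -- latent processes at every electrode mixed
#' through a Gaussian distance kernel of length `local_scale` -- and an
#' independent per-channel component, with mixing fraction `local_coupling`.
#' A spatially distant pair's phase difference therefore has stationary sd
#' `coupling_kappa` and expected phase-locking value `exp(-kappa^2/2)`,
#' while nearby channels are more synchronized, which plants clustered
#' (geometric) network topology. Right-hemisphere members of configured
#' electrode pairs have their band amplitude scaled by the square root of
#' the configured power ratio.
#'
#' Amplitudes are calibrated so that clean recordings stay well inside the
#' +/-100 uV artifact-rejection threshold; with `artifact_rate > 0`,
#' rejected-epoch test cases are produced by injecting 0.5-s 150 uV square
#' pulses into randomly chosen 40-s windows.
#'
#' @param config a [cohort_config()].
#' @return A list of [recording()] objects, patients first.
#' @seealso [generate_fnirs_cohort()], [generate_cohort()]
#' @export
generate_eeg_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_pat <- config$n_per_group[["patient"]]
  n_con <- config$n_per_group[["control"]]
  groups <- rep(c("patient", "control"), c(n_pat, n_con))
  ids <- sprintf("S%02d", seq_along(groups))
  seeds <- derive_seeds(config$seed, length(groups))
  purrr::map(seq_along(groups), function(i) {
    set.seed(seeds[i])
    generate_eeg_subject(config, groups[i], ids[i])
  })
}

generate_eeg_subject <- function(config, group, id) {
  fs <- config$fs_eeg
  n <- round(config$duration_eeg * fs)
  channels <- config$eeg_channels
  nch <- length(channels)
  bands <- eeg_bands()$band
  centre_freq <- c(delta = 2.25, theta = 6, alpha = 10.5)

  # per-subject amplitude ratios for every (band, pair); base ratio 1 unless
  # the config plants a shift for this group
  pairs <- symmetric_pairs()
  ratio <- matrix(1, nrow = length(bands), ncol = nrow(pairs),
                  dimnames = list(bands, pairs$pair))
  shifts <- config$asymmetry_shift[[group]]
  if (length(shifts)) {
    keys <- strsplit(names(shifts), ":", fixed = TRUE)
    for (k in seq_along(shifts)) {
      ratio[keys[[k]][1], keys[[k]][2]] <- shifts[[k]]
    }
  }
  ratio[] <- exp(rnorm(length(ratio), log(ratio), config$subject_asym_sd))

  # knot grid for the smooth phase jitter (Gaussian autocorrelation with
  # correlation time jitter_T, so the jitter spectrum fits inside every
  # analysis band and the planted phase-difference variance is preserved
  # through band-pass filtering)
  knot_fs <- 20          # ample for jitter band-limited below ~1 Hz
  nk <- floor(config$duration_eeg * knot_fs) + 2L
  jitter_T <- config$jitter_T %||% 0.5

  sig <- matrix(0, nrow = nch, ncol = n, dimnames = list(channels, NULL))
  # one coupling deviation per subject, shared across bands: a subject who
  # couples locally more than their group mean does so in every band, so
  # band-wise network features are correlated within subject while each
  # band's group contrast keeps its full size
  z_rho <- rnorm(1)
  z_scale <- rnorm(1)
  for (b in bands) {
    kappa <- config$coupling_kappa[b, group]
    rho <- clamp(config$local_coupling[b, group] + config$subject_rho_sd * z_rho,
                 0, 0.95)
    lscale <- max(config$local_scale[b, group] + config$subject_scale_sd * z_scale,
                  0.15)
    loadings <- spatial_loadings(channels, length_scale = lscale)
    s_ch <- kappa / sqrt(2)             # per-channel jitter sd
    # shared spatial jitter: latent processes at every electrode, mixed
    # through the Gaussian distance kernel, so nearby channels share jitter
    # and the pairwise phase-difference sd shrinks smoothly with distance
    ge <- smooth_noise_matrix(nk, 2L * nch, 1 / knot_fs, s_ch, jitter_T)
    shared <- ge[, seq_len(nch), drop = FALSE] %*% t(loadings)
    e_knots <- ge[, nch + seq_len(nch), drop = FALSE]
    amp_b <- config$band_amplitude_uV[[b]]
    knots <- matrix(0, nrow = nk, ncol = nch)
    amp <- numeric(nch)
    theta0 <- numeric(nch)
    for (ci in seq_len(nch)) {
      ch <- channels[ci]
      knots[, ci] <- rho * shared[, ci] + sqrt(1 - rho^2) * e_knots[, ci]
      theta0[ci] <- runif(1, 0, 2 * pi)
      a <- amp_b
      pr <- which(pairs$right == ch)
      if (length(pr)) a <- a * sqrt(ratio[b, pairs$pair[pr]])
      # left members keep the base amplitude; the pair ratio is carried by
      # the right channel so the planted power ratio equals `ratio` exactly
      amp[ci] <- a
    }
    cpp_add_band(sig, centre_freq[[b]], fs, knots, 1 / knot_fs, amp, theta0)
  }
  cpp_add_upsampled(sig, pink_noise_low(n, nch, config$noise_rms_uV), 8)

  if (config$artifact_rate > 0) {
    win <- 40 * fs
    starts <- seq(10 * fs + 1, n - win + 1, by = win)
    for (st in starts) {
      if (runif(1) < config$artifact_rate) {
        at <- st + sample.int(win - fs / 2, 1)
        idx <- at:(at + fs / 2 - 1)
        sig[sample.int(nch, 1), idx] <- sig[sample.int(nch, 1), idx] + 150
      }
    }
  }
  recording(sig, channels, fs = fs, group = group, subject_id = id)
}

#' Generate a synthetic fNIRS (HbO2) cohort
#'
#' Eight forehead channels per subject: a set of slow oscillations
#' (0.02-0.08 Hz) with phases shared across channels (plus small
#' channel-specific phase offsets and an independent slow component, so ROI
#' correlations are high but not unity), irregularity noise band-limited to
#' the fast edge of the haemodynamic band (0.07-0.25 Hz) with group-specific
#' amplitude `entropy_noise_sd` (tilting the in-band spectrum toward its
#' fast edge, which raises sample entropy and mildly decorrelates the
#' ROIs), and right-side channels scaled by `1 + li_imbalance`.
#' Subject ids and groups align with [generate_eeg_cohort()] under the same
#' config.
#'
#' @inheritParams generate_eeg_cohort
#' @return A list of [recording()] objects, patients first.
#' @export
generate_fnirs_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_pat <- config$n_per_group[["patient"]]
  n_con <- config$n_per_group[["control"]]
  groups <- rep(c("patient", "control"), c(n_pat, n_con))
  ids <- sprintf("S%02d", seq_along(groups))
  seeds <- derive_seeds(config$seed + 500009L, length(groups))
  purrr::map(seq_along(groups), function(i) {
    set.seed(seeds[i])
    generate_fnirs_subject(config, groups[i], ids[i])
  })
}

generate_fnirs_subject <- function(config, group, id) {
  fs <- config$fs_fnirs
  n <- round(config$duration_fnirs * fs)
  t <- (seq_len(n) - 1) / fs
  channels <- config$fnirs_channels
  side <- fnirs_side_map()
  freqs <- c(0.02, 0.033, 0.05, 0.08)
  amps <- c(0.5, 0.4, 0.35, 0.25)
  psi <- runif(length(freqs), 0, 2 * pi)
  noise_sd <- exp(rnorm(1, log(config$entropy_noise_sd[[group]]),
                        config$subject_entropy_sd))
  li <- rnorm(1, config$li_imbalance[[group]], 0.05)

  sig <- matrix(0, nrow = length(channels), ncol = n,
                dimnames = list(channels, NULL))
  for (ci in seq_along(channels)) {
    x <- numeric(n)
    delta_ph <- rnorm(length(freqs), 0, 0.3)
    for (k in seq_along(freqs)) {
      x <- x + amps[k] * cos(2 * pi * freqs[k] * t + psi[k] + delta_ph[k])
    }
    f_own <- runif(1, 0.01, 0.1)
    x <- x + 0.2 * cos(2 * pi * f_own * t + runif(1, 0, 2 * pi))
    # irregularity noise concentrated at the upper edge of the haemodynamic
    # band (0.07-0.25 Hz): the part surviving the 0.01-0.1 Hz preprocessing
    # band-pass tilts the in-band spectrum toward its fast edge, which is
    # what raises sample entropy at the 0.2-s embedding delay. Broadband
    # white noise does not work here: its in-band remnant is smooth and only
    # inflates the entropy tolerance r = 0.2 SD
    irr <- bandpass_filtfilt(rnorm(n), 0.07, 0.25, fs, order = 4)
    x <- x + irr * (noise_sd / stats::sd(irr))
    if (side[[channels[ci]]] == "right") x <- x * (1 + li)
    sig[ci, ] <- x
  }
  recording(sig, channels, fs = fs, group = group, subject_id = id)
}

#' Generate a paired EEG + fNIRS cohort
#'
#' @inheritParams generate_eeg_cohort
#' @return A list with elements `eeg` and `fnirs`, each a list of
#'   [recording()] objects with aligned subject ids and groups.
#' @export
generate_cohort <- function(config) {
  list(eeg = generate_eeg_cohort(config),
       fnirs = generate_fnirs_cohort(config))
}

#' Write a cohort to disk with a manifest
#'
#' One CSV per subject per modality plus a `manifest.csv` with columns
#' `subject_id`, `group`, `eeg_path`, `fnirs_path`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest as a tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map2_dfr(cohort$eeg, cohort$fnirs, function(e, f) {
    stopifnot(identical(e$subject_id, f$subject_id))
    ep <- file.path(dir, paste0(e$subject_id, "_eeg.csv"))
    fp <- file.path(dir, paste0(f$subject_id, "_fnirs.csv"))
    write_recording(e, ep)
    write_recording(f, fp)
    tibble(subject_id = e$subject_id, group = e$group,
           eeg_path = ep, fnirs_path = fp)
  })
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path path to a `manifest.csv` written by [write_cohort()].
#' @return A list with elements `eeg` and `fnirs` as in [generate_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  manifest <- read.csv(manifest_path)
  dir <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, basename(p))
  for (i in seq_len(nrow(manifest))) {
    for (col in c("eeg_path", "fnirs_path")) {
      p <- resolve(manifest[[col]][i])
      if (!file.exists(p)) {
        abort(paste0("missing ", col, " for subject ", manifest$subject_id[i]))
      }
      manifest[[col]][i] <- p
    }
  }
  list(eeg = purrr::map(manifest$eeg_path, read_recording),
       fnirs = purrr::map(manifest$fnirs_path, read_recording))
}
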