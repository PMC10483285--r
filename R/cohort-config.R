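#' Synthetic cohort configuration
#'
#' Defines the study conditions a simulated cohort is drawn under: cohort
#' sizes, recording geometry, and the planted group effects. The defaults
#' reproduce the structure of the clinical study the pipeline targets: 25
#' patients and 30 controls, 6-minute simultaneous recordings (28-channel EEG
#' at 500 Hz, 8-channel forehead HbO2 at 10 Hz), stronger local phase
#' coupling in the delta and theta bands of patients (driving their higher
#' clustering coefficient and local efficiency), a right-dominant theta power
#' shift at FC2-FC1 in patients, higher HbO2 irregularity (sample entropy) in
#' patients, and a small rightward haemodynamic imbalance in patients.
#'
#' Phase coupling is parameterised so that a spatially distant channel pair
#' in band b has phase-difference standard deviation `coupling_kappa[b, g]`
#' (radians) and therefore an expected phase-locking value of
#' `exp(-kappa^2 / 2)`. Each channel draws a fraction `local_coupling[b, g]`
#' of its phase jitter from a spatially shared field whose correlation
#' decays with scalp distance over `local_scale[b, g]` head-radius units,
#' so nearby channels synchronize more strongly and the thresholded
#' networks acquire clustered, geometry-driven topology.
#'
#' @param n_per_group named integer vector `c(patient = , control = )`, or a
#'   single integer used for both groups.
#' @param eeg_channels ordered EEG labels (default the 28-label montage).
#' @param fs_eeg,duration_eeg EEG rate (Hz) and length (s).
#' @param fnirs_channels,fs_fnirs,duration_fnirs fNIRS labels, rate, length.
#' @param coupling_kappa 3 x 2 matrix (bands x groups) of phase-jitter scales
#'   sigma in radians; sigma >= 0.
#' @param local_coupling 3 x 2 matrix of jitter-sharing fractions in
#'   [0, 1): the fraction of each channel's phase jitter drawn from the
#'   spatially shared field.
#' @param local_scale 3 x 2 matrix of kernel length scales (head-radius
#'   units) of the shared field: larger scales couple wider neighbourhoods
#'   and plant more clustered (higher C / LE) thresholded networks.
#' @param asymmetry_shift named list per group; each element a named numeric
#'   vector of right/left band-power ratios keyed `"<band>:<pair>"`, e.g.
#'   `c("theta:FC2-FC1" = 1.5)`. Unlisted pairs have ratio 1.
#' @param entropy_noise_sd named vector, amplitude (uM) of the band-limited
#'   (0.07-0.25 Hz) irregularity noise added to each group's HbO2 channels;
#'   the part surviving preprocessing raises sample entropy.
#' @param li_imbalance named vector, right-minus-left HbO2 amplitude factor
#'   per group: right-side channels are scaled by `1 + li_imbalance`.
#' @param band_amplitude_uV amplitudes of the delta/theta/alpha oscillations
#'   (uV); `noise_rms_uV` the 1/f background RMS.
#' @param subject_rho_sd,subject_asym_sd,subject_entropy_sd between-subject
#'   heterogeneity: sd of the per-subject local-coupling fraction, of the
#'   per-subject log power ratio for every pair, and of the per-subject log
#'   noise amplitude.
#' @param jitter_T correlation time (s) of the smooth phase-jitter
#'   processes; its Gaussian autocorrelation keeps the jitter spectrum
#'   inside every analysis band.
#' @param artifact_rate probability that an EEG epoch receives an injected
#'   high-amplitude (>100 uV) artifact; 0 disables injection.
#' @param seed integer RNG seed; identical config + seed gives a
#'   bit-identical cohort.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_per_group = c(patient = 25L, control = 30L),
                          eeg_channels = eeg_montage(),
                          fs_eeg = 500, duration_eeg = 360,
                          fnirs_channels = paste0("ch", 1:8),
                          fs_fnirs = 10, duration_fnirs = 360,
                          coupling_kappa = default_coupling_kappa(),
                          local_coupling = default_local_coupling(),
                          local_scale = default_local_scale(),
                          asymmetry_shift = default_asymmetry_shift(),
                          entropy_noise_sd = c(patient = 1.3, control = 0.4),
                          li_imbalance = c(patient = 0.15, control = 0.0),
                          band_amplitude_uV = c(delta = 18, theta = 12, alpha = 22),
                          noise_rms_uV = 8,
                          subject_rho_sd = 0.05,
                          subject_scale_sd = 0.035,
                          subject_asym_sd = 0.15,
                          subject_entropy_sd = 0.15,
                          jitter_T = 0.5,
                          artifact_rate = 0,
                          seed = 1L) {
  if (length(n_per_group) == 1L) {
    n_per_group <- c(patient = as.integer(n_per_group),
                     control = as.integer(n_per_group))
  }
  n_per_group <- n_per_group[c("patient", "control")]
  if (anyNA(n_per_group) || any(n_per_group <= 0)) {
    abort("n_per_group must be positive for both 'patient' and 'control'")
  }
  stopifnot(fs_eeg > 0, duration_eeg > 0, fs_fnirs > 0, duration_fnirs > 0)
  coupling_kappa <- check_band_group_matrix(coupling_kappa, "coupling_kappa")
  if (any(coupling_kappa < 0)) abort("coupling_kappa must be >= 0")
  local_coupling <- check_band_group_matrix(local_coupling, "local_coupling")
  if (any(local_coupling < 0 | local_coupling >= 1)) {
    abort("local_coupling fractions must lie in [0, 1)")
  }
  local_scale <- check_band_group_matrix(local_scale, "local_scale")
  if (any(local_scale <= 0)) abort("local_scale must be positive")
  for (g in c("patient", "control")) {
    shifts <- asymmetry_shift[[g]]
    if (length(shifts)) {
      keys <- strsplit(names(shifts), ":", fixed = TRUE)
      bands <- vapply(keys, `[`, "", 1L)
      pairs <- vapply(keys, `[`, "", 2L)
      if (!all(bands %in% eeg_bands()$band)) {
        abort("asymmetry_shift keys must start with a valid band name")
      }
      if (!all(pairs %in% symmetric_pairs()$pair)) {
        abort("asymmetry_shift names an unknown electrode pair")
      }
      if (any(shifts <= 0)) abort("asymmetry_shift ratios must be positive")
    }
  }
  cfg <- list(
    n_per_group = n_per_group, eeg_channels = eeg_channels,
    fs_eeg = fs_eeg, duration_eeg = duration_eeg,
    fnirs_channels = fnirs_channels, fs_fnirs = fs_fnirs,
    duration_fnirs = duration_fnirs,
    coupling_kappa = coupling_kappa, local_coupling = local_coupling,
    local_scale = local_scale, asymmetry_shift = asymmetry_shift,
    entropy_noise_sd = entropy_noise_sd[c("patient", "control")],
    li_imbalance = li_imbalance[c("patient", "control")],
    band_amplitude_uV = band_amplitude_uV, noise_rms_uV = noise_rms_uV,
    subject_rho_sd = subject_rho_sd, subject_scale_sd = subject_scale_sd,
    subject_asym_sd = subject_asym_sd,
    subject_entropy_sd = subject_entropy_sd, jitter_T = jitter_T,
    artifact_rate = artifact_rate, seed = as.integer(seed)
  )
  structure(cfg, class = "cohort_config")
}

check_band_group_matrix <- function(m, what) {
  bands <- eeg_bands()$band
  groups <- c("patient", "control")
  if (!is.matrix(m) || !setequal(rownames(m), bands) ||
      !setequal(colnames(m), groups)) {
    abort(paste0(what, " must be a matrix with rows ",
                 paste(bands, collapse = "/"), " and columns patient/control"))
  }
  m[bands, groups]
}

band_group_matrix <- function(patient, control) {
  m <- cbind(patient = patient, control = control)
  rownames(m) <- eeg_bands()$band
  m
}

#' @rdname cohort_config
#' @export
default_coupling_kappa <- function() {
  band_group_matrix(patient = c(1.5, 1.5, 1.5), control = c(1.5, 1.5, 1.5))
}

#' @rdname cohort_config
#' @export
default_local_coupling <- function() {
  band_group_matrix(patient = c(0.75, 0.75, 0.55), control = c(0.50, 0.50, 0.55))
}

#' @rdname cohort_config
#' @export
default_local_scale <- function() {
  band_group_matrix(patient = c(0.75, 0.75, 0.30), control = c(0.25, 0.25, 0.30))
}

#' @rdname cohort_config
#' @export
default_asymmetry_shift <- function() {
  list(patient = c("theta:FC2-FC1" = 1.25), control = numeric(0))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d patients + %d controls, seed %d\n",
              x$n_per_group[["patient"]], x$n_per_group[["control"]], x$seed))
  cat(sprintf("  EEG: %d ch @ %g Hz, %g s; fNIRS: %d ch @ %g Hz, %g s\n",
              length(x$eeg_channels), x$fs_eeg, x$duration_eeg,
              length(x$fnirs_channels), x$fs_fnirs, x$duration_fnirs))
  invisible(x)
}
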