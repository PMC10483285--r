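#' Per-subject EEG analysis
#'
#' Runs one subject's EEG through the full chain -- preprocessing, epoching
#' with artifact rejection, band extraction, PLV connectivity, the
#' proportional-threshold metric sweep, and Welch spectral asymmetry -- and
#' returns the network AUC features (6 metrics x 3 bands), the asymmetry
#' scores (11 pairs x 3 bands) and the underlying metric curves.
#'
#' @param rec a raw EEG [recording()].
#' @param thresholds proportional-threshold grid for the metric sweep.
#' @param band_method `"spectral"` computes the band-limited analytic
#'   signals with [plv_by_band()] (one FFT round trip per epoch);
#'   `"filtfilt"` uses the time-domain [extract_band()] + [plv_matrix()]
#'   composition. The two agree to well under 0.01 in PLV.
#' @return List with tibbles `auc` (`band`, `metric`, `auc`), `asym`
#'   (`band`, `pair`, `score`) and `curves` (`band`, `metric`, `threshold`,
#'   `value`).
#' @export
subject_eeg_analysis <- function(rec, thresholds = seq(0.2, 0.5, by = 0.01),
                                 band_method = c("spectral", "filtfilt")) {
  band_method <- match.arg(band_method)
  es <- segment_and_reject(preprocess_recording(rec))
  bands <- eeg_bands()$band
  plvs <- if (band_method == "spectral") {
    plv_by_band(es, bands)
  } else {
    purrr::map(setNames(bands, bands),
               function(b) plv_matrix(extract_band(es, b)))
  }
  net <- purrr::map_dfr(bands, function(b) {
    metric_curves(plvs[[b]], thresholds = thresholds) %>%
      mutate(band = b, .before = 1)
  })
  ps <- welch_psd(es)
  asym <- purrr::map_dfr(bands, function(b) asymmetry_features(ps, b))
  auc <- net %>%
    group_by(.data$band, .data$metric) %>%
    summarise(auc = trapezoid(.data$threshold, .data$value), .groups = "drop")
  list(auc = auc, asym = asym, curves = net)
}

#' Per-subject fNIRS analysis
#'
#' Preprocesses the HbO2 recording and extracts per-channel sample entropy
#' (m = 2, r = 0.2 SD, tau = 2), the 6 Fisher-Z ROI connectivity values and
#' the laterality index.
#'
#' @param rec a raw fNIRS [recording()].
#' @return List with `sampen` (tibble `channel`, `value`), `roi` (tibble
#'   `pair`, `r`, `z`) and `li` (scalar).
#' @export
subject_fnirs_analysis <- function(rec) {
  h <- preprocess_hbo2(rec)
  sampen <- tibble(
    channel = h$channel_labels,
    value = purrr::map_dbl(seq_along(h$channel_labels),
                           function(i) sample_entropy(h$data[i, ]))
  )
  list(sampen = sampen, roi = roi_connectivity(h), li = laterality_index(h))
}

#' Assemble the subject-by-feature matrix
#'
#' Runs every subject of a cohort through [subject_eeg_analysis()] and
#' [subject_fnirs_analysis()] and assembles the 66 named features: 18
#' network AUCs (`eeg_auc_<metric>_<band>`), 33 asymmetry scores
#' (`eeg_asym_<band>_<pair>`), 8 sample entropies (`fnirs_sampen_<ch>`), 6
#' ROI connectivities (`fnirs_z_<roiA>_<roiB>`) and 1 laterality index
#' (`fnirs_li`). Feature modality is encoded in the `eeg_` / `fnirs_` name
#' prefix.
#'
#' @param cohort list with `eeg` and `fnirs` recording lists (see
#'   [generate_cohort()]); `fnirs` may be `NULL` for an EEG-only matrix.
#' @param keep_curves also return the per-subject metric curves.
#' @return A tibble with `subject_id`, `group` and one column per feature
#'   (no missing values). With `keep_curves = TRUE`, a list `features` +
#'   `curves`.
#' @export
build_feature_matrix <- function(cohort, keep_curves = FALSE) {
  eeg <- cohort$eeg
  fnirs <- cohort$fnirs
  if (!is.null(fnirs) && length(fnirs) != length(eeg)) {
    abort("eeg and fnirs cohorts must have the same subjects")
  }
  rows <- vector("list", length(eeg))
  curves <- vector("list", length(eeg))
  for (i in seq_along(eeg)) {
    rec <- eeg[[i]]
    ea <- subject_eeg_analysis(rec)
    feats <- c(
      setNames(ea$auc$auc,
               paste0("eeg_auc_", ea$auc$metric, "_", ea$auc$band)),
      setNames(ea$asym$score,
               paste0("eeg_asym_", ea$asym$band, "_",
                      gsub("-", "_", ea$asym$pair)))
    )
    if (!is.null(fnirs)) {
      if (!identical(fnirs[[i]]$subject_id, rec$subject_id)) {
        abort(paste0("subject id mismatch between modalities at position ", i))
      }
      fa <- subject_fnirs_analysis(fnirs[[i]])
      feats <- c(
        feats,
        setNames(fa$sampen$value, paste0("fnirs_sampen_", fa$sampen$channel)),
        setNames(fa$roi$z,
                 paste0("fnirs_z_", gsub("-", "_", fa$roi$pair))),
        fnirs_li = fa$li
      )
    }
    rows[[i]] <- tibble(subject_id = rec$subject_id, group = rec$group,
                        !!!as.list(feats))
    curves[[i]] <- ea$curves %>%
      mutate(subject_id = rec$subject_id, group = rec$group, .before = 1)
  }
  features <- bind_rows(rows)
  if (anyNA(features)) abort("missing values after feature assembly")
  if (keep_curves) {
    list(features = features, curves = bind_rows(curves))
  } else {
    features
  }
}

# Names of the numeric feature columns of a feature tibble.
feature_columns <- function(features, modality = c("all", "eeg", "fnirs")) {
  modality <- match.arg(modality)
  cols <- setdiff(names(features), c("subject_id", "group"))
  switch(modality,
         all = cols,
         eeg = cols[startsWith(cols, "eeg_")],
         fnirs = cols[startsWith(cols, "fnirs_")])
}

#' Modality of each feature column
#' @param features a feature tibble.
#' @return Tibble `feature`, `modality` ("EEG" or "fNIRS").
#' @export
feature_modalities <- function(features) {
  cols <- feature_columns(features)
  tibble(feature = cols,
         modality = ifelse(startsWith(cols, "eeg_"), "EEG", "fNIRS"))
}
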