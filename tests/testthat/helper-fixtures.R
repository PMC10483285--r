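# Fixture builders shared across the test files. All data is generated in
# code; the EEG fixtures use the shortest duration that still yields the
# four analysis epochs (10 s discard + 4 x 40 s).

make_epoch_set <- function(epochs, fs = 500, labels = NULL, band = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(epochs[[1]])))
  es <- structure(
    list(epochs = epochs, fs = fs, channel_labels = labels,
         epoch_s = ncol(epochs[[1]]) / fs, n_rejected = 0L,
         group = "control", subject_id = "T01"),
    class = "epoch_set"
  )
  if (!is.null(band)) {
    es$band <- band
    class(es) <- c("band_epochs", "epoch_set")
  }
  es
}

make_hbo2 <- function(data, labels = paste0("ch", 1:8)) {
  rownames(data) <- labels
  structure(
    list(data = data, fs = 10, channel_labels = labels,
         group = "control", subject_id = "T01"),
    class = "hbo2_series"
  )
}

# A raw 28-channel recording with prescribed per-channel content.
make_eeg_recording <- function(fill, duration = 190, fs = 500,
                               group = "control", id = "T01") {
  n <- duration * fs
  chans <- eeg_montage()
  data <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
  for (ch in chans) data[ch, ] <- fill(ch, n, fs)
  recording(data, chans, fs = fs, group = group, subject_id = id)
}

test_cohort_config <- function(n_per_group = 2L, seed = 42L, ...) {
  cohort_config(n_per_group = n_per_group, duration_eeg = 190,
                duration_fnirs = 240, seed = seed, ...)
}

flat_band_matrix <- function(v) {
  m <- default_local_coupling()
  m[] <- v
  m
}

no_asym <- list(patient = numeric(0), control = numeric(0))
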