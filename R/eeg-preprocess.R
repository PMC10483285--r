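#' EEG preprocessing chain
#'
#' Implements the standard resting-state chain: drop the muscle-contaminated
#' temporal channels T7/T8, apply a 50 Hz notch (second-order IIR, quality
#' factor 35) and a 0.5-30 Hz Butterworth band-pass, discard the first 10 s,
#' and re-reference to the average of the remaining 26 channels. All filters
#' run forward-backward ([signal::filtfilt()]) so they are zero-phase.
#'
#' @param rec a [recording()] containing at least the 28-channel montage.
#' @param fs_expected required sampling rate (Hz).
#' @param discard_s initial segment dropped (s).
#' @return A 26-channel [recording()], `discard_s` shorter than the input.
#' @export
preprocess_recording <- function(rec, fs_expected = 500, discard_s = 10) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs != fs_expected) {
    abort(sprintf("expected fs = %g Hz, got %g Hz", fs_expected, rec$fs))
  }
  if (!all(c("T7", "T8") %in% rec$channel_labels)) {
    abort("recording must contain T7 and T8 (removed during preprocessing)")
  }
  missing <- setdiff(eeg_montage(), rec$channel_labels)
  if (length(missing)) {
    abort(paste0("missing expected channels: ", paste(missing, collapse = ", ")))
  }
  if (ncol(rec$data) <= discard_s * rec$fs) {
    abort(paste0("recording too short for subject ", rec$subject_id))
  }
  keep <- setdiff(rec$channel_labels, c("T7", "T8"))
  x <- rec$data[keep, , drop = FALSE]
  notch <- notch_coefficients(f0 = 50, fs = rec$fs, q = 35)
  bp <- signal::butter(2, c(0.5, 30) / (rec$fs / 2), type = "pass")
  x <- cpp_filtfilt_rows(
    x,
    list(notch$b, bp$b), list(notch$a, bp$a),
    list(lfilter_zi(notch$b, notch$a), lfilter_zi(bp$b, bp$a))
  )
  rownames(x) <- keep
  x <- x[, -seq_len(discard_s * rec$fs), drop = FALSE]
  x <- sweep(x, 2, colMeans(x))         # average reference
  recording(x, keep, fs = rec$fs, group = rec$group, subject_id = rec$subject_id)
}

# Zero-phase Butterworth band-pass; `order` is the order of the resulting
# band-pass transfer function (so order = 4 uses signal::butter(2, ...)).
bandpass_filtfilt <- function(x, f1, f2, fs, order = 4) {
  bf <- signal::butter(order / 2, c(f1, f2) / (fs / 2), type = "pass")
  fast_filtfilt(bf$b, bf$a, x)
}

notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase second-order IIR notch with quality factor q.
notch_filtfilt <- function(x, f0, fs, q) {
  co <- notch_coefficients(f0, fs, q)
  fast_filtfilt(co$b, co$a, x)
}

#' Segment a preprocessed recording into epochs and reject artifacts
#'
#' Cuts consecutive non-overlapping epochs (40 s by default), drops every
#' epoch containing any sample with absolute value strictly exceeding the
#' amplitude threshold (+/-100 uV), and keeps the first `max_epochs`
#' survivors. At 500 Hz a 40-s epoch holds exactly 20000 samples.
#'
#' @param rec a preprocessed 26-channel [recording()].
#' @param epoch_s epoch length in seconds.
#' @param max_epochs number of surviving epochs retained.
#' @param amp_threshold_uV rejection threshold; strict inequality, so epochs
#'   touching exactly the threshold are retained.
#' @return An `epoch_set`: list with `epochs` (list of channels x samples
#'   matrices), `fs`, `channel_labels`, `epoch_s`, `n_rejected`, `group`,
#'   `subject_id`.
#' @export
segment_and_reject <- function(rec, epoch_s = 40, max_epochs = 4,
                               amp_threshold_uV = 100) {
  stopifnot(inherits(rec, "recording"))
  len <- round(epoch_s * rec$fs)
  n_full <- floor(ncol(rec$data) / len)
  if (n_full < 1) abort(paste0("recording shorter than one epoch for subject ",
                               rec$subject_id))
  epochs <- list()
  n_rejected <- 0L
  for (k in seq_len(n_full)) {
    if (length(epochs) >= max_epochs) break
    e <- rec$data[, ((k - 1) * len + 1):(k * len), drop = FALSE]
    if (max(abs(e)) > amp_threshold_uV) {
      n_rejected <- n_rejected + 1L
    } else {
      epochs[[length(epochs) + 1L]] <- e
    }
  }
  if (length(epochs) < max_epochs) {
    abort(sprintf("subject %s: only %d artifact-free %g-s epochs (need %d)",
                  rec$subject_id, length(epochs), epoch_s, max_epochs))
  }
  structure(
    list(epochs = epochs, fs = rec$fs, channel_labels = rec$channel_labels,
         epoch_s = epoch_s, n_rejected = n_rejected,
         group = rec$group, subject_id = rec$subject_id),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d epochs of %g s, %d channels @ %g Hz\n",
              x$subject_id, length(x$epochs), x$epoch_s,
              length(x$channel_labels), x$fs))
  invisible(x)
}

#' Band-pass an epoch set into one EEG band
#'
#' Zero-phase Butterworth band-pass of every epoch at the band's edges:
#' delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-13 Hz.
#'
#' @param es an `epoch_set` from [segment_and_reject()].
#' @param band `"delta"`, `"theta"` or `"alpha"`.
#' @return A `band_epochs` object: the epoch set plus a `band` field.
#' @export
extract_band <- function(es, band) {
  stopifnot(inherits(es, "epoch_set"))
  edges <- band_edges(band)
  out <- es
  out$epochs <- purrr::map(es$epochs, function(e) {
    t(apply(e, 1, bandpass_filtfilt, f1 = edges[1], f2 = edges[2],
            fs = es$fs, order = 4))
  })
  out$band <- band
  class(out) <- c("band_epochs", "epoch_set")
  out
}
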