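#' Multichannel recording container
#'
#' A `recording` holds one subject's multichannel time series: a
#' channels-by-samples numeric matrix (microvolts for EEG, micromolar
#' concentration change for HbO2), ordered channel labels, the sampling rate,
#' the group label and a subject id.
#'
#' @param data numeric matrix, channels x samples.
#' @param channel_labels character vector, one label per row of `data`.
#' @param fs sampling rate in Hz.
#' @param group `"patient"` or `"control"`.
#' @param subject_id subject identifier string.
#' @return An object of class `recording`.
#' @export
recording <- function(data, channel_labels, fs, group, subject_id) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels)) {
    abort("row count of data must equal number of channel labels")
  }
  if (!all(is.finite(data))) abort("recording contains non-finite samples")
  if (!is.numeric(fs) || fs <= 0) abort("fs must be a positive rate in Hz")
  group <- match.arg(group, c("patient", "control"))
  rownames(data) <- channel_labels
  structure(
    list(data = data, channel_labels = as.character(channel_labels),
         fs = fs, group = group, subject_id = as.character(subject_id)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Write / read a recording as CSV
#'
#' Cohort CSVs are one file per subject: columns are channel labels, rows are
#' samples, and the first line is a comment header `# fs=<Hz> group=<g>
#' subject=<id>` carrying the metadata. The round trip is lossless up to
#' numeric printing precision (15 significant digits are written).
#'
#' @param rec a [recording()].
#' @param path file path.
#' @return `read_recording()` returns a [recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g group=%s subject=%s",
                     rec$fs, rec$group, rec$subject_id), con)
  df <- as.data.frame(signif(t(rec$data), 15))
  names(df) <- rec$channel_labels
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# fs=", header)) {
    abort(paste0("malformed cohort CSV header in ", path))
  }
  fields <- strsplit(sub("^# ", "", header), " ")[[1]]
  kv <- strsplit(fields, "=")
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  mat <- t(as.matrix(df))
  if (anyNA(mat)) abort(paste0("ragged or non-numeric rows in ", path))
  recording(mat, colnames(df), fs = as.numeric(meta[["fs"]]),
            group = meta[["group"]], subject_id = meta[["subject"]])
}
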