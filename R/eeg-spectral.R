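#' Welch power spectral density of an epoch set
#'
#' Hann-windowed 8.192-s segments (4096 samples at 500 Hz) with 50% overlap;
#' modified periodograms are averaged across segments and across epochs.
#' The density is one-sided and scaled so that its integral over frequency
#' equals the signal variance (Parseval).
#'
#' @param es an `epoch_set` (broadband, i.e. after [preprocess_recording()]
#'   and [segment_and_reject()]).
#' @param segment_s segment length in seconds.
#' @return A `power_spectrum`: list with `frequencies` (Hz), `density`
#'   (channels x frequencies, power per Hz), `channel_labels`, `fs`.
#' @export
welch_psd <- function(es, segment_s = 8.192) {
  stopifnot(inherits(es, "epoch_set"))
  nseg <- round(segment_s * es$fs)
  n_epoch <- ncol(es$epochs[[1]])
  if (n_epoch < nseg) abort("epoch shorter than one Welch segment")
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  scale <- 1 / (es$fs * sum(w^2))
  step <- nseg %/% 2
  starts <- seq(1, n_epoch - nseg + 1, by = step)
  nfreq <- nseg %/% 2 + 1
  nch <- length(es$channel_labels)
  # all windowed segments of all channels and epochs in one transform
  count <- length(es$epochs) * length(starts)
  segs <- matrix(0, nrow = nseg, ncol = nch * count)
  col <- 0L
  for (e in es$epochs) {
    for (st in starts) {
      segs[, col + seq_len(nch)] <- t(e[, st:(st + nseg - 1), drop = FALSE]) * w
      col <- col + nch
    }
  }
  sp <- Mod(stats::mvfft(segs)[seq_len(nfreq), , drop = FALSE])^2 * scale
  sp[2:(nfreq - 1), ] <- 2 * sp[2:(nfreq - 1), ]     # one-sided
  acc <- matrix(0, nrow = nch, ncol = nfreq)
  for (si in seq_len(count)) {
    acc <- acc + t(sp[, (si - 1) * nch + seq_len(nch), drop = FALSE])
  }
  structure(
    list(frequencies = (seq_len(nfreq) - 1) * es$fs / nseg,
         density = acc / count, channel_labels = es$channel_labels,
         fs = es$fs),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d channels, %d frequency bins (0-%.1f Hz, df=%.4g Hz)\n",
              nrow(x$density), length(x$frequencies),
              max(x$frequencies), x$frequencies[2]))
  invisible(x)
}

#' @export
tidy.power_spectrum <- function(x, ...) {
  tibble(channel = rep(x$channel_labels, times = length(x$frequencies)),
         frequency = rep(x$frequencies, each = length(x$channel_labels)),
         density = as.vector(x$density))
}

#' Relative band power of one channel
#'
#' Band power summed over the half-open interval `[f1, f2)` of the Welch
#' grid, divided by the total power over 0.5-30 Hz. Half-open band edges put
#' the 4 Hz and 8 Hz boundary bins in exactly one band each.
#'
#' @param ps a `power_spectrum`.
#' @param channel channel label.
#' @param band `"delta"`, `"theta"` or `"alpha"`.
#' @param total_range denominator frequency range (Hz).
#' @return Relative power in `[0, 1]`, or `NA` if total power is zero.
#' @export
relative_power <- function(ps, channel, band, total_range = c(0.5, 30)) {
  stopifnot(inherits(ps, "power_spectrum"))
  i <- match(channel, ps$channel_labels)
  if (is.na(i)) abort(paste0("unknown channel ", channel))
  edges <- band_edges(band)
  f <- ps$frequencies
  band_mask <- f >= edges[1] - 1e-9 & f < edges[2] - 1e-9
  total_mask <- f >= total_range[1] - 1e-9 & f <= total_range[2] + 1e-9
  total <- sum(ps$density[i, total_mask])
  if (total <= 0) return(NA_real_)
  sum(ps$density[i, band_mask & total_mask]) / total
}

#' Inter-hemispheric asymmetry scores
#'
#' For each of the 11 symmetric electrode pairs, the score is
#' `(R - L) / (R + L)` where `R` and `L` are the relative band powers of the
#' right and left electrode. Positive scores mean right-dominant band power;
#' scores are bounded in `[-1, 1]` and antisymmetric under swapping the
#' pair.
#'
#' @param es a broadband `epoch_set` (the spectrum is computed once and
#'   shared across bands), or a precomputed `power_spectrum`.
#' @param band band name.
#' @return A tibble with columns `band`, `pair`, `score` (11 rows).
#' @export
asymmetry_features <- function(es, band) {
  ps <- if (inherits(es, "power_spectrum")) es else welch_psd(es)
  pairs <- symmetric_pairs()
  need <- c(pairs$right, pairs$left)
  missing <- setdiff(need, ps$channel_labels)
  if (length(missing)) {
    abort(paste0("missing channels for asymmetry: ",
                 paste(missing, collapse = ", ")))
  }
  score <- purrr::map2_dbl(pairs$right, pairs$left, function(r, l) {
    rp <- relative_power(ps, r, band)
    lp <- relative_power(ps, l, band)
    if (rp + lp == 0) return(0)
    (rp - lp) / (rp + lp)
  })
  tibble(band = band, pair = pairs$pair, score = score)
}
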