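#' fNIRS HbO2 preprocessing
#'
#' Chain for the 8-channel forehead HbO2 series: zero-phase second-order
#' Butterworth band-pass at 0.01-0.1 Hz, removal of a third-order
#' least-squares polynomial trend, wavelet denoising (Daubechies-4, 5
#' decomposition levels, soft universal threshold), then the first 30 s are
#' discarded and a stable 3-min window is kept (1800 samples at 10 Hz).
#'
#' @param rec a [recording()] with 8 channels at 10 Hz, at least 3.5 min.
#' @param discard_s seconds discarded at the start.
#' @param keep_s length of the retained window (s).
#' @return An `hbo2_series`: list with `data` (8 x 1800 matrix, uM), `fs`,
#'   `channel_labels`, `group`, `subject_id`.
#' @export
preprocess_hbo2 <- function(rec, discard_s = 30, keep_s = 180) {
  stopifnot(inherits(rec, "recording"))
  if (length(rec$channel_labels) != 8L) abort("expected 8 fNIRS channels")
  if (rec$fs != 10) abort(sprintf("expected fs = 10 Hz, got %g", rec$fs))
  n_need <- (discard_s + keep_s) * rec$fs
  if (ncol(rec$data) < 3.5 * 60 * rec$fs || ncol(rec$data) < n_need) {
    abort(paste0("fNIRS recording too short for subject ", rec$subject_id))
  }
  n <- ncol(rec$data)
  tt <- seq_len(n) / n - 0.5
  design <- cbind(1, tt, tt^2, tt^3)
  qrd <- qr(design)
  x <- t(apply(rec$data, 1, function(ch) {
    ch <- bandpass_filtfilt(ch, 0.01, 0.1, rec$fs, order = 4)
    ch <- ch - design %*% qr.coef(qrd, ch)
    wavelet_denoise(ch, levels = 5L)
  }))
  rownames(x) <- rec$channel_labels
  sel <- (discard_s * rec$fs + 1):n_need
  structure(
    list(data = x[, sel, drop = FALSE], fs = rec$fs,
         channel_labels = rec$channel_labels,
         group = rec$group, subject_id = rec$subject_id),
    class = "hbo2_series"
  )
}

#' @export
print.hbo2_series <- function(x, ...) {
  cat(sprintf("<hbo2_series> %s (%s): %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

# --- Daubechies-4 (8-tap) orthonormal wavelet transform, periodized -------

db4_filters <- function() {
  h <- c(0.230377813308855230, 0.714846570552541500,
         0.630880767929590400, -0.027983769416983850,
         -0.187034811718881140, 0.030841381835986965,
         0.032883011666982945, -0.010597401784997278)
  g <- rev(h) * c(1, -1)
  list(h = h, g = g)
}

dwt_step <- function(x) {
  f <- db4_filters()
  n <- length(x)
  half <- n / 2
  a <- numeric(half); d <- numeric(half)
  base <- 2 * (seq_len(half) - 1)
  for (k in seq_along(f$h)) {
    idx <- (base + (k - 1)) %% n + 1
    a <- a + f$h[k] * x[idx]
    d <- d + f$g[k] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d) {
  f <- db4_filters()
  n <- 2 * length(a)
  x <- numeric(n)
  base <- 2 * (seq_along(a) - 1)
  for (k in seq_along(f$h)) {
    idx <- (base + (k - 1)) %% n + 1
    contrib <- f$h[k] * a + f$g[k] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

# Soft-threshold wavelet denoising: decimated db4 pyramid on a
# reflection-padded copy, universal threshold sigma * sqrt(2 log N) with
# sigma estimated from the finest detail level (MAD / 0.6745).
wavelet_denoise <- function(x, levels = 5L) {
  n0 <- length(x)
  block <- 2^levels
  n <- ceiling(n0 / block) * block
  pad <- n - n0
  xp <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x
  details <- vector("list", levels)
  a <- xp
  for (l in seq_len(levels)) {
    st <- dwt_step(a)
    a <- st$a
    details[[l]] <- st$d
  }
  sigma <- stats::mad(details[[1]])
  thr <- sigma * sqrt(2 * log(length(xp)))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  for (l in rev(seq_len(levels))) {
    a <- idwt_step(a, soft(details[[l]]))
  }
  a[seq_len(n0)]
}

#' Sample entropy with embedding delay
#'
#' Templates of length `m` are built with delay `tau`
#' (`x_i = (x[i], x[i + tau], ..., x[i + (m-1) tau])`); `B_i` counts other
#' templates within Chebyshev distance `r` (self-matches excluded), and the
#' entropy is `-ln(U^(m+1) / U^m)` of the mean match frequencies. By default
#' the match-frequency denominators follow the formulation this pipeline
#' reproduces (`C_i^m = B_i / (N - (m+1) tau)` with `U^m` averaged over the
#' `N - m tau` templates); `classical = TRUE` switches to the
#' Richman-Moorman convention for cross-checks. Because `r` defaults to a
#' multiple of the series SD, the value is invariant under affine amplitude
#' scaling.
#'
#' @param x numeric series.
#' @param m embedding dimension.
#' @param r tolerance; default `0.2 * sd(x)`.
#' @param tau embedding delay.
#' @param classical use the Richman-Moorman denominators.
#' @return Sample entropy (non-negative; `Inf` if no (m+1)-matches exist,
#'   0 with a warning for a constant series).
#' @export
sample_entropy <- function(x, m = 2L, r = NULL, tau = 2L, classical = FALSE) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0) {
    warn("constant series: sample entropy defined as 0")
    return(0)
  }
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  stopifnot(m >= 1, tau >= 1, r > 0)
  if (length(x) <= (m + 1) * tau + 1) abort("series too short for SampEn")
  cpp_sampen(x, as.integer(m), r, as.integer(tau), isTRUE(classical))
}

#' ROI functional connectivity of the forehead HbO2 channels
#'
#' The 8 channels form 4 regions of interest (roi1: ch1+ch3, roi2: ch2+ch4,
#' roi3: ch5+ch7, roi4: ch6+ch8); each ROI series is the mean of its two
#' channels. Pearson correlations between the 6 ROI pairs are Fisher-Z
#' transformed (`atanh`) after clamping `|r| <= 1 - 1e-7`, so perfect
#' correlation maps to a finite z of about 8.4.
#'
#' @param h an `hbo2_series`.
#' @return A tibble with columns `pair`, `r`, `z` (6 rows).
#' @export
roi_connectivity <- function(h) {
  stopifnot(inherits(h, "hbo2_series"))
  rois <- fnirs_rois()
  series <- purrr::map(rois, function(chs) {
    colMeans(h$data[chs, , drop = FALSE])
  })
  if (any(purrr::map_dbl(series, stats::sd) == 0)) {
    abort("zero-variance ROI series")
  }
  combos <- utils::combn(names(rois), 2)
  r <- purrr::map_dbl(seq_len(ncol(combos)), function(k) {
    cor(series[[combos[1, k]]], series[[combos[2, k]]])
  })
  r_cl <- clamp(r, -1 + 1e-7, 1 - 1e-7)
  tibble(pair = paste(combos[1, ], combos[2, ], sep = "-"),
         r = r, z = atanh(r_cl))
}

#' Haemodynamic laterality index
#'
#' Side-averaged HbO2 series are anchored at their minima and the laterality
#' index is the normalized difference of the summed right and left activity:
#' `LI = sum((R - min R) - (L - min L)) / sum((R - min R) + (L - min L))`.
#' LI lies in `[-1, 1]`; positive values mean right-dominant activity, and
#' the sign flips when the side map is swapped.
#'
#' @param h an `hbo2_series`.
#' @param side_map optional named vector mapping ch1..ch8 to sides; see
#'   [fnirs_side_map()].
#' @return The laterality index (0 with a warning if both sides are
#'   constant).
#' @export
laterality_index <- function(h, side_map = NULL) {
  stopifnot(inherits(h, "hbo2_series"))
  side <- fnirs_side_map(side_map)
  right <- colMeans(h$data[names(side)[side == "right"], , drop = FALSE])
  left <- colMeans(h$data[names(side)[side == "left"], , drop = FALSE])
  r <- right - min(right)
  l <- left - min(left)
  denom <- sum(r + l)
  if (denom == 0) {
    warn("both sides constant: laterality index defined as 0")
    return(0)
  }
  sum(r - l) / denom
}
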