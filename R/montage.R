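#' Electrode montage and frequency-band constants
#'
#' The analysis works on a 28-electrode subset of the standard 10-20 system
#' recorded at 500 Hz; T7 and T8 are discarded before analysis because of
#' muscle contamination, leaving 26 channels. Frontal fNIRS channels are
#' labelled ch1..ch8, with ch1-ch4 on the right forehead and ch5-ch8 on the
#' left by default (the side map is configurable wherever it matters).
#'
#' @name montage
NULL

#' Full 28-channel EEG montage labels
#' @return Character vector of 28 channel labels in recording order.
#' @export
eeg_montage <- function() {
  c("Fz", "F3", "F4", "F7", "F8", "FC1", "FC2", "FC5", "FC6",
    "Cz", "C3", "C4", "T7", "T8", "CP1", "CP2", "CP5", "CP6",
    "Pz", "P3", "P4", "P7", "P8", "PO3", "PO4", "Oz", "O1", "O2")
}

#' The 26 channels retained for analysis (T7/T8 removed)
#' @export
#' @rdname eeg_montage
eeg_analysis_channels <- function() {
  setdiff(eeg_montage(), c("T7", "T8"))
}

#' The 11 right-left symmetric electrode pairs used for asymmetry scoring
#'
#' Each pair is named "right-left"; the asymmetry score of a pair is
#' (R - L) / (R + L) of the two relative powers, so a positive score means
#' right-dominant band power.
#'
#' @return A tibble with columns `pair`, `right`, `left`.
#' @export
symmetric_pairs <- function() {
  right <- c("F4", "F8", "FC2", "FC6", "C4", "CP2", "CP6", "P4", "P8", "PO4", "O2")
  left  <- c("F3", "F7", "FC1", "FC5", "C3", "CP1", "CP5", "P3", "P7", "PO3", "O1")
  tibble(pair = paste(right, left, sep = "-"), right = right, left = left)
}

#' EEG frequency bands
#' @return A tibble with columns `band`, `f1`, `f2` (Hz).
#' @export
eeg_bands <- function() {
  tibble(band = c("delta", "theta", "alpha"),
         f1 = c(0.5, 4, 8),
         f2 = c(4, 8, 13))
}

band_edges <- function(band) {
  b <- eeg_bands()
  i <- match(band, b$band)
  if (is.na(i)) abort(paste0("unknown band '", band, "'"))
  c(b$f1[i], b$f2[i])
}

#' Approximate 2-D scalp coordinates of the montage
#'
#' Schematic top-view coordinates of the 10-20 positions (x positive toward
#' the right ear, y positive anterior, unit head radius), used by the
#' synthetic generator to couple spatially neighbouring channels.
#'
#' @return A tibble with columns `channel`, `x`, `y`.
#' @export
montage_coords <- function() {
  tribble(
    ~channel, ~x, ~y,
    "Fz", 0.00, 0.50, "F3", -0.35, 0.50, "F4", 0.35, 0.50,
    "F7", -0.70, 0.55, "F8", 0.70, 0.55,
    "FC1", -0.20, 0.25, "FC2", 0.20, 0.25,
    "FC5", -0.60, 0.30, "FC6", 0.60, 0.30,
    "Cz", 0.00, 0.00, "C3", -0.40, 0.00, "C4", 0.40, 0.00,
    "T7", -0.80, 0.00, "T8", 0.80, 0.00,
    "CP1", -0.20, -0.25, "CP2", 0.20, -0.25,
    "CP5", -0.60, -0.30, "CP6", 0.60, -0.30,
    "Pz", 0.00, -0.50, "P3", -0.35, -0.50, "P4", 0.35, -0.50,
    "P7", -0.70, -0.55, "P8", 0.70, -0.55,
    "PO3", -0.25, -0.75, "PO4", 0.25, -0.75,
    "Oz", 0.00, -0.95, "O1", -0.30, -0.90, "O2", 0.30, -0.90
  )
}

# Row-normalized Gaussian spatial loading matrix W (channels x channels):
# W[c, k] ~ exp(-d(c, k)^2 / (2 l^2)), rows scaled to unit sum of squares,
# so rho^2 * (W W^T) is the inter-channel correlation of the shared phase
# jitter and decays smoothly with scalp distance.
spatial_loadings <- function(channels, length_scale = 0.35) {
  coords <- montage_coords()
  idx <- match(channels, coords$channel)
  if (anyNA(idx)) abort("channel(s) outside the standard montage")
  xy <- as.matrix(coords[idx, c("x", "y")])
  d2 <- outer(xy[, 1], xy[, 1], "-")^2 + outer(xy[, 2], xy[, 2], "-")^2
  w <- exp(-d2 / (2 * length_scale^2))
  w / sqrt(rowSums(w^2))
}

#' fNIRS channel labels and default hemisphere map
#' @param side_map named character vector mapping each of ch1..ch8 to
#'   "right" or "left". The default puts ch1-ch4 on the right forehead.
#' @return `fnirs_channels()`: the 8 labels; `fnirs_side_map()`: a named
#'   vector of sides.
#' @export
fnirs_channels <- function() paste0("ch", 1:8)

#' @rdname fnirs_channels
#' @export
fnirs_side_map <- function(side_map = NULL) {
  if (is.null(side_map)) {
    side_map <- setNames(rep(c("right", "left"), each = 4L), fnirs_channels())
  }
  if (!setequal(names(side_map), fnirs_channels()) ||
      !all(side_map %in% c("right", "left"))) {
    abort("side_map must assign each of ch1..ch8 to 'right' or 'left'")
  }
  side_map[fnirs_channels()]
}

# ROI grouping of the 8 forehead channels.
fnirs_rois <- function() {
  list(roi1 = c("ch1", "ch3"), roi2 = c("ch2", "ch4"),
       roi3 = c("ch5", "ch7"), roi4 = c("ch6", "ch8"))
}
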