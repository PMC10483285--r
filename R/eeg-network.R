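#' Phase-locking value matrix of a band-limited epoch set
#'
#' For each epoch, instantaneous phases are taken from the analytic signal
#' (frequency-domain Hilbert transform) of every channel, and the PLV of a
#' channel pair is the modulus of the time average of `exp(i * (psi_x -
#' psi_y))` over the whole epoch. The per-epoch matrices are then averaged
#' across epochs. PLV is 1 for perfectly phase-locked pairs (including any
#' constant lag) and near 0 for independent signals.
#'
#' @param be a `band_epochs` object from [extract_band()].
#' @return A `plv_matrix`: list with `values` (symmetric channels x channels
#'   matrix, unit diagonal), `band`, `channel_labels`.
#' @export
plv_matrix <- function(be) {
  stopifnot(inherits(be, "epoch_set"))
  if (!length(be$epochs)) abort("no epochs to compute PLV from")
  mats <- purrr::map(be$epochs, function(e) {
    if (!all(is.finite(e))) abort("non-finite samples in epoch")
    n <- ncol(e)
    if (n < 2) abort("epochs must have at least 2 samples")
    # analytic signal of all channels at once, then unit phasors
    X <- stats::mvfft(t(e))
    h <- numeric(n)
    if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
    else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
    Z <- stats::mvfft(X * h, inverse = TRUE)        # unscaled; phase only
    P <- cpp_unit_phasor(Z)                          # n x nch
    Mod(crossprod(Conj(P), P)) / n
  })
  v <- Reduce(`+`, mats) / length(mats)
  v <- clamp((v + t(v)) / 2, 0, 1)
  diag(v) <- 1
  dimnames(v) <- list(be$channel_labels, be$channel_labels)
  structure(list(values = v, band = be$band %||% NA_character_,
                 channel_labels = be$channel_labels),
            class = "plv_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Band-wise PLV matrices via spectral zero-phase filtering
#'
#' Equivalent fast path for [extract_band()] followed by [plv_matrix()]:
#' each epoch is transformed once, the squared-magnitude response of the
#' band's Butterworth filter (identical to the forward-backward time-domain
#' pass, up to epoch-edge handling) is applied together with the one-sided
#' analytic-signal weighting, and a single inverse transform yields the
#' band-limited analytic signal of every channel. Interior samples match
#' the time-domain path; only filter edge transients differ, which perturbs
#' epoch-averaged PLV by well under 0.01.
#'
#' @param es an `epoch_set` (broadband).
#' @param bands band names.
#' @return Named list of `plv_matrix` objects, one per band.
#' @export
plv_by_band <- function(es, bands = eeg_bands()$band) {
  stopifnot(inherits(es, "epoch_set"))
  n <- ncol(es$epochs[[1]])
  nch <- length(es$channel_labels)
  omega <- 2 * pi * (seq_len(n) - 1) / n
  z1 <- exp(-1i * omega)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  masks <- purrr::map(bands, function(b) {
    edges <- band_edges(b)
    bf <- signal::butter(2, edges / (es$fs / 2), type = "pass")
    resp <- polyval_z(bf$b, z1) / polyval_z(bf$a, z1)
    Mod(resp)^2 * h                       # filtfilt magnitude + analytic gain
  })
  names(masks) <- bands
  acc <- purrr::map(bands, function(b) matrix(0, nch, nch))
  names(acc) <- bands
  for (e in es$epochs) {
    X <- stats::mvfft(t(e))
    for (b in bands) {
      Z <- stats::mvfft(X * masks[[b]], inverse = TRUE)
      P <- cpp_unit_phasor(Z)
      acc[[b]] <- acc[[b]] + Mod(crossprod(Conj(P), P)) / n
    }
  }
  purrr::map(setNames(bands, bands), function(b) {
    v <- acc[[b]] / length(es$epochs)
    v <- clamp((v + t(v)) / 2, 0, 1)
    diag(v) <- 1
    dimnames(v) <- list(es$channel_labels, es$channel_labels)
    structure(list(values = v, band = b, channel_labels = es$channel_labels),
              class = "plv_matrix")
  })
}

# Horner evaluation of a polynomial (coefficients in decreasing power of
# z^-1, i.e. filter-coefficient order) at complex points.
polyval_z <- function(coefs, z) {
  out <- rep(coefs[1] + 0i, length(z))
  for (k in seq_along(coefs)[-1]) out <- out * z + coefs[k]
  out
}

#' @export
print.plv_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<plv_matrix> band %s: %d channels, mean off-diagonal PLV %.3f\n",
              x$band, nrow(x$values), mean(off)))
  invisible(x)
}

# Upper-triangle pairs of an n x n matrix ordered by descending value with
# deterministic (row, column) lexicographic tie-break.
ranked_pairs <- function(values) {
  n <- nrow(values)
  idx <- which(upper.tri(values), arr.ind = TRUE)
  v <- values[idx]
  ord <- order(-v, idx[, 1], idx[, 2], method = "radix")
  list(i = idx[ord, 1], j = idx[ord, 2], n_pairs = nrow(idx))
}

# Proportional edge target: round-half-up of (1 - threshold) * n_pairs.
# The epsilon guards against binary representation of the threshold pushing
# an exact .5 target just below the rounding boundary (0.7 * 325 = 227.5).
proportional_edge_count <- function(threshold, n_pairs) {
  as.integer(floor((1 - threshold) * n_pairs + 0.5 + 1e-9))
}

#' Binarize a PLV matrix by proportional thresholding
#'
#' Keeps the strongest `(1 - threshold)` fraction of the off-diagonal
#' upper-triangle connections as edges (so threshold 0.3 keeps the top 70%),
#' with round-half-up of the edge target and stable (row, column) tie-breaks.
#'
#' @param plv a `plv_matrix` or a symmetric numeric matrix.
#' @param threshold proportional threshold in `[0, 1)`.
#' @return A `binary_network`: list with `adjacency` (0/1 symmetric matrix,
#'   zero diagonal), `threshold`, `n_edges`.
#' @export
binarize_proportional <- function(plv, threshold) {
  values <- if (inherits(plv, "plv_matrix")) plv$values else as.matrix(plv)
  if (!isSymmetric(unname(values), tol = 1e-10)) {
    abort("connection matrix must be symmetric")
  }
  if (threshold < 0 || threshold >= 1) abort("threshold must be in [0, 1)")
  rp <- ranked_pairs(values)
  k <- proportional_edge_count(threshold, rp$n_pairs)
  adj <- matrix(0L, nrow(values), ncol(values), dimnames = dimnames(values))
  if (k > 0) {
    sel <- seq_len(k)
    adj[cbind(rp$i[sel], rp$j[sel])] <- 1L
    adj[cbind(rp$j[sel], rp$i[sel])] <- 1L
  }
  structure(list(adjacency = adj, threshold = threshold, n_edges = k),
            class = "binary_network")
}

# Deterministic vertex permutations for the Louvain restarts, generated from
# a fixed internal seed without disturbing the caller's RNG stream.
louvain_perms <- function(n, restarts = 10L, seed = 1299709L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  t(vapply(seq_len(restarts), function(r) sample.int(n) - 1L, integer(n)))
}

#' Six binary-network properties
#'
#' Computes, with the standard binary undirected definitions: clustering
#' coefficient `C` (mean nodal fraction of closed neighbour pairs, 0 for
#' degree < 2), characteristic path length `L` (mean finite shortest-path
#' length over connected pairs; `NA` for an empty graph), global efficiency
#' `GE` (mean inverse distance, disconnected pairs contributing 0), local
#' efficiency `LE` (mean over nodes of the efficiency of each node's
#' neighbour subgraph), transitivity `T` (3 x triangles / connected triples),
#' and modularity `M` (exact best-partition Newman Q by enumeration for
#' graphs of at most 8 nodes; the best Q over `restarts` Louvain runs with
#' seeded vertex orders beyond that).
#'
#' @param net a `binary_network` from [binarize_proportional()], or a 0/1
#'   symmetric adjacency matrix.
#' @param restarts Louvain restarts used for `M`.
#' @return A one-row tibble with columns `C`, `L`, `GE`, `LE`, `T`, `M`.
#' @export
network_metrics <- function(net, restarts = 10L) {
  adj <- if (inherits(net, "binary_network")) net$adjacency else as.matrix(net)
  storage.mode(adj) <- "integer"
  perms <- louvain_perms(nrow(adj), restarts)
  as_tibble(as.list(cpp_network_metrics(adj, perms)))
}

#' Metric curves over the proportional-threshold sweep
#'
#' Evaluates all six network properties at every threshold of the grid
#' (0.20, 0.21, ..., 0.50 by default, 31 points).
#'
#' @param plv a `plv_matrix` or symmetric numeric matrix.
#' @param thresholds threshold grid.
#' @param restarts Louvain restarts for `M`.
#' @return A tibble with columns `threshold`, `metric`, `value` (class
#'   `metric_curves`). Summarize with [curve_auc()]; plot with `autoplot()`.
#' @export
metric_curves <- function(plv, thresholds = seq(0.2, 0.5, by = 0.01),
                          restarts = 10L) {
  values <- if (inherits(plv, "plv_matrix")) plv$values else as.matrix(plv)
  if (!isSymmetric(unname(values), tol = 1e-10)) {
    abort("connection matrix must be symmetric")
  }
  rp <- ranked_pairs(values)
  ecounts <- vapply(thresholds, proportional_edge_count,
                    integer(1), n_pairs = rp$n_pairs)
  perms <- louvain_perms(nrow(values), restarts)
  m <- cpp_metric_sweep(nrow(values), rp$i - 1L, rp$j - 1L, ecounts, perms)
  out <- tibble(threshold = rep(thresholds, times = 6L),
                metric = rep(colnames(m), each = length(thresholds)),
                value = as.vector(m))
  class(out) <- c("metric_curves", class(out))
  out
}

#' Area under each metric's threshold curve
#'
#' Composite trapezoidal integration of each metric over the threshold axis;
#' the scalar summary used as a classification feature.
#'
#' @param curves a `metric_curves` tibble.
#' @return A tibble with columns `metric`, `auc`.
#' @export
curve_auc <- function(curves) {
  curves %>%
    group_by(.data$metric) %>%
    summarise(auc = trapezoid(.data$threshold, .data$value),
              .groups = "drop")
}

trapezoid <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
autoplot.metric_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "proportional threshold", y = "metric value")
}
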