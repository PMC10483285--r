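# Independent brute-force oracles, deliberately written with naive
# algorithms (Floyd-Warshall, exhaustive triangle and partition
# enumeration, double-loop template matching) so they share no code with
# the package implementations they check.

oracle_apsp <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_metrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  tri <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) >= 2) {
      cmb <- combn(nb, 2)
      tri[i] <- sum(adj[cbind(cmb[1, ], cmb[2, ])])
    }
  }
  C <- mean(ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0))
  Tn <- sum(tri)
  Td <- sum(deg * (deg - 1) / 2)
  Tr <- if (Td > 0) Tn / Td else 0
  d <- oracle_apsp(adj)
  ut <- upper.tri(d)
  finite <- is.finite(d[ut]) & d[ut] > 0
  L <- if (any(finite)) mean(d[ut][finite]) else NA_real_
  GE <- mean(ifelse(is.finite(d[ut]) & d[ut] > 0, 1 / d[ut], 0))
  LE <- mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    ds <- oracle_apsp(sub)
    u <- upper.tri(ds)
    mean(ifelse(is.finite(ds[u]) & ds[u] > 0, 1 / ds[u], 0))
  }, numeric(1)))
  c(C = C, L = L, GE = GE, LE = LE, T = Tr)
}

# All set partitions of n elements as membership vectors (restricted
# growth strings); feasible up to n = 8 (Bell(8) = 4140).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxc) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (c in seq_len(maxc + 1)) {
      rec(c(prefix, c), max(maxc, c))
    }
  }
  rec(integer(0), 0L)
  out
}

oracle_newman_q <- function(adj, membership) {
  m2 <- sum(adj)
  if (m2 == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(adj[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
  }
  q
}

oracle_best_modularity <- function(adj) {
  parts <- all_partitions(nrow(adj))
  max(vapply(parts, function(p) oracle_newman_q(adj, p), numeric(1)))
}

random_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  ut <- which(upper.tri(adj))
  on <- ut[runif(length(ut)) < p]
  adj[on] <- 1L
  adj + t(adj)
}

# Double-loop sample entropy following the printed template-counting rule.
oracle_sampen <- function(x, m, r, tau) {
  N <- length(x)
  count_matches <- function(mm) {
    n_t <- N - mm * tau
    B <- numeric(n_t)
    for (i in seq_len(n_t)) {
      ti <- x[i + (0:(mm - 1)) * tau]
      for (j in seq_len(n_t)) {
        if (j == i) next
        tj <- x[j + (0:(mm - 1)) * tau]
        if (max(abs(ti - tj)) <= r) B[i] <- B[i] + 1
      }
    }
    mean(B / (N - (mm + 1) * tau))
  }
  -log(count_matches(m + 1) / count_matches(m))
}
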