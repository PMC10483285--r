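#' Two-group comparison of one feature
#'
#' Shapiro-Wilk normality is checked in each group at alpha = 0.05; if both
#' groups look normal an independent two-sided t-test (pooled variance) is
#' used, otherwise a Mann-Whitney U test. Cohen's d (pooled SD,
#' `nA + nB - 2` denominator) is always reported as `(mean(B) - mean(A)) /
#' SD_pooled`.
#'
#' @param group_a,group_b numeric vectors (each n >= 3).
#' @param alpha normality-gate level.
#' @return One-row tibble: `test_used`, `statistic`, `p_raw`, `cohens_d`.
#' @export
compare_feature <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    abort("each group needs at least 3 observations")
  }
  normal <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    shapiro.test(x)$p.value > alpha
  }
  use_t <- normal(group_a) && normal(group_b)
  if (use_t) {
    tst <- t.test(group_a, group_b, var.equal = TRUE)
    res <- tibble(test_used = "t", statistic = unname(tst$statistic),
                  p_raw = tst$p.value)
  } else {
    tst <- suppressWarnings(wilcox.test(group_a, group_b))
    res <- tibble(test_used = "mann-whitney",
                  statistic = unname(tst$statistic), p_raw = tst$p.value)
  }
  na <- length(group_a); nb <- length(group_b)
  pooled <- sqrt(((na - 1) * var(group_a) + (nb - 1) * var(group_b)) /
                   (na + nb - 2))
  d <- if (pooled == 0) NA_real_ else (mean(group_b) - mean(group_a)) / pooled
  res$cohens_d <- d
  res
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values, monotone, capped at 1, returned in the input
#' order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  if (!length(p_values)) abort("empty p-value list")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Without continuity correction (df = 1) -- the convention that reproduces
#' standard demographic sex-ratio comparisons.
#'
#' @param table 2x2 matrix of counts.
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) abort("zero marginal in 2x2 table")
  tst <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(statistic = unname(tst$statistic), df = unname(tst$parameter),
         p = tst$p.value)
}

#' Group comparison of metric curves and their AUCs
#'
#' Compares the two groups at every threshold of every metric curve
#' (FDR-corrected within each band x metric family of 31 thresholds) and
#' compares the per-metric AUC summaries (FDR-corrected within each band's
#' family of 6 metrics). Per-group means and standard errors of the mean
#' are included for curve plotting.
#'
#' @param curves tibble of per-subject curves with columns `subject_id`,
#'   `group`, `band`, `metric`, `threshold`, `value`.
#' @return List of two tibbles: `thresholds` (per band/metric/threshold
#'   comparison) and `auc` (per band/metric AUC comparison).
#' @export
curve_comparison <- function(curves) {
  need <- c("subject_id", "group", "band", "metric", "threshold", "value")
  if (!all(need %in% names(curves))) {
    abort(paste0("curves must have columns ", paste(need, collapse = ", ")))
  }
  grids <- curves %>%
    group_by(.data$band, .data$metric, .data$group) %>%
    summarise(k = dplyr::n_distinct(.data$threshold), .groups = "drop")
  if (length(unique(grids$k)) != 1) abort("threshold grids differ across groups")

  by_thr <- curves %>%
    group_by(.data$band, .data$metric, .data$threshold) %>%
    summarise(
      compare_feature(.data$value[.data$group == "control"],
                      .data$value[.data$group == "patient"]),
      mean_control = mean(.data$value[.data$group == "control"]),
      sem_control = stats::sd(.data$value[.data$group == "control"]) /
        sqrt(sum(.data$group == "control")),
      mean_patient = mean(.data$value[.data$group == "patient"]),
      sem_patient = stats::sd(.data$value[.data$group == "patient"]) /
        sqrt(sum(.data$group == "patient")),
      .groups = "drop"
    ) %>%
    group_by(.data$band, .data$metric) %>%
    mutate(p_fdr = fdr_correct(.data$p_raw)) %>%
    ungroup()

  aucs <- curves %>%
    group_by(.data$subject_id, .data$group, .data$band, .data$metric) %>%
    summarise(auc = trapezoid(.data$threshold, .data$value), .groups = "drop")
  by_auc <- aucs %>%
    group_by(.data$band, .data$metric) %>%
    summarise(
      compare_feature(.data$auc[.data$group == "control"],
                      .data$auc[.data$group == "patient"]),
      .groups = "drop"
    ) %>%
    group_by(.data$band) %>%
    mutate(p_fdr = fdr_correct(.data$p_raw)) %>%
    ungroup()

  list(thresholds = by_thr, auc = by_auc)
}

#' Compare every feature column between groups with FDR correction
#'
#' @param features feature tibble with `subject_id`, `group` and numeric
#'   feature columns (as from [build_feature_matrix()]).
#' @return Tidy tibble: `feature`, `test_used`, `statistic`, `p_raw`,
#'   `p_fdr`, `cohens_d`, ordered by `p_raw`.
#' @export
group_feature_stats <- function(features) {
  cols <- feature_columns(features)
  res <- purrr::map_dfr(cols, function(f) {
    compare_feature(features[[f]][features$group == "control"],
                    features[[f]][features$group == "patient"]) %>%
      mutate(feature = f, .before = 1)
  })
  res$p_fdr <- fdr_correct(res$p_raw)
  arrange(res, .data$p_raw)
}
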