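#' Min-max normalization fitted on a subject subset
#'
#' Each feature is mapped through `(x - min) / (max - min)` with the min and
#' max computed on `fit_rows` only and the mapping applied to all rows, so a
#' held-out subject never influences the scaling. A constant feature on the
#' fit rows maps to 0 everywhere.
#'
#' @param features feature tibble (`subject_id`, `group`, numeric columns).
#' @param fit_rows integer or logical row subset the statistics are fitted
#'   on; default all rows.
#' @return The feature tibble with transformed columns.
#' @export
minmax_normalize <- function(features, fit_rows = NULL) {
  cols <- feature_columns(features)
  if (!length(cols) || !nrow(features)) abort("empty feature matrix")
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(features))
  if (is.logical(fit_rows)) fit_rows <- which(fit_rows)
  if (!length(fit_rows)) abort("fit_rows must be non-empty")
  for (f in cols) {
    x <- features[[f]]
    lo <- min(x[fit_rows]); hi <- max(x[fit_rows])
    features[[f]] <- if (hi > lo) (x - lo) / (hi - lo) else rep(0, length(x))
  }
  features
}

#' LASSO feature selection with 10-fold cross-validation
#'
#' L1-penalized least squares of the 0/1 group label on the features
#' (fitted with [glmnet::glmnet()]); the penalty is chosen on a 50-point
#' log-spaced grid running four decades down from the smallest lambda that
#' zeroes every coefficient, by minimizing mean 10-fold cross-validated
#' squared error. Features with non-zero coefficients at the chosen lambda
#' are returned ordered by decreasing `|coefficient|`. If the chosen lambda
#' selects nothing, the largest grid lambda selecting at least one feature
#' is used instead and the result is flagged (`fallback = TRUE`).
#'
#' @param features feature tibble with a `group` column.
#' @param lambda_grid optional penalty grid (positive, decreasing).
#' @param folds CV folds.
#' @param seed seed for the fold assignment.
#' @param response optional continuous response overriding the default 0/1
#'   group encoding (useful for selection against external scores).
#' @return A `lasso_selection`: list with `selected` (tibble `feature`,
#'   `coefficient`), `lambda_chosen`, `fallback`, `cv` (tibble `lambda`,
#'   `cv_mse`). `tidy()` returns the selected features.
#' @export
lasso_select <- function(features, lambda_grid = NULL, folds = 10, seed = 1L,
                         response = NULL) {
  cols <- feature_columns(features)
  x <- as.matrix(features[cols])
  y <- if (is.null(response)) as.numeric(features$group == "patient")
       else as.numeric(response)
  n <- nrow(x)
  if (n < folds) abort("need at least as many subjects as folds")
  if (is.null(lambda_grid)) {
    lambda_max <- max(abs(crossprod(x, y - mean(y)))) / n
    if (lambda_max <= 0) lambda_max <- 1e-3
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                           length.out = 50))
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  # small folds legitimately trigger glmnet's ungrouped-CV notice
  cvfit <- withCallingHandlers(
    glmnet::cv.glmnet(x, y, family = "gaussian", lambda = lambda_grid,
                      foldid = foldid, standardize = FALSE),
    warning = function(w) {
      if (grepl("grouped=FALSE", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  lambda_chosen <- cvfit$lambda.min
  fit <- cvfit$glmnet.fit
  pick <- function(lam) {
    beta <- as.numeric(coef(fit, s = lam, exact = FALSE))[-1]
    tibble(feature = cols, coefficient = beta) %>%
      filter(.data$coefficient != 0) %>%
      arrange(desc(abs(.data$coefficient)))
  }
  selected <- pick(lambda_chosen)
  fallback <- FALSE
  if (!nrow(selected)) {
    for (lam in sort(fit$lambda, decreasing = TRUE)) {
      selected <- pick(lam)
      if (nrow(selected)) { lambda_chosen <- lam; fallback <- TRUE; break }
    }
  }
  structure(
    list(selected = selected, lambda_chosen = lambda_chosen,
         fallback = fallback,
         cv = tibble(lambda = cvfit$lambda, cv_mse = cvfit$cvm)),
    class = "lasso_selection"
  )
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("<lasso_selection> %d features at lambda = %.4g%s\n",
              nrow(x$selected), x$lambda_chosen,
              if (x$fallback) " (fallback)" else ""))
  invisible(x)
}

#' @export
tidy.lasso_selection <- function(x, ...) x$selected

# Linear SVM decision values signed so that positive means "patient".
svm_decision <- function(model, newdata) {
  pr <- predict(model, newdata, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  lab <- colnames(attr(pr, "decision.values"))[1]
  if (startsWith(lab, "control")) dv <- -dv
  list(class = as.character(pr), decision = dv)
}

fit_svm <- function(x, y, cost) {
  e1071::svm(x, factor(y, levels = c("control", "patient")),
             kernel = "linear", cost = cost, scale = FALSE)
}

# k-fold CV accuracy of a linear SVM on the given feature subset.
inner_cv_accuracy <- function(x, y, cost, folds, foldid) {
  correct <- 0L
  for (k in seq_len(folds)) {
    tr <- foldid != k
    if (length(unique(y[tr])) < 2) next
    m <- fit_svm(x[tr, , drop = FALSE], y[tr], cost)
    pred <- predict(m, x[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == y[!tr])
  }
  correct / length(y)
}

# Backward elimination over the |coefficient|-ranked feature list: starting
# from the top `max_start` features, the lowest-|coefficient| feature is
# dropped one at a time; each subset is scored by inner CV accuracy and the
# best is kept, preferring the smaller subset on ties. Elimination stops at
# the first strict accuracy decrease (dropping further from an already
# hurting subset is not explored).
backward_eliminate <- function(x, y, ranked, cost, folds, seed,
                               max_start = 15L) {
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = length(y)))
  ranked <- ranked[seq_len(min(length(ranked), max_start))]
  best <- ranked
  best_acc <- -1
  for (k in rev(seq_along(ranked))) {
    subset <- ranked[seq_len(k)]
    acc <- inner_cv_accuracy(x[, subset, drop = FALSE], y, cost, folds, foldid)
    if (acc >= best_acc) {     # ties prefer the smaller subset (later k)
      best_acc <- acc
      best <- subset
    } else {
      break
    }
  }
  best
}

#' Leave-one-out cross-validated linear SVM classification
#'
#' For every held-out subject the remaining subjects form the training fold;
#' min-max normalization is fitted on the training fold, LASSO selection
#' ([lasso_select()]) is run on it, backward feature elimination (starting
#' from the 15 largest-`|coefficient|` features, dropping the smallest one
#' at a time, keeping the subset with the best inner 10-fold CV accuracy,
#' smaller subsets preferred on ties, stopping at the first strict accuracy
#' decrease) prunes the selection, a linear SVM (C = 1 by default) is
#' fitted, and the held-out subject is predicted. Predictions are aggregated into a
#' confusion matrix, accuracy/precision/recall (positive class = patient)
#' and an ROC curve from the pooled signed distances to the hyperplane.
#'
#' With `paper_mode = TRUE` the normalization and feature selection are
#' instead performed once on the full data set before the LOOCV loop -- the
#' literal order of operations some clinical reports describe, which leaks
#' test information into selection and is provided for comparison only.
#'
#' @param features feature tibble (`subject_id`, `group`, numeric columns).
#' @param svm_cost linear SVM cost parameter C.
#' @param backward run backward feature elimination.
#' @param paper_mode global (leaky) normalization + selection.
#' @param inner_folds folds of the inner CVs (LASSO and elimination).
#' @param seed RNG seed; the full report is reproducible given the seed.
#' @return A `classifier_report`; see [tidy.classifier_report()] and
#'   [glance.classifier_report()].
#' @export
loocv_classify <- function(features, svm_cost = 1, backward = TRUE,
                           paper_mode = FALSE, inner_folds = 10, seed = 1L) {
  n <- nrow(features)
  y <- features$group
  if (sum(y == "patient") < 2 || sum(y == "control") < 2) {
    abort("need at least 2 subjects per class")
  }
  global_ranked <- NULL
  inner_folds <- min(inner_folds, n - 1L)
  if (paper_mode) {
    norm_all <- minmax_normalize(features)
    sel <- lasso_select(norm_all, folds = inner_folds, seed = seed)
    global_ranked <- sel$selected$feature
    if (backward && length(global_ranked) > 1) {
      x_all <- as.matrix(norm_all[feature_columns(norm_all)])
      global_ranked <- backward_eliminate(x_all, y, global_ranked, svm_cost,
                                          inner_folds, seed)
    }
    if (!length(global_ranked)) abort("empty global selection")
  }

  pred_class <- character(n)
  decision <- numeric(n)
  n_selected <- integer(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    if (length(unique(y[train])) < 2) {
      abort("degenerate training fold: one class only")
    }
    if (paper_mode) {
      norm <- minmax_normalize(features)      # global (leaky) scaling
      ranked <- global_ranked
    } else {
      folds_i <- min(inner_folds, length(train))
      norm <- minmax_normalize(features, fit_rows = train)
      sel <- lasso_select(norm[train, ], folds = folds_i,
                          seed = seed + i)
      ranked <- sel$selected$feature
      x_tr <- as.matrix(norm[train, ][feature_columns(norm)])
      if (backward && length(ranked) > 1) {
        ranked <- backward_eliminate(x_tr, y[train], ranked, svm_cost,
                                     folds_i, seed + i)
      }
    }
    if (!length(ranked)) ranked <- feature_columns(norm)
    x <- as.matrix(norm[ranked])
    m <- fit_svm(x[train, , drop = FALSE], y[train], svm_cost)
    out <- svm_decision(m, x[i, , drop = FALSE])
    pred_class[i] <- out$class
    decision[i] <- out$decision
    n_selected[i] <- length(ranked)
  }

  predictions <- tibble(subject_id = features$subject_id, truth = y,
                        predicted = pred_class, decision = decision,
                        n_features = n_selected)
  classifier_report(predictions)
}

# Build a classifier_report from a per-subject prediction table.
classifier_report <- function(predictions) {
  truth <- factor(predictions$truth, levels = c("control", "patient"))
  pred <- factor(predictions$predicted, levels = c("control", "patient"))
  confusion <- table(truth = truth, predicted = pred)
  tp <- confusion["patient", "patient"]
  fp <- confusion["control", "patient"]
  fn <- confusion["patient", "control"]
  accuracy <- sum(diag(confusion)) / sum(confusion)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  roc <- pROC::roc(response = truth, predictor = predictions$decision,
                   levels = c("control", "patient"), direction = "<",
                   quiet = TRUE)
  structure(
    list(predictions = predictions, confusion = confusion,
         accuracy = accuracy, precision = precision, recall = recall,
         roc_points = tibble(fpr = rev(1 - roc$specificities),
                             tpr = rev(roc$sensitivities)),
         roc_auc = as.numeric(pROC::auc(roc))),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> accuracy %.1f%%, precision %.1f%%, recall %.1f%%, ROC AUC %.2f\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$recall, x$roc_auc))
  print(x$confusion)
  invisible(x)
}

#' Per-subject LOOCV predictions
#' @param x a `classifier_report`.
#' @param ... unused.
#' @export
tidy.classifier_report <- function(x, ...) x$predictions

#' One-row performance summary
#' @param x a `classifier_report`.
#' @param ... unused.
#' @export
glance.classifier_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, precision = x$precision, recall = x$recall,
         roc_auc = x$roc_auc, n = nrow(x$predictions))
}

#' @export
autoplot.classifier_report <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("LOOCV ROC (AUC = %.2f)", object$roc_auc))
}

#' Compare EEG-only and hybrid classifiers
#'
#' Runs [loocv_classify()] twice -- once on the EEG feature columns only and
#' once on the full hybrid matrix -- and reports both with their accuracy
#' difference.
#'
#' @inheritParams loocv_classify
#' @return List with `eeg`, `hybrid` (both `classifier_report`) and
#'   `accuracy_difference` (hybrid minus EEG-only).
#' @export
compare_modalities <- function(features, svm_cost = 1, backward = TRUE,
                               paper_mode = FALSE, inner_folds = 10,
                               seed = 1L) {
  eeg_cols <- feature_columns(features, "eeg")
  fnirs_cols <- feature_columns(features, "fnirs")
  if (!length(fnirs_cols)) abort("no fNIRS columns: hybrid comparison refused")
  eeg_fm <- features[c("subject_id", "group", eeg_cols)]
  eeg_rep <- loocv_classify(eeg_fm, svm_cost, backward, paper_mode,
                            inner_folds, seed)
  hyb_rep <- loocv_classify(features, svm_cost, backward, paper_mode,
                            inner_folds, seed)
  list(eeg = eeg_rep, hybrid = hyb_rep,
       accuracy_difference = hyb_rep$accuracy - eeg_rep$accuracy)
}
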