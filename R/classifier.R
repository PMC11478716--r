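# Apnea-severity classification: AHI-quantile dichotomization, SVM decision
# scores, empirical ROC/AUC with DeLong confidence intervals, and
# leave-one-out cross-validation.

#' Dichotomize AHI at a cohort quantile
#'
#' Labels are 1 iff AHI strictly exceeds the cohort quantile cut-off;
#' ties at the cut-off go to the negative class.
#'
#' @param ahi_values Numeric AHI vector (events/h).
#' @param quantile Cut-off quantile in (0, 1); default 0.5 (cohort median).
#' @return List with `labels` (integer 0/1) and `cutoff` (events/h).
#' @export
#' @examples
#' dichotomize(1:10)$labels  # five positives above the median 5.5
dichotomize <- function(ahi_values, quantile = 0.5) {
  stopifnot(is.numeric(ahi_values), length(ahi_values) >= 2L)
  if (quantile <= 0 || quantile >= 1)
    stop_invalid("'quantile' must lie strictly in (0, 1)")
  if (diff(range(ahi_values)) == 0)
    stop_invalid("degenerate AHI distribution: all values equal")
  cutoff <- stats::quantile(ahi_values, quantile, names = FALSE)
  list(labels = as.integer(ahi_values > cutoff), cutoff = cutoff)
}

feature_columns <- function(table, feature_set = c("combined", "ecg", "bf")) {
  feature_set <- match.arg(feature_set)
  hrv <- grep("^hrv_", names(table), value = TRUE)
  brv <- grep("^brv_", names(table), value = TRUE)
  cols <- switch(feature_set, ecg = hrv, bf = brv, combined = c(hrv, brv))
  if (!length(cols))
    stop_invalid("no feature columns found for set '%s'", feature_set)
  cols
}

scale_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

scale_apply <- function(x, sc) {
  sweep(sweep(x, 2L, sc$center, `-`), 2L, sc$scale, `/`)
}

#' Fit an SVM on a cohort table and return decision scores
#'
#' Selects the feature set (`"ecg"` = HRV columns, `"bf"` = BRV columns,
#' `"combined"` = both), standardizes features to zero mean and unit
#' variance on the training rows, fits the C-SVM and returns continuous
#' decision scores for ROC construction.
#'
#' @param table Cohort data.frame with `hrv_*`/`brv_*` feature columns.
#' @param feature_set One of `"combined"`, `"ecg"`, `"bf"`.
#' @param labels Binary labels (0/1), e.g. from [dichotomize()].
#' @param cost,gamma,kernel Passed to [svm_fit()].
#' @return List with `scores` (resubstitution decision values), `model`,
#'   `scaling` and `columns`.
#' @export
fit_predict_svm <- function(table, feature_set = "combined", labels,
                            cost = 1, gamma = NULL, kernel = "rbf") {
  cols <- feature_columns(table, feature_set)
  x <- as.matrix(table[, cols, drop = FALSE])
  if (length(unique(labels)) < 2L)
    stop_invalid("labels contain a single class")
  if (min(sum(labels == labels[1L]), sum(labels != labels[1L])) < 3L)
    stop_invalid("need at least 3 observations per class")
  sc <- scale_fit(x)
  xs <- scale_apply(x, sc)
  fit <- svm_fit(xs, labels, cost = cost, gamma = gamma, kernel = kernel)
  list(scores = predict(fit, xs), model = fit, scaling = sc, columns = cols)
}

# AUC as the Mann-Whitney statistic via ranks; ties count 1/2.
auc_rank <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop_invalid("AUC undefined: one class is empty")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the empirical AUC via placement values.
delong_var <- function(scores, labels) {
  xs <- scores[labels == 1L]
  ys <- scores[labels == 0L]
  m <- length(xs); n <- length(ys)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(xs, function(a) mean(psi(a, ys)), numeric(1))
  v01 <- vapply(ys, function(b) mean(psi(xs, b)), numeric(1))
  s10 <- if (m > 1L) var(v10) else 0
  s01 <- if (n > 1L) var(v01) else 0
  s10 / m + s01 / n
}

#' Empirical ROC curve, AUC and DeLong confidence interval
#'
#' ROC points are generated by thresholding the decision scores at every
#' unique value (prediction positive iff `score >= threshold`). The AUC is
#' the Mann-Whitney statistic (ties counted 1/2); its 95% CI uses the
#' DeLong variance estimate, clipped to \[0, 1\]. Sensitivity, specificity
#' and the confusion matrix are reported at the Youden-optimal point
#' (maximal sensitivity + specificity - 1).
#'
#' @param scores Continuous decision scores (higher = more severe).
#' @param labels Binary labels (0/1).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `roc_result`: `auc`, `auc_ci`, `roc_points`
#'   (data.frame `threshold`, `fpr`, `tpr`), `youden_threshold`,
#'   `sensitivity`, `specificity`, `confusion` (tp, tn, fp, fn).
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop_invalid("ROC undefined with a single class")
  auc <- auc_rank(scores, labels)
  se <- sqrt(delong_var(scores, labels))
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1))
  roc <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  j <- which.max(roc$tpr - roc$fpr)
  t_star <- roc$threshold[j]
  tp <- sum(scores >= t_star & labels == 1L)
  fn <- n1 - tp
  fp <- sum(scores >= t_star & labels == 0L)
  tn <- n0 - fp
  structure(list(auc = auc, auc_ci = ci, auc_se = se, roc_points = roc,
                 youden_threshold = t_star,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
                 n = length(labels)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f to %.3f), n = %d\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n))
  cat(sprintf("  Youden point: sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Classify apnea severity with optional leave-one-out cross-validation
#'
#' Dichotomizes the cohort AHI at `quantile`, then either fits once and
#' scores in-sample (`loocv = FALSE`) or, for honest AUC estimates,
#' successively withdraws each subject-night, refits the standardization
#' and the SVM on the remainder, and scores the withheld row
#' (`loocv = TRUE`). ROC/AUC are computed on the pooled scores. Folds
#' whose training set degenerates to one class are skipped with a warning.
#'
#' @param table Cohort data.frame with `hrv_*`/`brv_*` columns and `ahi`.
#' @param feature_set `"combined"`, `"ecg"` or `"bf"`.
#' @param quantile AHI dichotomization quantile (default 0.5).
#' @param loocv Logical; leave-one-out cross-validation (default TRUE).
#' @param cost,gamma,kernel Passed to [svm_fit()].
#' @param min_n Minimum rows required for LOOCV (default 10).
#' @return Object of class `classification_result` wrapping the
#'   [roc_auc()] output plus `feature_set`, `cutoff_quantile`, `cutoff`,
#'   `loocv` and the per-row `scores`/`labels`.
#' @export
classify_severity <- function(table, feature_set = "combined",
                              quantile = 0.5, loocv = TRUE, cost = 1,
                              gamma = NULL, kernel = "rbf", min_n = 10L) {
  stopifnot(is.data.frame(table), "ahi" %in% names(table))
  n <- nrow(table)
  lab <- dichotomize(table$ahi, quantile)
  labels <- lab$labels
  cols <- feature_columns(table, feature_set)
  x <- as.matrix(table[, cols, drop = FALSE])
  if (loocv) {
    if (n < min_n)
      stop_invalid("LOOCV needs at least %d rows, got %d", min_n, n)
    scores <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      ytr <- labels[-i]
      if (length(unique(ytr)) < 2L || min(sum(ytr == 1L), sum(ytr == 0L)) < 2L) {
        warning(sprintf("fold %d skipped: single-class training set", i))
        next
      }
      xtr <- x[-i, , drop = FALSE]
      sc <- scale_fit(xtr)
      fit <- svm_fit(scale_apply(xtr, sc), ytr, cost = cost, gamma = gamma,
                     kernel = kernel)
      scores[i] <- predict(fit, scale_apply(x[i, , drop = FALSE], sc))
    }
    ok <- !is.na(scores)
    roc <- roc_auc(scores[ok], labels[ok])
  } else {
    fp <- fit_predict_svm(table, feature_set, labels, cost = cost,
                          gamma = gamma, kernel = kernel)
    scores <- fp$scores
    roc <- roc_auc(scores, labels)
  }
  structure(c(roc, list(feature_set = feature_set,
                        cutoff_quantile = quantile, cutoff = lab$cutoff,
                        loocv = loocv, scores = scores, labels = labels)),
            class = c("classification_result", "roc_result"))
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("SA severity classification [%s]%s, AHI cutoff %.1f/h (q=%.2f)\n",
              x$feature_set, if (x$loocv) " (LOOCV)" else "",
              x$cutoff, x$cutoff_quantile))
  NextMethod()
}

#' Leave-one-out cross-validated AUC for one feature set
#'
#' Convenience wrapper around [classify_severity()] with `loocv = TRUE`.
#'
#' @inheritParams classify_severity
#' @return A `classification_result`.
#' @export
loocv_auc <- function(table, feature_set = "combined", quantile = 0.5,
                      cost = 1, gamma = NULL, kernel = "rbf") {
  classify_severity(table, feature_set, quantile, loocv = TRUE,
                    cost = cost, gamma = gamma, kernel = kernel)
}
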