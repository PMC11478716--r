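# Two-class C-SVM with RBF (or linear) kernel, solved as the dual
# quadratic program with quadprog. Cohorts here are small (tens of
# subject-nights), where the exact QP is fast and dependency-free.

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit a two-class support vector machine
#'
#' C-classification SVM solved exactly via the dual quadratic program
#' (box-constrained, one equality constraint). Defaults follow common
#' practice: RBF kernel, cost 1, `gamma = 1/(p * var(x))` computed on the
#' training matrix.
#'
#' @param x Numeric feature matrix (rows = observations). Should already
#'   be standardized; see [fit_predict_svm()].
#' @param y Labels coercible to two classes; internally mapped to -1/+1
#'   (the second sorted unique value is +1).
#' @param cost Soft-margin cost C (> 0).
#' @param gamma RBF width; `NULL` for the `1/(p * var)` default.
#' @param kernel `"rbf"` or `"linear"`.
#' @param class_weight `"balanced"` (default) rescales each class's cost
#'   inversely to its frequency, so decision scores are not biased by
#'   class imbalance (important for pooled leave-one-out scores, where
#'   each fold is imbalanced by construction); `"none"` uses `cost`
#'   for every observation.
#' @return Object of class `sleepbelt_svm` with the support coefficients,
#'   intercept and training data needed for prediction.
#' @export
svm_fit <- function(x, y, cost = 1, gamma = NULL,
                    kernel = c("rbf", "linear"),
                    class_weight = c("balanced", "none")) {
  kernel <- match.arg(kernel)
  class_weight <- match.arg(class_weight)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  lev <- sort(unique(y))
  if (length(lev) != 2L)
    stop_invalid("svm_fit() needs exactly 2 classes, got %d", length(lev))
  yy <- ifelse(y == lev[2L], 1, -1)
  n <- nrow(x)
  if (min(table(yy)) < 2L)
    stop_invalid("each class needs at least 2 observations")
  if (is.null(gamma)) {
    v <- var(as.vector(x))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  ci <- rep(cost, n)
  if (class_weight == "balanced") {
    n_pos <- sum(yy > 0)
    ci <- ifelse(yy > 0, cost * n / (2 * n_pos), cost * n / (2 * (n - n_pos)))
  }
  K <- if (kernel == "rbf") rbf_kernel(x, x, gamma) else tcrossprod(x)
  D <- (yy %o% yy) * K + diag(1e-8, n)
  A <- cbind(yy, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), -ci)
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1L)
  alpha <- pmin(pmax(sol$solution, 0), ci)
  f0 <- as.vector(K %*% (alpha * yy))
  eps <- 1e-6 * cost
  free <- alpha > eps & alpha < ci - eps
  if (any(free)) {
    b <- mean(yy[free] - f0[free])
  } else {
    # all SVs at bounds: take the midpoint of the KKT-feasible interval
    lower <- suppressWarnings(max((yy - f0)[(yy > 0 & alpha <= eps) |
                                              (yy < 0 & alpha >= ci - eps)]))
    upper <- suppressWarnings(min((yy - f0)[(yy < 0 & alpha <= eps) |
                                              (yy > 0 & alpha >= ci - eps)]))
    if (!is.finite(lower)) lower <- upper
    if (!is.finite(upper)) upper <- lower
    b <- if (is.finite(lower) && is.finite(upper)) (lower + upper) / 2 else 0
  }
  structure(list(x = x, y = yy, levels = lev, alpha = alpha, b = b,
                 gamma = gamma, cost = cost, kernel = kernel),
            class = "sleepbelt_svm")
}

#' Decision scores of a fitted SVM
#'
#' @param object A `sleepbelt_svm`.
#' @param newdata Feature matrix on the same standardized scale as the
#'   training data.
#' @param ... Unused.
#' @return Numeric decision values; positive scores favour the positive
#'   (second-level) class.
#' @export
predict.sleepbelt_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  sv <- object$alpha > 1e-8
  K <- if (object$kernel == "rbf") {
    rbf_kernel(newdata, object$x[sv, , drop = FALSE], object$gamma)
  } else {
    tcrossprod(newdata, object$x[sv, , drop = FALSE])
  }
  as.vector(K %*% (object$alpha[sv] * object$y[sv]) + object$b)
}
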