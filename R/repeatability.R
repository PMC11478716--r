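# Multi-night repeatability: intra-class correlation from a Gaussian
# random-intercept mixed model (REML), with parametric-bootstrap CIs,
# plus the per-channel median/IQR summary across features.

#' Repeatability (intra-class correlation) of nightly measurements
#'
#' Fits the random-intercept model `value ~ 1 + (1 | subject)` by REML and
#' reports `R = sigma2_subject / (sigma2_subject + sigma2_residual)`, the
#' proportion of total variance attributable to stable between-subject
#' differences. The confidence interval is a seeded parametric bootstrap:
#' responses are simulated from the fitted model and the model refitted.
#'
#' @param values Numeric vector of nightly feature values.
#' @param subject Subject identifier per value.
#' @param nboot Bootstrap draws for the CI (default 1000; 0 skips the CI).
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @param min_subjects Minimum number of subjects (default 5).
#' @return Object of class `repeatability_result`: `r_pt`, `ci`,
#'   `var_subject`, `var_residual`, `n_subjects`, `n_obs`.
#' @export
repeatability <- function(values, subject, nboot = 1000L, conf = 0.95,
                          seed = 1L, min_subjects = 5L) {
  stopifnot(length(values) == length(subject))
  ok <- is.finite(values) & !is.na(subject)
  values <- values[ok]
  subject <- factor(subject[ok])
  counts <- table(subject)
  if (length(counts) < min_subjects)
    stop_invalid("need at least %d subjects, got %d", min_subjects,
                 length(counts))
  if (sum(counts >= 2L) < 3L)
    stop_invalid("repeatability inestimable: fewer than 3 subjects with >= 2 nights")
  df <- data.frame(value = values, subject = subject)
  fit <- suppressMessages(
    lme4::lmer(value ~ 1 + (1 | subject), data = df, REML = TRUE))
  r_of <- function(f) {
    vc <- lme4::VarCorr(f)
    vs <- as.numeric(vc$subject)
    ve <- attr(vc, "sc")^2
    if (vs + ve <= 0) return(0)
    vs / (vs + ve)
  }
  r_pt <- r_of(fit)
  ci <- c(NA_real_, NA_real_)
  if (nboot > 0L) {
    boots <- with_seed(seed, {
      sims <- simulate(fit, nsim = nboot)
      vapply(seq_len(nboot), function(b) {
        fb <- tryCatch(suppressMessages(suppressWarnings(
          lme4::refit(fit, newresp = sims[[b]]))),
          error = function(e) NULL)
        if (is.null(fb)) NA_real_ else r_of(fb)
      }, numeric(1))
    })
    boots <- boots[is.finite(boots)]
    if (length(boots) >= 10L) {
      ci <- unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
    }
  }
  vc <- lme4::VarCorr(fit)
  structure(list(r_pt = r_pt, ci = ci,
                 var_subject = as.numeric(vc$subject),
                 var_residual = attr(vc, "sc")^2,
                 n_subjects = length(counts), n_obs = nrow(df),
                 nboot = nboot),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f", x$r_pt))
  if (all(is.finite(x$ci)))
    cat(sprintf(" (95%% CI %.3f to %.3f, %d bootstrap draws)",
                x$ci[1], x$ci[2], x$nboot))
  cat(sprintf("; %d subjects, %d nights\n", x$n_subjects, x$n_obs))
  invisible(x)
}

# Method-of-moments (one-way ANOVA) variance components for a balanced
# design; used as the independent oracle for the REML fit.
anova_icc <- function(values, subject) {
  subject <- factor(subject)
  k <- as.numeric(table(subject))
  stopifnot(length(unique(k)) == 1L)  # balanced only
  k <- k[1L]
  m <- tapply(values, subject, mean)
  grand <- mean(values)
  a <- length(m)
  msb <- k * sum((m - grand)^2) / (a - 1)
  msw <- sum((values - m[subject])^2) / (a * (k - 1))
  vs <- max((msb - msw) / k, 0)
  vs / (vs + msw)
}

#' Summarize repeatability across features per channel
#'
#' Median and inter-quartile range of the per-feature repeatability
#' estimates, grouped by channel (HRV vs BRV).
#'
#' @param results Data.frame with columns `feature`, `channel`, `r_pt`
#'   (e.g. accumulated from [repeatability()] runs).
#' @return Data.frame with one row per channel: `median`, `q1`, `q3`,
#'   `n_features`.
#' @export
summarize_repeatability <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("channel", "r_pt") %in% names(results)))
  if (!nrow(results)) stop_invalid("no repeatability results to summarize")
  out <- lapply(split(results$r_pt, results$channel), function(r) {
    q <- quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(median = q[2], q1 = q[1], q3 = q[3], n_features = length(r))
  })
  res <- do.call(rbind, out)
  res$channel <- names(out)
  rownames(res) <- NULL
  res[, c("channel", "median", "q1", "q3", "n_features")]
}
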