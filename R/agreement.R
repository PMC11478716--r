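# Device-agreement analysis: whole-night mean instantaneous rates and
# Bland-Altman comparison of belt vs PSG.

#' Whole-night mean instantaneous rate
#'
#' The mean of the per-interval instantaneous rates (60000/RR for ms
#' intervals, 60/BB for second intervals) -- not the rate of the mean
#' interval. This is the "mean instantaneous" convention; the alternative
#' (60/mean interval) is available via `convention = "rate_of_mean"`.
#'
#' @param series A `filtered_intervals` data.frame or numeric vector of
#'   intervals.
#' @param units `"ms"` (RR) or `"s"` (breath-to-breath); taken from the
#'   series attribute when present.
#' @param convention `"mean_instantaneous"` (default) or `"rate_of_mean"`.
#' @return Rate in beats/min or breaths/min.
#' @export
#' @examples
#' whole_night_mean_rate(c(500, 1000), units = "ms")  # 90, not 80
whole_night_mean_rate <- function(series, units = NULL,
                                  convention = c("mean_instantaneous",
                                                 "rate_of_mean")) {
  convention <- match.arg(convention)
  if (is.data.frame(series)) {
    if (is.null(units)) units <- attr(series, "units")
    ivl <- series$ivl
  } else {
    ivl <- as.numeric(series)
  }
  if (is.null(units) || !units %in% c("ms", "s"))
    stop_invalid("'units' must be \"ms\" or \"s\"")
  if (length(ivl) < 2L)
    stop_invalid("need at least 2 intervals for a whole-night mean rate")
  k <- if (units == "ms") 60000 else 60
  switch(convention,
         mean_instantaneous = mean(k / ivl),
         rate_of_mean = k / mean(ivl))
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `belt - psg`, so a positive bias means the
#' wearable reads higher than the reference. Reports the bias (mean
#' difference) with its 95% t-interval, the 95% limits of agreement
#' `bias +/- 1.96 sd`, and confidence intervals for each limit using the
#' standard Bland-Altman standard error `sqrt(3 sd^2 / n)`.
#'
#' @param belt,psg Paired measurement vectors (same length, n >= 3).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `bland_altman`: list with `bias`, `bias_ci`,
#'   `sd_diff`, `loa_lower`, `loa_upper`, `loa_lower_ci`, `loa_upper_ci`,
#'   `n`, and the per-pair `means`/`differences` for plotting.
#' @export
bland_altman <- function(belt, psg, conf = 0.95) {
  stopifnot(is.numeric(belt), is.numeric(psg))
  if (length(belt) != length(psg))
    stop_invalid("'belt' and 'psg' must be paired vectors of equal length")
  ok <- is.finite(belt) & is.finite(psg)
  belt <- belt[ok]; psg <- psg[ok]
  n <- length(belt)
  if (n < 3L) stop_invalid("Bland-Altman needs at least 3 complete pairs")
  d <- belt - psg
  bias <- mean(d)
  sdd <- sd(d)
  tq <- qt(1 - (1 - conf) / 2, df = n - 1L)
  se_bias <- sdd / sqrt(n)
  loa_half <- 1.96 * sdd
  se_loa <- sqrt(3 * sdd^2 / n)
  structure(list(
    bias = bias,
    bias_ci = c(bias - tq * se_bias, bias + tq * se_bias),
    sd_diff = sdd,
    loa_lower = bias - loa_half,
    loa_upper = bias + loa_half,
    loa_lower_ci = c(bias - loa_half - tq * se_loa,
                     bias - loa_half + tq * se_loa),
    loa_upper_ci = c(bias + loa_half - tq * se_loa,
                     bias + loa_half + tq * se_loa),
    n = n,
    means = (belt + psg) / 2,
    differences = d
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat(sprintf("Bland-Altman agreement (belt - reference), n = %d\n", x$n))
  cat(sprintf("  bias: %.*f (95%% CI %.*f to %.*f)\n", digits, x$bias,
              digits, x$bias_ci[1], digits, x$bias_ci[2]))
  cat(sprintf("  limits of agreement: %.*f to %.*f\n", digits, x$loa_lower,
              digits, x$loa_upper))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Mean-vs-difference scatter with dashed bias and limits-of-agreement
#' lines and dotted confidence-interval lines.
#'
#' @param x A `bland_altman` object.
#' @param ... Passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$means, x$differences, xlab = "mean of methods",
       ylab = "difference (belt - reference)", ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper), lty = 2)
  graphics::abline(h = c(x$bias_ci, x$loa_lower_ci, x$loa_upper_ci),
                   lty = 3, col = "grey40")
  invisible(x)
}
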