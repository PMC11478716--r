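# Independent brute-force oracles used for dual-route checks. These are
# deliberately naive (loops, explicit formulas) and share no code with the
# package implementations.

oracle_sdnn <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_pnn <- function(x, thr) {
  n <- 0L
  for (i in 2:length(x)) if (abs(x[i] - x[i - 1]) > thr) n <- n + 1L
  n / (length(x) - 1)
}

oracle_rmssd <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s / (length(x) - 1))
}

# type-7 quantile by explicit interpolation on the sorted sample
oracle_q7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_irrr <- function(x) oracle_q7(x, 0.75) - oracle_q7(x, 0.25)

oracle_madrr <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
}

oracle_hrvi <- function(x, bw) {
  anchor <- bw * floor(min(x) / bw)
  bins <- integer(0)
  for (v in x) {
    b <- floor((v - anchor) / bw) + 1L
    if (b > length(bins)) bins <- c(bins, integer(b - length(bins)))
    bins[b] <- bins[b] + 1L
  }
  length(x) / max(bins)
}

# AUC by explicit pairwise comparison, ties counted one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

oracle_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# one-way ANOVA method-of-moments ICC for balanced designs
oracle_anova_icc <- function(values, subject) {
  subject <- factor(subject)
  k <- unique(as.vector(table(subject)))
  stopifnot(length(k) == 1)
  m <- tapply(values, subject, mean)
  a <- length(m)
  msb <- k * sum((m - mean(values))^2) / (a - 1)
  msw <- sum((values - m[subject])^2) / (a * (k - 1))
  vs <- max((msb - msw) / k, 0)
  vs / (vs + msw)
}
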