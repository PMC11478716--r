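# Heart-rate and breathing-rate variability features: six time-domain
# statistics plus four spectral band powers and the LF/HF ratio, computed
# identically for RR series (ms) and breath-to-breath series (s).

#' Spectral analysis configuration
#'
#' Defaults mirror standard whole-night HRV practice: 300-s short-time
#' Fourier windows (Hann, non-overlapping), interval series interpolated
#' to an evenly sampled signal at 4 Hz, and the canonical frequency bands
#' ULF 0--0.003, VLF 0.003--0.03, LF 0.03--0.15 and HF 0.15--0.4 Hz.
#'
#' @param window_s STFT window length in seconds.
#' @param overlap Window overlap proportion in \[0, 1).
#' @param resample_hz Resampling rate for the interpolated interval signal.
#' @param bands Named list of `c(lo, hi)` Hz pairs (ascending,
#'   non-overlapping) for `ulf`, `vlf`, `lf`, `hf`.
#' @param max_gap_s Windows overlapping a gap longer than this (from
#'   quality-rejected stretches) are skipped rather than interpolated
#'   across.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(window_s = 300, overlap = 0, resample_hz = 4,
                            bands = list(ulf = c(0, 0.003),
                                         vlf = c(0.003, 0.03),
                                         lf = c(0.03, 0.15),
                                         hf = c(0.15, 0.4)),
                            max_gap_s = 15) {
  stopifnot(window_s > 0, overlap >= 0, overlap < 1, resample_hz > 0)
  edges <- unlist(bands)
  if (is.unsorted(edges)) stop_invalid("bands must be ascending and disjoint")
  structure(list(window_s = window_s, overlap = overlap,
                 resample_hz = resample_hz, bands = bands,
                 max_gap_s = max_gap_s),
            class = "spectral_config")
}

#' Time-domain variability features
#'
#' The six time-domain statistics of an interval series:
#' \describe{
#'   \item{sdnn}{standard deviation of the intervals}
#'   \item{pnn50}{proportion of successive-difference magnitudes exceeding
#'     `diff_threshold` (50 ms for RR series)}
#'   \item{rmssd}{root mean square of successive differences}
#'   \item{irrr}{inter-quartile range of the intervals}
#'   \item{madrr}{median of the intervals}
#'   \item{hrvi}{triangular index: total interval count divided by the
#'     maximum bin count of the interval histogram (bin width
#'     `bin_width`, 1/128 s for RR series)}
#' }
#'
#' @param intervals Numeric vector of intervals (ms for HRV, s for BRV).
#' @param diff_threshold Successive-difference threshold, same units as
#'   `intervals` (default 50 ms).
#' @param bin_width Histogram bin width for the triangular index, same
#'   units (default 7.8125 ms).
#' @return Named list with `sdnn`, `pnn50`, `rmssd`, `irrr`, `madrr`,
#'   `hrvi`.
#' @export
#' @examples
#' time_domain_features(c(800, 860, 870))
time_domain_features <- function(intervals, diff_threshold = 50,
                                 bin_width = 7.8125) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2L)
    stop_invalid("need at least 2 intervals for time-domain features")
  if (any(!is.finite(intervals)))
    stop_invalid("intervals must be finite")
  d <- diff(intervals)
  anchor <- bin_width * floor(min(intervals) / bin_width)
  counts <- tabulate(floor((intervals - anchor) / bin_width) + 1L)
  list(sdnn = sd(intervals),
       pnn50 = mean(abs(d) > diff_threshold),
       rmssd = sqrt(mean(d^2)),
       irrr = unname(diff(quantile(intervals, c(0.25, 0.75)))),
       madrr = median(intervals),
       hrvi = length(intervals) / max(counts))
}

# One-sided PSD of a single Hann-windowed, mean-removed segment.
# Returns data.frame(f, psd) with df = fs/n; excludes the DC bin.
segment_psd <- function(x, fs) {
  n <- length(x)
  w <- hann_window(n)
  y <- (x - mean(x)) * w
  sp <- abs(fft(y))^2 / (fs * sum(w^2))
  nf <- n %/% 2L
  f <- seq_len(nf) * fs / n
  psd <- 2 * sp[2L:(nf + 1L)]
  if (n %% 2L == 0L) psd[nf] <- psd[nf] / 2  # Nyquist bin is not doubled
  data.frame(f = f, psd = psd)
}

band_power_from_psd <- function(ps, lo, hi, fs, n) {
  df <- fs / n
  sum(ps$psd[ps$f > lo & ps$f <= hi]) * df
}

#' Spectral band powers of an interval series
#'
#' The interval series is interpolated (cubic spline) to an evenly
#' sampled signal at `cfg$resample_hz`, cut into `cfg$window_s` short-time
#' Fourier windows (Hann, mean-removed), and the one-sided power spectral
#' density of each window is integrated over the ULF/VLF/LF/HF bands.
#' Whole-night band powers are means over windows. Windows overlapping a
#' gap longer than `cfg$max_gap_s` (e.g. quality-rejected stretches) are
#' skipped. Because a 300-s window cannot resolve the ULF band
#' (1/300 Hz > 0.003 Hz), ULF is additionally estimated from the
#' whole-night periodogram and reported as `ulf_whole_night`.
#'
#' @param series A `filtered_intervals` data.frame (columns `t`, `ivl`) or
#'   any data.frame with interval end times and interval values.
#' @param cfg A [spectral_config()].
#' @return List with `ulf`, `vlf`, `lf`, `hf` (mean per-window powers,
#'   units of `intervals` squared), `lfhf`, `ulf_whole_night`,
#'   `n_windows`, and `windows` (per-window data.frame including
#'   `total_power` over (0, 0.4] Hz).
#' @export
band_powers <- function(series, cfg = spectral_config()) {
  stopifnot(is.data.frame(series), all(c("t", "ivl") %in% names(series)))
  t <- series$t
  v <- series$ivl
  if (length(t) < 4L || diff(range(t)) < cfg$window_s)
    stop_invalid("series span (%.0f s) shorter than one %g-s window",
                 if (length(t)) diff(range(t)) else 0, cfg$window_s)
  fs <- cfg$resample_hz
  grid <- seq(min(t), max(t), by = 1 / fs)
  x <- spline(t, v, xout = grid)$y
  # mark grid samples inside long gaps; windows touching them are skipped
  gaps <- which(diff(t) > cfg$max_gap_s)
  in_gap <- rep(FALSE, length(grid))
  for (g in gaps) {
    in_gap[grid > t[g] & grid < t[g + 1L]] <- TRUE
  }
  nwin <- as.integer(round(cfg$window_s * fs))
  step <- max(1L, as.integer(round(nwin * (1 - cfg$overlap))))
  starts <- seq(1L, length(grid) - nwin + 1L, by = step)
  bands <- cfg$bands
  rows <- list()
  for (s0 in starts) {
    idx <- s0:(s0 + nwin - 1L)
    if (any(in_gap[idx])) next
    ps <- segment_psd(x[idx], fs)
    p <- vapply(bands, function(b)
      band_power_from_psd(ps, b[1], b[2], fs, nwin), numeric(1))
    total <- band_power_from_psd(ps, 0, bands$hf[2], fs, nwin)
    rows[[length(rows) + 1L]] <-
      c(t_start = grid[s0], p, total_power = total)
  }
  if (!length(rows))
    stop_invalid("no complete spectral window free of long gaps")
  W <- as.data.frame(do.call(rbind, rows))
  pm <- colMeans(W[, names(bands), drop = FALSE])
  hf <- pm[["hf"]]
  lfhf <- if (hf > 0) pm[["lf"]] / hf else NA_real_
  if (!is.finite(lfhf)) warning("HF power is zero; LF/HF undefined")
  # whole-night periodogram for the ULF band
  ps_all <- segment_psd(x, fs)
  ulf_night <- band_power_from_psd(ps_all, bands$ulf[1], bands$ulf[2],
                                   fs, length(x))
  list(ulf = pm[["ulf"]], vlf = pm[["vlf"]], lf = pm[["lf"]], hf = hf,
       lfhf = lfhf, ulf_whole_night = ulf_night,
       n_windows = nrow(W), windows = W)
}

feature_names <- c("sdnn", "pnn50", "rmssd", "irrr", "madrr", "hrvi",
                   "ulf", "vlf", "lf", "hf", "lfhf")

#' Whole-night variability feature vector
#'
#' Computes the 11 named features (six time-domain, four band powers and
#' LF/HF) on a quality-filtered whole-night interval series. The identical
#' code path serves heart-rate variability (RR in ms) and breathing-rate
#' variability (breath-to-breath in s); only the units-dependent defaults
#' differ. For BRV the successive-difference threshold keeps its literal
#' 50 ms (0.05 s) value, and the triangular-index bin width is scaled by
#' the ratio of the median interval to a nominal 800 ms RR so the index
#' stays comparable across channels. The reported `ulf` is the whole-night
#' periodogram estimate (a 300-s window cannot resolve 0.003 Hz).
#'
#' @param series A `filtered_intervals` data.frame (`t`, `ivl`).
#' @param cfg A [spectral_config()].
#' @param channel `"hrv"` (RR ms) or `"brv"` (breath s).
#' @param diff_threshold,bin_width Override the units-dependent defaults.
#' @return Object of class `variability_features`: named list of the 11
#'   features with attribute `channel`.
#' @export
whole_night_features <- function(series, cfg = spectral_config(),
                                 channel = c("hrv", "brv"),
                                 diff_threshold = NULL, bin_width = NULL) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(series))
  if (!nrow(series))
    stop_invalid("empty interval series: refusing to compute features")
  ivl <- series$ivl
  if (is.null(diff_threshold))
    diff_threshold <- if (channel == "hrv") 50 else 0.05
  if (is.null(bin_width)) {
    bin_width <- if (channel == "hrv") 7.8125
      else 7.8125 / 800 * median(ivl)
  }
  td <- time_domain_features(ivl, diff_threshold, bin_width)
  bp <- band_powers(series, cfg)
  out <- c(td, list(ulf = bp$ulf_whole_night, vlf = bp$vlf, lf = bp$lf,
                    hf = bp$hf, lfhf = bp$lfhf))
  out <- out[feature_names]
  structure(out, channel = channel, n_intervals = length(ivl),
            n_windows = bp$n_windows, class = "variability_features")
}

#' @export
print.variability_features <- function(x, ...) {
  cat(sprintf("<variability_features> channel %s (%d intervals)\n",
              attr(x, "channel"), attr(x, "n_intervals")))
  print(round(unlist(x[feature_names]), 4))
  invisible(x)
}

#' @export
as.data.frame.variability_features <- function(x, ...,
                                               prefix = attr(x, "channel")) {
  v <- unlist(x[feature_names])
  names(v) <- paste(prefix, feature_names, sep = "_")
  as.data.frame(as.list(v))
}
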