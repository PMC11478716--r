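# Breathing pipeline: cycle detection from thoracic-excursion signals,
# 32-s template-matching quality filter and the 5-50 breaths/min
# plausibility band.

#' Construct a breath series
#'
#' Container for detected breathing cycles; breath-to-breath intervals
#' (s) are derived as successive onset differences.
#'
#' @param onset_times Strictly increasing breath-onset times (s).
#' @param inhale_durations Onset-to-peak durations (s), one per onset.
#' @param amplitudes Peak-to-trough excursions, one per onset.
#' @param source Device label.
#' @return Object of class `breath_series`.
#' @export
breath_series <- function(onset_times, inhale_durations = NULL,
                          amplitudes = NULL, source = "belt") {
  n <- length(onset_times)
  new_breath_series(as.numeric(onset_times),
                    inhale_durations %||% rep(NA_real_, n),
                    amplitudes %||% rep(NA_real_, n), source)
}

new_breath_series <- function(onset_times, inhale_durations, amplitudes,
                              source = "belt") {
  bb <- if (length(onset_times) >= 2L) diff(onset_times) else numeric(0)
  structure(list(onset_times = onset_times, bb_intervals = bb,
                 inhale_durations = inhale_durations,
                 amplitudes = amplitudes, source = source),
            class = "breath_series")
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %d cycles (%s), median interval %.2f s\n",
              length(x$onset_times), x$source,
              if (length(x$bb_intervals)) median(x$bb_intervals) else NA))
  invisible(x)
}

# Strict turning points of a smoothed trace, pruned so that adjacent
# extrema closer (in amplitude) than `thr` are removed pairwise. Returns
# indices and kinds (+1 peak, -1 trough), alternating.
pruned_extrema <- function(z, thr) {
  dz <- diff(z)
  s <- sign(dz)
  s[s == 0] <- 1  # break plateaus towards "rising"
  turn <- which(diff(s) != 0) + 1L
  if (!length(turn)) return(list(idx = integer(0), kind = integer(0)))
  kind <- ifelse(s[turn - 1L] > 0, 1L, -1L)
  idx <- turn
  repeat {
    if (length(idx) < 2L) break
    amp <- abs(diff(z[idx]))
    bad <- which(amp < thr)
    if (!length(bad)) break
    # remove the weakest adjacent pair, then re-evaluate
    b <- bad[which.min(amp[bad])]
    drop <- c(b, b + 1L)
    idx <- idx[-drop]
    kind <- kind[-drop]
  }
  # enforce alternation (pruning keeps it, but guard against plateaus)
  keep <- c(TRUE, diff(kind) != 0)
  list(idx = idx[keep], kind = kind[keep])
}

#' Detect breathing cycles in an excursion record
#'
#' Smooths the excursion trace (0.5 s moving average), extracts
#' amplitude-pruned turning points and pairs each trough with the
#' following peak: the trough is the breath onset (start of inhalation),
#' trough-to-peak time is the inhale duration, and trough-to-peak
#' excursion is the cycle amplitude. Cycles closer than `min_cycle_s`
#' are merged. A flat record yields an empty series.
#'
#' @param rec A `signal_record` with channel `"excursion"`, `fs >= 10`.
#' @param min_cycle_s Minimum onset-to-onset separation (default 1.2 s,
#'   i.e. 50 breaths/min).
#' @param prominence Turning-point pruning threshold as a fraction of the
#'   robust signal amplitude (default 0.08).
#' @param smooth_s Moving-average width (s).
#' @return A `breath_series`.
#' @export
detect_breaths <- function(rec, min_cycle_s = 1.2, prominence = 0.08,
                           smooth_s = 0.5) {
  stopifnot(inherits(rec, "signal_record"))
  if (!identical(rec$channel, "excursion"))
    stop_invalid("detect_breaths() requires an excursion record, got '%s'",
                 rec$channel)
  if (rec$fs < 10) stop_invalid("excursion sampling rate must be >= 10 Hz")
  fs <- rec$fs
  z <- moving_average(rec$samples, round(smooth_s * fs))
  amp_robust <- diff(quantile(z, c(0.05, 0.95), names = FALSE))
  if (!is.finite(amp_robust) || amp_robust <= 0)
    return(new_breath_series(numeric(0), numeric(0), numeric(0), rec$device))
  ex <- pruned_extrema(z, thr = prominence * amp_robust)
  if (length(ex$idx) < 2L)
    return(new_breath_series(numeric(0), numeric(0), numeric(0), rec$device))
  troughs <- ex$idx[ex$kind == -1L]
  peaks <- ex$idx[ex$kind == 1L]
  onsets <- numeric(0); inhale <- numeric(0); amps <- numeric(0)
  for (tr in troughs) {
    pk <- peaks[peaks > tr][1L]
    if (is.na(pk)) next
    t_on <- rec$t0 + (tr - 1L) / fs
    if (length(onsets) && t_on - onsets[length(onsets)] < min_cycle_s) next
    onsets <- c(onsets, t_on)
    inhale <- c(inhale, (pk - tr) / fs)
    amps <- c(amps, z[pk] - z[tr])
  }
  new_breath_series(onsets, inhale, amps, rec$device)
}

# Time-normalize one breathing cycle: inhale and exhale phases resampled
# separately to fixed grids, then unit-amplitude scaled. Operationalizes
# the reference-template adjustment for total cycle duration, inhale-phase
# duration and excursion amplitude.
normalize_cycle <- function(z, fs, t0, onset, peak_t, end_t,
                            n_inhale = 40L, n_exhale = 60L) {
  t_of <- function(tt) (tt - t0) * fs + 1
  i0 <- t_of(onset); ip <- t_of(peak_t); i1 <- t_of(end_t)
  n <- length(z)
  if (!all(is.finite(c(i0, ip, i1)))) return(NULL)
  if (i0 < 1 || i1 > n || ip <= i0 || i1 <= ip) return(NULL)
  grab <- function(a, b, m) {
    xs <- seq(a, b, length.out = max(m, 2L))
    approx(seq_len(n), z, xout = xs, rule = 2)$y
  }
  v <- c(grab(i0, ip, n_inhale), grab(ip, i1, n_exhale))
  rng <- range(v)
  if (diff(rng) <= 0) return(NULL)
  (v - rng[1]) / diff(rng)
}

#' Template-matching quality of breathing segments
#'
#' The record is cut into consecutive `segment_s` segments (32 s). Each
#' breathing cycle (onset to next onset, peak at the inhale end) is
#' time-normalized phase-wise -- inhale and exhale resampled separately to
#' fixed-length grids -- and amplitude-normalized to \[0, 1\], which
#' adjusts the comparison for total cycle duration, inhale-phase duration
#' and excursion amplitude. The segment's reference template is the
#' element-wise median of its normalized cycles; the segment r is the mean
#' Pearson correlation of each cycle against the reference. A segment is
#' accepted iff `r >= r_threshold` (inclusive, 0.75). Segments with fewer
#' than 2 complete cycles are rejected.
#'
#' @param rec The excursion `signal_record`.
#' @param breaths The `breath_series` detected from `rec`.
#' @param segment_s Segment length (default 32 s).
#' @param r_threshold Acceptance threshold (default 0.75, inclusive).
#' @param smooth_s Smoothing used before cycle extraction (matches
#'   [detect_breaths()]).
#' @return Data.frame of class `breath_quality_segments` with columns
#'   `start`, `duration`, `n_cycles`, `r_template`, `verdict`.
#' @export
breath_template_quality <- function(rec, breaths, segment_s = 32,
                                    r_threshold = 0.75, smooth_s = 0.5) {
  stopifnot(inherits(rec, "signal_record"), inherits(breaths, "breath_series"))
  fs <- rec$fs
  z <- moving_average(rec$samples, round(smooth_s * fs))
  dur_total <- length(rec$samples) / fs
  n_seg <- max(1L, ceiling(dur_total / segment_s - 1e-9))
  starts <- rec$t0 + segment_s * (seq_len(n_seg) - 1L)
  on <- breaths$onset_times
  n_cyc <- length(on) - 1L
  cyc_mat <- NULL
  cyc_seg <- integer(0)
  if (n_cyc >= 1L) {
    rows <- vector("list", n_cyc)
    for (k in seq_len(n_cyc)) {
      rows[[k]] <- normalize_cycle(z, fs, rec$t0, on[k],
                                   on[k] + breaths$inhale_durations[k],
                                   on[k + 1L])
    }
    okc <- !vapply(rows, is.null, logical(1))
    if (any(okc)) {
      cyc_mat <- do.call(rbind, rows[okc])
      cyc_seg <- findInterval(on[seq_len(n_cyc)][okc], starts)
    }
  }
  res <- data.frame(start = starts, duration = segment_s, n_cycles = 0L,
                    r_template = NA_real_, verdict = "rejected",
                    stringsAsFactors = FALSE)
  for (s in seq_along(starts)) {
    rows <- which(cyc_seg == s)
    res$n_cycles[s] <- length(rows)
    if (length(rows) < 2L) next
    M <- cyc_mat[rows, , drop = FALSE]
    ref <- matrixStats::colMedians(M)
    r <- row_cor(M, ref)
    if (all(is.na(r))) next
    res$r_template[s] <- mean(r, na.rm = TRUE)
    if (res$r_template[s] >= r_threshold) res$verdict[s] <- "accepted"
  }
  class(res) <- c("breath_quality_segments", "data.frame")
  res
}

#' Exclude implausible breath-to-breath intervals
#'
#' Removes intervals whose instantaneous rate falls outside
#' `[min_bpm, max_bpm]` breaths per minute, i.e. intervals outside
#' `[60/max_bpm, 60/min_bpm]` seconds. Boundary rates are kept (only
#' rates strictly below 5 or above 50 are excluded).
#'
#' @param breaths A `breath_series`.
#' @param min_bpm,max_bpm Plausibility band (defaults 5 and 50 /min).
#' @return A `breath_series` containing only the onsets that start a
#'   surviving interval (the final onset is retained as interval end).
#' @export
breath_rate_filter <- function(breaths, min_bpm = 5, max_bpm = 50) {
  stopifnot(inherits(breaths, "breath_series"))
  if (!length(breaths$bb_intervals)) return(breaths)
  # compare in the interval domain so the printed boundary rates (5 and
  # 50 /min exactly) are kept without floating-point surprises
  bb <- breaths$bb_intervals
  keep <- bb >= 60 / max_bpm - 1e-9 & bb <= 60 / min_bpm + 1e-9
  on_keep <- c(keep, FALSE) | c(FALSE, keep)
  flt <- breaths
  flt$bb_intervals <- breaths$bb_intervals[keep]
  flt$onset_times <- breaths$onset_times[on_keep]
  flt$inhale_durations <- breaths$inhale_durations[on_keep]
  flt$amplitudes <- breaths$amplitudes[on_keep]
  flt$keep <- keep
  flt
}

#' Combined quality + plausibility filter for breath intervals
#'
#' An interval survives iff its starting onset lies in an accepted 32-s
#' segment and its instantaneous rate is within the plausibility band.
#'
#' @inheritParams breath_rate_filter
#' @param segments Output of [breath_template_quality()].
#' @return A `filtered_intervals` data.frame (`t` = interval end time s,
#'   `ivl` in seconds, `gap_before` logical); attribute `units = "s"`.
#' @export
filtered_bb <- function(breaths, segments, min_bpm = 5, max_bpm = 50) {
  stopifnot(inherits(breaths, "breath_series"))
  bb <- breaths$bb_intervals
  if (!length(bb)) return(empty_intervals("s"))
  on <- breaths$onset_times[seq_along(bb)]
  seg_of <- findInterval(on, segments$start)
  seg_of[seg_of < 1L | seg_of > nrow(segments)] <- NA_integer_
  ok <- !is.na(seg_of) & segments$verdict[seg_of] == "accepted" &
    bb >= 60 / max_bpm - 1e-9 & bb <= 60 / min_bpm + 1e-9
  if (!any(ok)) {
    warning("no breath interval passed the quality and plausibility filters")
    return(empty_intervals("s"))
  }
  idx <- which(ok)
  out <- data.frame(t = breaths$onset_times[idx + 1L], ivl = bb[idx],
                    gap_before = c(TRUE, diff(idx) > 1L))
  attr(out, "units") <- "s"
  class(out) <- c("filtered_intervals", "data.frame")
  out
}
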