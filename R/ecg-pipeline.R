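# ECG quality pipeline: R-peak detection, segment-wise template-correlation
# quality verdicts with a physiological-plausibility fallback, and the
# whole-night quality summary.

#' Construct an R-peak series
#'
#' Container for detected R-peak times; RR intervals (ms) are derived as
#' successive differences. Use this to feed externally detected peaks into
#' the quality filters.
#'
#' @param times Strictly increasing peak times in seconds.
#' @param source Device label, e.g. `"belt"` or `"psg"`.
#' @return Object of class `rpeak_series` with `times`, `rr` (ms),
#'   `source`.
#' @export
rpeak_series <- function(times, source = "belt") {
  new_rpeak_series(as.numeric(times), source)
}

new_rpeak_series <- function(times, source = "belt") {
  stopifnot(!is.unsorted(times, strictly = TRUE) || length(times) <= 1L)
  rr <- if (length(times) >= 2L) diff(times) * 1000 else numeric(0)
  structure(list(times = times, rr = rr, source = source),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d peaks (%s), median RR %.0f ms\n",
              length(x$times), x$source,
              if (length(x$rr)) median(x$rr) else NA))
  invisible(x)
}

#' Detect R-peaks in an ECG record
#'
#' Derivative-energy detector in the Pan-Tompkins family: baseline removal
#' by moving-average subtraction, squared derivative, moving-window
#' integration (120 ms), block-adaptive thresholding, and refinement of
#' each detection to the local signal maximum. A 200 ms refractory period
#' is enforced; of two candidates closer than that, the taller survives.
#'
#' @param rec A `signal_record` with channel `"ecg"` and `fs >= 125`.
#' @param refractory_s Minimum peak-to-peak separation (s).
#' @return An `rpeak_series`: `times` (s), `rr` (ms), `source` (device).
#' @export
detect_r_peaks <- function(rec, refractory_s = 0.2) {
  stopifnot(inherits(rec, "signal_record"))
  if (!identical(rec$channel, "ecg"))
    stop_invalid("detect_r_peaks() requires an ECG record, got '%s'",
                 rec$channel)
  if (rec$fs < 125) stop_invalid("ECG sampling rate must be >= 125 Hz")
  x <- rec$samples
  fs <- rec$fs
  if (length(x) / fs < 10)
    stop_invalid("signal too short for R-peak detection (< 10 s)")
  xf <- x - moving_average(x, round(0.6 * fs))
  e <- c(0, diff(xf))^2
  ei <- moving_average(e, round(0.12 * fs))
  if (max(ei) <= 0) return(new_rpeak_series(numeric(0), rec$device))
  # block-adaptive threshold (10-s blocks) with a global floor so that
  # quiet blocks do not promote numerical noise to beats
  n <- length(ei)
  block <- as.integer(10 * fs)
  nblk <- ceiling(n / block)
  blk_id <- rep(seq_len(nblk), each = block, length.out = n)
  blk_max <- tapply(ei, blk_id, max)
  thr <- pmax(0.25 * blk_max[blk_id], 1e-4 * max(ei))
  locmax <- c(FALSE, diff(ei) > 0) & c(ei[-n] >= ei[-1], FALSE)
  cand <- which(locmax & ei > thr)
  if (!length(cand)) return(new_rpeak_series(numeric(0), rec$device))
  # refine each candidate to the raw (baseline-removed) maximum nearby
  half <- as.integer(round(0.10 * fs))
  ref <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(xf[lo:hi]) - 1L
  }, integer(1))
  ref <- sort(unique(ref))
  # refractory: greedy keep-the-taller merge
  keep <- integer(0)
  min_gap <- refractory_s * fs
  for (i in ref) {
    if (!length(keep) || i - keep[length(keep)] >= min_gap) {
      keep <- c(keep, i)
    } else if (xf[i] > xf[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  new_rpeak_series(rec$t0 + (keep - 1L) / fs, rec$device)
}

#' Plausibility verdict for one quality segment
#'
#' Fallback applied when template correlation fails: the segment's RR
#' intervals are physiologically plausible iff every interval lies in
#' `[rr_min, rr_max]` ms (333--2000 ms, i.e. 180 down to 30 beats/min) and
#' no interval deviates from the segment's median by more than `max_dev`
#' (33%). An interval belongs to the segment containing its ending R-peak.
#'
#' @param peaks An `rpeak_series`.
#' @param start,duration Segment bounds in seconds.
#' @param rr_min,rr_max Plausibility band in ms.
#' @param max_dev Maximum relative deviation from the segment median.
#' @return `"accepted_by_plausibility"` or `"rejected"`.
#' @export
plausibility_filter <- function(peaks, start, duration = 15,
                                rr_min = 333, rr_max = 2000,
                                max_dev = 0.33) {
  stopifnot(inherits(peaks, "rpeak_series"))
  if (!length(peaks$rr)) return("rejected")
  ends <- peaks$times[-1L]
  rr <- peaks$rr[ends >= start & ends < start + duration]
  if (!length(rr)) return("rejected")
  if (any(rr < rr_min | rr > rr_max)) return("rejected")
  med <- median(rr)
  if (any(abs(rr - med) / med > max_dev)) return("rejected")
  "accepted_by_plausibility"
}

# Extract aligned beat complexes as a matrix: one row per peak, columns are
# fixed sample offsets around the R sample. Peaks whose window leaves the
# record are dropped (their row is NA and flagged).
beat_matrix <- function(x, fs, t0, peak_times, lo_s, hi_s) {
  off <- seq.int(-round(lo_s * fs), round(hi_s * fs))
  ridx <- round((peak_times - t0) * fs) + 1L
  n <- length(x)
  M <- matrix(NA_real_, nrow = length(ridx), ncol = length(off))
  ok <- ridx + off[1L] >= 1L & ridx + off[length(off)] <= n
  if (any(ok)) {
    idx <- outer(ridx[ok], off, `+`)
    M[ok, ] <- x[idx]
  }
  list(M = M, complete = ok)
}

#' Segment-wise template-correlation quality of an ECG record
#'
#' The record is cut into consecutive `segment_s` segments (15 s). Within a
#' segment, every beat's QRS and PQRST complex (fixed windows around the
#' R sample; windows may span segment borders) is correlated against the
#' segment's reference complex, the element-wise median of all complexes in
#' the segment. The segment correlation is the mean of the per-beat Pearson
#' r, computed separately for the QRS and PQRST windows. A segment is
#' `accepted_by_correlation` iff the better of the two exceeds
#' `r_threshold` strictly (r > 0.98); otherwise the RR plausibility
#' fallback of [plausibility_filter()] decides between
#' `accepted_by_plausibility` and `rejected`. Segments with fewer than
#' 3 usable beats have undefined r and fall through to the fallback.
#'
#' @param rec The ECG `signal_record`.
#' @param peaks The `rpeak_series` detected from `rec`.
#' @param segment_s Segment length in seconds (default 15).
#' @param r_threshold Correlation acceptance threshold (default 0.98,
#'   strict inequality).
#' @param qrs_half_s QRS window half-width around R (default 0.06 s).
#' @param pqrst_lo_s,pqrst_hi_s PQRST window before/after R (defaults
#'   0.25 s and 0.40 s).
#' @param rr_min,rr_max,max_dev Passed to [plausibility_filter()].
#' @return A data.frame of class `quality_segments` with columns `start`,
#'   `duration`, `n_beats`, `r_qrs`, `r_pqrst`, `verdict`.
#' @export
segment_template_quality <- function(rec, peaks, segment_s = 15,
                                     r_threshold = 0.98,
                                     qrs_half_s = 0.06,
                                     pqrst_lo_s = 0.25, pqrst_hi_s = 0.40,
                                     rr_min = 333, rr_max = 2000,
                                     max_dev = 0.33) {
  stopifnot(inherits(rec, "signal_record"), inherits(peaks, "rpeak_series"))
  dur_total <- length(rec$samples) / rec$fs
  n_seg <- max(1L, ceiling(dur_total / segment_s - 1e-9))
  starts <- rec$t0 + segment_s * (seq_len(n_seg) - 1L)
  qrs <- beat_matrix(rec$samples, rec$fs, rec$t0, peaks$times,
                     qrs_half_s, qrs_half_s)
  pqrst <- beat_matrix(rec$samples, rec$fs, rec$t0, peaks$times,
                       pqrst_lo_s, pqrst_hi_s)
  seg_of <- findInterval(peaks$times, starts)
  res <- data.frame(start = starts, duration = segment_s,
                    n_beats = 0L, r_qrs = NA_real_, r_pqrst = NA_real_,
                    verdict = NA_character_, stringsAsFactors = FALSE)
  seg_r <- function(bm, rows) {
    rows <- rows[bm$complete[rows]]
    if (length(rows) < 3L) return(NA_real_)
    M <- bm$M[rows, , drop = FALSE]
    ref <- matrixStats::colMedians(M)
    r <- row_cor(M, ref)
    if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
  }
  for (s in seq_along(starts)) {
    rows <- which(seg_of == s)
    res$n_beats[s] <- length(rows)
    res$r_qrs[s] <- seg_r(qrs, rows)
    res$r_pqrst[s] <- seg_r(pqrst, rows)
    best <- suppressWarnings(max(res$r_qrs[s], res$r_pqrst[s], na.rm = TRUE))
    if (is.finite(best) && best > r_threshold) {
      res$verdict[s] <- "accepted_by_correlation"
    } else {
      res$verdict[s] <- plausibility_filter(peaks, starts[s], segment_s,
                                            rr_min, rr_max, max_dev)
    }
  }
  class(res) <- c("quality_segments", "data.frame")
  res
}

#' Quality-filter an RR series by segment verdicts
#'
#' Removes RR intervals belonging to rejected segments (an interval belongs
#' to the segment containing its ending R-peak). Gap positions are recorded
#' so that spectral analysis can treat the boundaries correctly.
#'
#' @param peaks An `rpeak_series`.
#' @param segments A `quality_segments` data.frame.
#' @return A data.frame of class `filtered_intervals` with columns `t`
#'   (interval end time, s), `ivl` (ms), `gap_before` (logical: preceding
#'   interval(s) were removed). Attribute `units` is `"ms"`. If everything
#'   is rejected, a zero-row frame is returned with a warning.
#' @export
filtered_rr <- function(peaks, segments) {
  stopifnot(inherits(peaks, "rpeak_series"))
  if (!length(peaks$rr)) {
    warning("no RR intervals to filter")
    return(empty_intervals("ms"))
  }
  ends <- peaks$times[-1L]
  seg_of <- findInterval(ends, segments$start)
  seg_of[seg_of < 1L | seg_of > nrow(segments)] <- NA_integer_
  ok <- !is.na(seg_of) & segments$verdict[seg_of] != "rejected"
  if (!any(ok)) {
    warning("all segments rejected: empty RR series; ",
            "variability features must not be computed")
    return(empty_intervals("ms"))
  }
  idx <- which(ok)
  gap <- c(TRUE, diff(idx) > 1L)
  out <- data.frame(t = ends[idx], ivl = peaks$rr[idx], gap_before = gap)
  attr(out, "units") <- "ms"
  class(out) <- c("filtered_intervals", "data.frame")
  out
}

empty_intervals <- function(units) {
  out <- data.frame(t = numeric(0), ivl = numeric(0), gap_before = logical(0))
  attr(out, "units") <- units
  class(out) <- c("filtered_intervals", "data.frame")
  out
}

#' Whole-night quality summary
#'
#' Per-segment correlation is the better of the QRS and PQRST r. The
#' summary is the whole-night mean and SD of the defined per-segment r
#' values and the fraction of segments accepted (by either route).
#'
#' @param segments A `quality_segments` data.frame.
#' @return List with `r_mean`, `r_sd`, `fraction_accepted`, `n_segments`.
#' @export
quality_summary <- function(segments) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L)
  r <- pmax(segments$r_qrs, segments$r_pqrst, na.rm = TRUE)
  r[is.infinite(r)] <- NA_real_
  r <- suppressWarnings(ifelse(is.na(segments$r_qrs) & is.na(segments$r_pqrst),
                               NA_real_, r))
  r_def <- r[!is.na(r)]
  if (!length(r_def))
    stop_invalid("no segment has a defined correlation; summary undefined")
  list(r_mean = mean(r_def),
       r_sd = if (length(r_def) > 1L) sd(r_def) else 0,
       fraction_accepted = mean(segments$verdict != "rejected"),
       n_segments = nrow(segments))
}
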