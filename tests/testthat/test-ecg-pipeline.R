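# ECG pipeline: R-peak detection, template-correlation quality, RR
# plausibility fallback, filtering, whole-night summary.

test_that("detect_r_peaks validates input and handles degenerate signals", {
  spec <- subject_spec("a", ahi = 0, noise_level = 0, seed = 1)
  exc <- synthesize_excursion(spec, schedule_apneas(spec, 60), fs = 10,
                              duration = 60)
  expect_error(detect_r_peaks(exc), "ECG")
  short <- signal_record("ecg", "belt", 125, rep(0, 125 * 5))
  expect_error(detect_r_peaks(short), "short")
  flat <- signal_record("ecg", "belt", 125, rep(0, 125 * 30))
  expect_length(detect_r_peaks(flat)$times, 0L)
})

test_that("detect_r_peaks matches ground truth on a clean night", {
  spec <- subject_spec("a", ahi = 20, noise_level = 0, seed = 2)
  ev <- schedule_apneas(spec, 600)
  rec <- synthesize_ecg(spec, ev, fs = 125, duration = 600)
  peaks <- detect_r_peaks(rec)
  gt <- rec$meta$r_times
  d <- vapply(gt, function(g) min(abs(peaks$times - g)), numeric(1))
  expect_gte(mean(d <= 0.02), 0.99)
})

test_that("refractory rule keeps one of two close candidates", {
  fs <- 125
  t <- seq(0, 30, by = 1 / fs)
  x <- numeric(length(t))
  spike <- function(at, amp) amp * exp(-((t - at)^2) / (2 * 0.012^2))
  for (b in seq(0.5, 29.5, by = 1)) x <- x + spike(b, 1)
  baseline <- detect_r_peaks(signal_record("ecg", "belt", fs, x))
  # an extra candidate 100 ms after an existing beat must not add a peak
  x2 <- x + spike(10.6, 0.8)
  doubled <- detect_r_peaks(signal_record("ecg", "belt", fs, x2))
  expect_identical(length(doubled$times), length(baseline$times))
})

test_that("identical complexes give r = 1 and correlation acceptance", {
  spec <- subject_spec("a", ahi = 0, noise_level = 0, seed = 3)
  rec <- synthesize_ecg(spec, schedule_apneas(spec, 120), fs = 125,
                        duration = 120)
  qs <- segment_template_quality(rec, detect_r_peaks(rec))
  full <- qs[qs$n_beats >= 3, ]
  expect_true(all(full$verdict == "accepted_by_correlation"))
  expect_true(all(full$r_qrs > 0.999, na.rm = TRUE))
})

test_that("white-noise 'beats' are not accepted by correlation", {
  set.seed(42)
  fs <- 125
  x <- rnorm(fs * 60)
  peaks <- rpeak_series(seq(0.5, 59.5, by = 0.8))
  qs <- segment_template_quality(signal_record("ecg", "belt", fs, x), peaks)
  defined <- qs[!is.na(qs$r_qrs), ]
  expect_true(all(defined$r_qrs < 0.5))
  expect_false(any(qs$verdict == "accepted_by_correlation"))
})

test_that("correlation threshold is strictly exceeded (r == threshold fails)", {
  # setting the threshold to a segment's measured r reproduces the
  # r == threshold boundary exactly: the strict inequality must reject the
  # correlation route and fall through to plausibility, which accepts the
  # regular rhythm
  spec <- subject_spec("a", ahi = 0, noise_level = 0.3, seed = 4)
  rec <- synthesize_ecg(spec, schedule_apneas(spec, 60), fs = 125,
                        duration = 60)
  peaks <- detect_r_peaks(rec)
  qs <- segment_template_quality(rec, peaks)
  k <- which(qs$n_beats >= 3)[1]
  r_star <- max(qs$r_qrs[k], qs$r_pqrst[k], na.rm = TRUE)
  qs2 <- segment_template_quality(rec, peaks, r_threshold = r_star)
  expect_identical(qs2$verdict[k], "accepted_by_plausibility")
  # nudging the threshold below r restores correlation acceptance
  qs3 <- segment_template_quality(rec, peaks, r_threshold = r_star - 1e-9)
  expect_identical(qs3$verdict[k], "accepted_by_correlation")
})

test_that("plausibility_filter implements band and deviation rules", {
  mk <- function(rr_ms) rpeak_series(cumsum(c(0, rr_ms)) / 1000)
  expect_identical(plausibility_filter(mk(c(800, 810, 820)), 0, 15),
                   "accepted_by_plausibility")
  expect_identical(plausibility_filter(mk(c(800, 250, 820)), 0, 15),
                   "rejected")
  # 1100/800 - 1 = 37.5% > 33%
  expect_identical(plausibility_filter(mk(c(800, 800, 1100)), 0, 15),
                   "rejected")
  # boundary: 2000 ms is inside the band
  expect_identical(plausibility_filter(mk(c(2000, 2000, 2000)), 0, 15),
                   "accepted_by_plausibility")
  empty <- rpeak_series(numeric(0))
  expect_identical(plausibility_filter(empty, 0, 15), "rejected")
})

test_that("filtered_rr removes exactly the rejected segments' intervals", {
  peaks <- rpeak_series(seq(0, 59, by = 1))  # 60 beats, 59 intervals of 1 s
  segs <- data.frame(start = seq(0, 45, by = 15), duration = 15,
                     verdict = "accepted_by_correlation")
  out <- filtered_rr(peaks, segs)
  expect_identical(nrow(out), 59L)
  expect_equal(out$ivl, rep(1000, 59))

  segs$verdict[2] <- "rejected"  # [15, 30): interval ends 16..29 -> 15 gone
  out2 <- filtered_rr(peaks, segs)
  expect_identical(nrow(out2), 44L)
  expect_true(any(out2$gap_before))

  segs$verdict[] <- "rejected"
  expect_warning(out3 <- filtered_rr(peaks, segs), "rejected")
  expect_identical(nrow(out3), 0L)
})

test_that("quality_summary aggregates segment correlations", {
  segs <- data.frame(start = c(0, 15, 30, 45), duration = 15,
                     r_qrs = c(1, 1, NA, 0.2), r_pqrst = c(1, NA, NA, 0.3),
                     verdict = c("accepted_by_correlation",
                                 "accepted_by_correlation",
                                 "accepted_by_plausibility", "rejected"))
  qsum <- quality_summary(segs)
  # per-segment r is the better of the two defined complexes
  expect_equal(qsum$r_mean, mean(c(1, 1, 0.3)))
  expect_equal(qsum$fraction_accepted, 0.75)

  all_one <- data.frame(start = 0, duration = 15, r_qrs = 1, r_pqrst = 1,
                        verdict = "accepted_by_correlation")
  s1 <- quality_summary(all_one)
  expect_equal(s1$r_mean, 1)
  expect_equal(s1$r_sd, 0)
  expect_equal(s1$fraction_accepted, 1)

  none <- data.frame(start = 0, duration = 15, r_qrs = NA_real_,
                     r_pqrst = NA_real_, verdict = "rejected")
  expect_error(quality_summary(none), "undefined")
})

test_that("segment r equals a brute-force oracle on a short segment", {
  spec <- subject_spec("a", ahi = 0, noise_level = 1, seed = 5)
  rec <- synthesize_ecg(spec, schedule_apneas(spec, 15), fs = 125,
                        duration = 15)
  peaks <- detect_r_peaks(rec)
  qs <- segment_template_quality(rec, peaks)
  # oracle: extract the same +/-60 ms windows, median reference, mean r
  fs <- rec$fs
  half <- round(0.06 * fs)
  ridx <- round(peaks$times * fs) + 1
  ok <- ridx - half >= 1 & ridx + half <= length(rec$samples)
  M <- t(vapply(ridx[ok], function(i) rec$samples[(i - half):(i + half)],
                numeric(2 * half + 1)))
  ref <- apply(M, 2, median)
  r_oracle <- mean(apply(M, 1, function(row) oracle_pearson(row, ref)))
  expect_equal(qs$r_qrs[1], r_oracle, tolerance = 1e-9)
})

test_that("added noise does not increase segment correlation (seeds)", {
  spec <- subject_spec("a", ahi = 0, noise_level = 0, seed = 6)
  rec <- synthesize_ecg(spec, schedule_apneas(spec, 120), fs = 125,
                        duration = 120)
  peaks <- detect_r_peaks(rec)
  r_clean <- mean(segment_template_quality(rec, peaks)$r_qrs, na.rm = TRUE)
  worse <- 0L
  for (s in 1:8) {
    noisy <- rec
    set.seed(s)
    noisy$samples <- rec$samples + rnorm(length(rec$samples), 0, 0.1)
    r_noisy <- mean(segment_template_quality(noisy, peaks)$r_qrs, na.rm = TRUE)
    worse <- worse + (r_noisy <= r_clean)
  }
  expect_gte(worse, 7L)
})

test_that("filter soundness: surviving RR in band or correlation-accepted", {
  spec <- subject_spec("a", ahi = 40, noise_level = 1.5, seed = 7)
  ev <- schedule_apneas(spec, 900)
  rec <- inject_artifacts(synthesize_ecg(spec, ev, fs = 125, duration = 900),
                          0.2, rng_seed = 8)
  peaks <- detect_r_peaks(rec)
  qs <- segment_template_quality(rec, peaks)
  flt <- suppressWarnings(filtered_rr(peaks, qs))
  seg_of <- findInterval(flt$t, qs$start)
  by_corr <- qs$verdict[seg_of] == "accepted_by_correlation"
  expect_true(all(by_corr | (flt$ivl >= 333 & flt$ivl <= 2000)))
})

test_that("noise-free night is almost fully accepted, HR recovered", {
  spec <- subject_spec("a", ahi = 0, noise_level = 0, seed = 8)
  rec <- synthesize_ecg(spec, schedule_apneas(spec, 600), fs = 125,
                        duration = 600)
  peaks <- detect_r_peaks(rec)
  qs <- segment_template_quality(rec, peaks)
  expect_gte(mean(qs$verdict != "rejected"), 0.99)
  flt <- filtered_rr(peaks, qs)
  expect_lt(abs(whole_night_mean_rate(flt) - spec$base_hr), 1)
})
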