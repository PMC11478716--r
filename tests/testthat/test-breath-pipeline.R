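# Breathing pipeline: cycle detection, template quality, rate plausibility.

test_that("detect_breaths validates input and handles flat signals", {
  spec <- subject_spec("a", ahi = 0, noise_level = 0, seed = 1)
  ecg <- synthesize_ecg(spec, schedule_apneas(spec, 60), fs = 125,
                        duration = 60)
  expect_error(detect_breaths(ecg), "excursion")
  flat <- signal_record("excursion", "belt", 10, rep(0, 600))
  expect_length(detect_breaths(flat)$onset_times, 0L)
})

test_that("detect_breaths counts a pure sinusoid correctly", {
  fs <- 10
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * (14 / 60) * t)
  br <- detect_breaths(signal_record("excursion", "belt", fs, x))
  expect_true(abs(length(br$onset_times) - 14) <= 1)
})

test_that("detect_breaths matches generator ground truth on clean night", {
  spec <- subject_spec("a", ahi = 0, noise_level = 0, seed = 2)
  rec <- synthesize_excursion(spec, schedule_apneas(spec, 600), fs = 10,
                              duration = 600)
  br <- detect_breaths(rec)
  gt <- rec$meta$onset_times
  d <- vapply(gt, function(g) min(abs(br$onset_times - g)), numeric(1))
  expect_gte(mean(d <= 0.25), 0.98)
})

test_that("identical cycles are accepted with r = 1; threshold inclusive", {
  spec <- subject_spec("a", ahi = 0, noise_level = 0, seed = 3)
  rec <- synthesize_excursion(spec, schedule_apneas(spec, 128), fs = 10,
                              duration = 128)
  br <- detect_breaths(rec)
  qs <- breath_template_quality(rec, br)
  full <- qs[qs$n_cycles >= 2, ]
  expect_true(all(full$r_template > 0.999))
  expect_true(all(full$verdict == "accepted"))
  # inclusive boundary: a threshold equal to the measured r still accepts,
  # and a threshold just above it rejects
  k <- which(qs$n_cycles >= 2)[1]
  r_star <- qs$r_template[k]
  qs_eq <- breath_template_quality(rec, br, r_threshold = r_star)
  expect_identical(qs_eq$verdict[k], "accepted")
  qs_hi <- breath_template_quality(rec, br, r_threshold = r_star + 1e-9)
  expect_identical(qs_hi$verdict[k], "rejected")
})

test_that("noise cycles are rejected; sparse segments are rejected", {
  set.seed(9)
  fs <- 10
  x <- rnorm(64 * fs)
  fake <- breath_series(seq(0.5, 62, by = 4))
  qs <- breath_template_quality(signal_record("excursion", "belt", fs, x),
                                fake)
  defined <- qs[!is.na(qs$r_template), ]
  expect_true(all(defined$r_template < 0.5))
  expect_true(all(qs$verdict == "rejected"))

  one_cycle <- breath_series(c(1, 5))
  qs2 <- breath_template_quality(signal_record("excursion", "belt", fs, x),
                                 one_cycle)
  expect_true(all(qs2$verdict == "rejected"))
})

test_that("breath_rate_filter excludes rates outside 5-50 /min", {
  br <- breath_series(cumsum(c(0, 12.5, 4, 1, 4)))
  flt <- breath_rate_filter(br)
  # 12.5 s = 4.8 /min excluded; 1 s = 60 /min excluded; 4 s kept
  expect_equal(flt$bb_intervals, c(4, 4))
  # boundary rates are kept: 12 s = 5 /min, 1.2 s = 50 /min
  br2 <- breath_series(cumsum(c(0, 12, 1.2)))
  expect_equal(breath_rate_filter(br2)$bb_intervals, c(12, 1.2))
  # all implausible -> empty
  br3 <- breath_series(cumsum(c(0, 1, 1, 1)))
  expect_length(breath_rate_filter(br3)$bb_intervals, 0L)
})

test_that("normalized-cycle r equals a brute-force oracle", {
  spec <- subject_spec("a", ahi = 0, noise_level = 0.6, seed = 4)
  rec <- synthesize_excursion(spec, schedule_apneas(spec, 32), fs = 10,
                              duration = 32)
  br <- detect_breaths(rec)
  qs <- breath_template_quality(rec, br)
  seg <- qs[which(qs$n_cycles >= 2)[1], ]
  # oracle: re-extract the same smoothed trace and phase-wise grids
  z <- rec$samples
  w <- round(0.5 * rec$fs)
  half <- w %/% 2
  zs <- vapply(seq_along(z), function(i) {
    lo <- max(1, i - half); hi <- min(length(z), i + half)
    mean(z[lo:hi])
  }, numeric(1))
  grab <- function(a, b, m) approx(seq_along(zs), zs,
                                   xout = seq(a, b, length.out = m),
                                   rule = 2)$y
  on <- br$onset_times
  rows <- list()
  for (k in seq_len(length(on) - 1)) {
    if (on[k] < seg$start || on[k] >= seg$start + seg$duration) next
    i0 <- on[k] * rec$fs + 1
    ip <- (on[k] + br$inhale_durations[k]) * rec$fs + 1
    i1 <- on[k + 1] * rec$fs + 1
    v <- c(grab(i0, ip, 40), grab(ip, i1, 60))
    rows[[length(rows) + 1]] <- (v - min(v)) / (max(v) - min(v))
  }
  M <- do.call(rbind, rows)
  ref <- apply(M, 2, median)
  r_oracle <- mean(apply(M, 1, function(row) oracle_pearson(row, ref)))
  expect_equal(seg$r_template, r_oracle, tolerance = 1e-9)
})

test_that("filtered_bb keeps only in-band intervals in accepted segments", {
  spec <- subject_spec("a", ahi = 30, noise_level = 1.2, seed = 5)
  ev <- schedule_apneas(spec, 900)
  rec <- synthesize_excursion(spec, ev, fs = 10, duration = 900)
  br <- detect_breaths(rec)
  qs <- breath_template_quality(rec, br)
  flt <- suppressWarnings(filtered_bb(br, qs))
  if (nrow(flt)) {
    rate <- 60 / flt$ivl
    expect_true(all(rate >= 5 & rate <= 50))
    on <- flt$t - flt$ivl
    seg_of <- findInterval(on, qs$start)
    expect_true(all(qs$verdict[seg_of] == "accepted"))
  } else {
    succeed("fully rejected night")
  }
})

test_that("noise-free synthetic night: >= 99% of segments accepted", {
  spec <- subject_spec("a", ahi = 0, noise_level = 0, seed = 6)
  rec <- synthesize_excursion(spec, schedule_apneas(spec, 640), fs = 10,
                              duration = 640)
  br <- detect_breaths(rec)
  qs <- breath_template_quality(rec, br)
  expect_gte(mean(qs$verdict == "accepted"), 0.99)
  flt <- filtered_bb(br, qs)
  expect_lt(abs(whole_night_mean_rate(flt) - spec$base_bf), 1)
})
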