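# Variability features: time-domain statistics, STFT band powers,
# whole-night aggregation.

test_that("time-domain features match hand computations", {
  td <- time_domain_features(c(800, 860, 870))
  expect_equal(td$pnn50, 0.5)
  expect_equal(td$rmssd, sqrt((3600 + 100) / 2), tolerance = 1e-12)

  const <- time_domain_features(rep(800, 100))
  expect_equal(const$sdnn, 0)
  expect_equal(const$pnn50, 0)
  expect_equal(const$rmssd, 0)
  expect_equal(const$irrr, 0)
  expect_equal(const$madrr, 800)

  expect_error(time_domain_features(800), "2 intervals")
})

test_that("time-domain features match brute-force oracles (random series)", {
  set.seed(101)
  for (i in 1:60) {
    x <- runif(sample(5:300, 1), 400, 1500)
    td <- time_domain_features(x)
    expect_equal(td$sdnn, oracle_sdnn(x), tolerance = 1e-9)
    expect_equal(td$pnn50, oracle_pnn(x, 50), tolerance = 1e-9)
    expect_equal(td$rmssd, oracle_rmssd(x), tolerance = 1e-9)
    expect_equal(td$irrr, oracle_irrr(x), tolerance = 1e-9)
    expect_equal(td$madrr, oracle_madrr(x), tolerance = 1e-9)
    expect_equal(td$hrvi, oracle_hrvi(x, 7.8125), tolerance = 1e-9)
  }
})

test_that("order-dependence: irrr/madrr permutation-invariant, rmssd not", {
  set.seed(7)
  changed <- 0L
  for (i in 1:20) {
    x <- runif(100, 600, 1200)
    xp <- sample(x)
    a <- time_domain_features(x)
    b <- time_domain_features(xp)
    expect_equal(a$irrr, b$irrr)
    expect_equal(a$madrr, b$madrr)
    expect_equal(a$sdnn, b$sdnn)
    changed <- changed + (abs(a$rmssd - b$rmssd) > 1e-9)
  }
  expect_gte(changed, 19L)
})

test_that("scale equivariance of the time-domain features", {
  set.seed(8)
  x <- runif(300, 600, 1200)
  c_ <- 2.5
  a <- time_domain_features(x)
  b <- time_domain_features(c_ * x, diff_threshold = 50 * c_,
                            bin_width = 7.8125 * c_)
  expect_equal(b$sdnn, c_ * a$sdnn, tolerance = 1e-9)
  expect_equal(b$rmssd, c_ * a$rmssd, tolerance = 1e-9)
  expect_equal(b$irrr, c_ * a$irrr, tolerance = 1e-9)
  expect_equal(b$madrr, c_ * a$madrr, tolerance = 1e-9)
  expect_equal(b$pnn50, a$pnn50)
  expect_equal(b$hrvi, a$hrvi)
})

test_that("band_powers: validation, constant series, modulation placement", {
  short <- interval_frame(cumsum(rep(0.8, 10)), rep(800, 10))
  expect_error(band_powers(short), "window")

  const <- interval_frame(cumsum(rep(0.8, 2000)), rep(800, 2000))
  # zero HF power flags the undefined LF/HF ratio
  expect_warning(bp <- band_powers(const), "HF")
  expect_lt(bp$lf + bp$hf + bp$vlf, 1e-12)
  expect_true(is.na(bp$lfhf))

  lf_mod <- band_powers(modulated_rr(0.10))
  tot <- lf_mod$ulf + lf_mod$vlf + lf_mod$lf + lf_mod$hf
  expect_gte(lf_mod$lf / tot, 0.90)
  expect_gt(lf_mod$lfhf, 1)

  hf_mod <- band_powers(modulated_rr(0.25))
  tot2 <- hf_mod$ulf + hf_mod$vlf + hf_mod$lf + hf_mod$hf
  expect_gte(hf_mod$hf / tot2, 0.90)
  expect_lt(hf_mod$lfhf, 1)
})

test_that("band powers partition the (0, 0.4] Hz window power (Parseval)", {
  set.seed(11)
  s <- modulated_rr(0.08, amp = 40)
  s$ivl <- s$ivl + rnorm(nrow(s), 0, 20)
  bp <- band_powers(s)
  W <- bp$windows
  lhs <- W$ulf + W$vlf + W$lf + W$hf
  expect_true(all(abs(lhs - W$total_power) <= 1e-6 * W$total_power))
})

test_that("whole-night features: 11 features, channel symmetry", {
  s <- modulated_rr(0.10)
  f <- whole_night_features(s, channel = "hrv")
  expect_named(f[1:11], c("sdnn", "pnn50", "rmssd", "irrr", "madrr", "hrvi",
                          "ulf", "vlf", "lf", "hf", "lfhf"))
  expect_identical(attr(f, "channel"), "hrv")
  # identical numeric input through the BRV path gives identical numbers
  g <- whole_night_features(s, channel = "brv", diff_threshold = 50,
                            bin_width = 7.8125)
  expect_equal(unclass(f)[1:11], unclass(g)[1:11])
  expect_identical(attr(g, "channel"), "brv")
  expect_error(whole_night_features(s[0, ], channel = "hrv"), "empty")
})

test_that("windows overlapping long gaps are skipped", {
  t1 <- cumsum(rep(0.8, 1500))
  t2 <- max(t1) + 60 + cumsum(rep(0.8, 1500))  # 60-s hole
  s <- interval_frame(c(t1, t2), rep(800, 3000) + rnorm(3000, 0, 5))
  bp <- band_powers(s)
  gap_lo <- max(t1)
  gap_hi <- max(t1) + 60
  expect_true(all(bp$windows$t_start + 300 <= gap_lo + 1e-9 |
                    bp$windows$t_start >= gap_hi - 1e-9))
})

test_that("apnea burden raises RR variability (paired simulations)", {
  wins <- 0L
  n_pairs <- 100L
  for (s in seq_len(n_pairs)) {
    hi <- subject_spec("h", ahi = 50, noise_level = 0, seed = s)
    lo <- subject_spec("l", ahi = 0, noise_level = 0, seed = s)
    tr_hi <- synthesize_rr_track(hi, schedule_apneas(hi, 1200), 1200)
    tr_lo <- synthesize_rr_track(lo, schedule_apneas(lo, 1200), 1200)
    sd_hi <- sd(tr_hi$rr, na.rm = TRUE)
    sd_lo <- sd(tr_lo$rr, na.rm = TRUE)
    wins <- wins + (sd_hi > sd_lo)
  }
  expect_gte(wins / n_pairs, 0.95)
})
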