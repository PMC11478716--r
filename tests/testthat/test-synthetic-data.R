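# Synthetic cohort generator: event scheduling, waveform synthesis,
# artifact injection, cohort assembly.

test_that("subject_spec validates its invariants", {
  expect_error(subject_spec("a", ahi = -1), "ahi")
  expect_error(subject_spec("a", ahi = 10, base_hr = 200), "base_hr")
  expect_error(subject_spec("a", ahi = 10, base_bf = 2), "base_bf")
  expect_error(subject_spec("a", ahi = 10, n_nights = 0), "n_nights")
  expect_s3_class(subject_spec("a", ahi = 0), "subject_spec")
})

test_that("schedule_apneas: zero rate, validation, geometry", {
  spec <- subject_spec("a", ahi = 0, seed = 1)
  expect_identical(nrow(schedule_apneas(spec, 7 * 3600)), 0L)
  expect_error(schedule_apneas(spec, -5), "positive")

  spec60 <- subject_spec("a", ahi = 60, seed = 1)
  for (s in 1:25) {
    ev <- schedule_apneas(spec60, 60, rng_seed = s)
    if (!nrow(ev)) next
    expect_true(all(ev$onset >= 0))
    expect_true(all(ev$onset + ev$duration <= 60 + 1e-9))
    expect_true(all(ev$duration >= 10))
    if (nrow(ev) > 1) {
      # brute-force pairwise overlap check
      for (i in 1:(nrow(ev) - 1)) {
        expect_lte(ev$onset[i] + ev$duration[i], ev$onset[i + 1] + 1e-9)
      }
    }
  }
})

test_that("schedule_apneas realizes the AHI rate (Monte-Carlo)", {
  spec <- subject_spec("a", ahi = 33, seed = 1)
  counts <- vapply(1:1000, function(s)
    nrow(schedule_apneas(spec, 7 * 3600, rng_seed = s)), integer(1))
  target <- 33 * 7
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - target), 3 * se)
})

test_that("schedule_apneas is deterministic given the seed", {
  spec <- subject_spec("a", ahi = 40, seed = 123)
  expect_identical(schedule_apneas(spec, 3600), schedule_apneas(spec, 3600))
})

test_that("synthesize_ecg: constant rhythm rate, fs validation, RR band", {
  spec <- subject_spec("a", ahi = 0, noise_level = 0, base_hr = 60, seed = 2)
  ev <- schedule_apneas(spec, 60)
  expect_error(synthesize_ecg(spec, ev, fs = 100, duration = 60), "125")
  rec <- synthesize_ecg(spec, ev, fs = 125, duration = 60)
  peaks <- detect_r_peaks(rec)
  expect_true(abs(length(peaks$times) - 60) <= 1)

  # ground-truth RR stays inside the plausibility band, with events and noise
  specn <- subject_spec("b", ahi = 60, noise_level = 2, seed = 3)
  for (s in 1:5) {
    evn <- schedule_apneas(specn, 1800, rng_seed = s)
    tr <- synthesize_rr_track(specn, evn, 1800, rng_seed = s)
    rr <- tr$rr[!is.na(tr$rr)]
    expect_true(all(rr >= 333 & rr <= 2000))
  }
})

test_that("apnea events raise RR variability around them", {
  spec <- subject_spec("a", ahi = 45, noise_level = 0, seed = 4)
  ev <- schedule_apneas(spec, 3600)
  tr <- synthesize_rr_track(spec, ev, 3600)
  near <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(ev))) {
    near <- near | (tr$t >= ev$onset[i] & tr$t <= ev$onset[i] + ev$duration[i] + 15)
  }
  rr <- tr$rr
  expect_gt(sd(rr[near], na.rm = TRUE), sd(rr[!near], na.rm = TRUE))
})

test_that("synthesize_excursion: rate, central cessation, plausibility band", {
  spec <- subject_spec("a", ahi = 0, noise_level = 0, base_bf = 14, seed = 5)
  rec <- synthesize_excursion(spec, schedule_apneas(spec, 60), fs = 10,
                              duration = 60)
  expect_true(abs(sum(rec$meta$onset_times < 60) - 14) <= 1)

  ev <- data.frame(onset = 20, duration = 20, type = "central")
  rec2 <- synthesize_excursion(spec, ev, fs = 10, duration = 60)
  x <- rec2$samples
  t <- (seq_along(x) - 1) / 10
  base_amp <- max(x[t < 18])
  # a breath initiated just before onset completes its exhale inside the
  # event; cessation holds from one cycle length into the event onwards
  expect_lt(max(x[t > 25 & t < 39]), 0.05 * base_amp)

  # instantaneous rate in [5, 50] breaths/min outside events
  specn <- subject_spec("b", ahi = 30, noise_level = 1, seed = 6)
  evn <- schedule_apneas(specn, 1800)
  tr <- synthesize_breath_track(specn, evn, 1800)
  rate <- 60 / tr$duration
  in_ev <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(evn))) {
    in_ev <- in_ev | (tr$onset >= evn$onset[i] - 2 &
                        tr$onset <= evn$onset[i] + evn$duration[i] + 16)
  }
  expect_true(all(rate[!in_ev] >= 5 & rate[!in_ev] <= 50))
})

test_that("inject_artifacts: identity, share, validation", {
  spec <- subject_spec("a", ahi = 0, noise_level = 1, seed = 7)
  rec <- synthesize_ecg(spec, schedule_apneas(spec, 120), fs = 125,
                        duration = 120)
  expect_identical(inject_artifacts(rec, 0, 1), rec)
  expect_error(inject_artifacts(rec, 1.2, 1), "0, 1")
  bad <- inject_artifacts(rec, 0.3, rng_seed = 8)
  share <- mean(bad$meta$artifact_mask)
  expect_gte(share, 0.2)
  expect_lte(share, 0.4)
})

test_that("fully corrupted ECG is mostly rejected by the quality filter", {
  spec <- subject_spec("a", ahi = 0, noise_level = 1, seed = 9)
  rec <- synthesize_ecg(spec, schedule_apneas(spec, 600), fs = 125,
                        duration = 600)
  bad <- inject_artifacts(rec, 1, rng_seed = 10)
  peaks <- detect_r_peaks(bad)
  if (length(peaks$times) >= 3) {
    qs <- segment_template_quality(bad, peaks)
    expect_lt(mean(qs$verdict != "rejected"), 0.10)
  } else {
    succeed("corruption left too few detections to segment")
  }
})

test_that("sample_ahi matches the target severity distribution", {
  meds <- vapply(1:200, function(s) median(sample_ahi(51, rng_seed = s)),
                 numeric(1))
  expect_gte(median(meds), 25)
  expect_lte(median(meds), 41)
})

test_that("generate_cohort: cardinality, shared ground truth, determinism", {
  co <- generate_cohort(1, night_duration = 120, rng_seed = 42)
  expect_length(co$records, 4L)
  expect_setequal(
    vapply(co$records, function(r) paste(r$channel, r$device), character(1)),
    c("ecg belt", "ecg psg", "excursion belt", "excursion psg"))
  # belt and psg share identical physiology (R-peak ground truth)
  ecg <- Filter(function(r) r$channel == "ecg", co$records)
  expect_identical(ecg[[1]]$meta$r_times, ecg[[2]]$meta$r_times)
  expect_identical(ecg[[1]]$meta$events, ecg[[2]]$meta$events)

  co2 <- generate_cohort(1, night_duration = 120, rng_seed = 42)
  expect_identical(co, co2)
})
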