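# Synthetic cohort generator: virtual subjects with an apnea burden (AHI)
# that drives the heart-rate and breathing variability structure the
# downstream pipeline is designed to detect, plus artifact injection to
# exercise the signal-quality filters.

#' Describe a virtual subject
#'
#' A subject specification bundles the physiological parameters from which
#' whole-night signals are synthesized. The apnea-hypopnea index (AHI,
#' events per hour) is the generative severity parameter: it sets the rate
#' of the nocturnal apnea events that perturb both the RR-interval and the
#' breathing-interval series.
#'
#' @param subject_id Opaque subject identifier.
#' @param ahi Apnea-hypopnea index in events per hour (>= 0).
#' @param n_nights Number of nights recorded for this subject (>= 1).
#' @param base_hr Baseline heart rate in beats per minute, in \[30, 180\].
#' @param base_bf Baseline breathing frequency in breaths per minute,
#'   in \[5, 50\].
#' @param noise_level Unitless noise multiplier (>= 0); 0 gives noise-free
#'   waveforms.
#' @param seed Integer seed governing every random draw for this subject.
#' @return An object of class `subject_spec`.
#' @export
#' @examples
#' subject_spec("S01", ahi = 33)
subject_spec <- function(subject_id, ahi, n_nights = 1L, base_hr = 60,
                         base_bf = 14, noise_level = 1, seed = 1L) {
  if (!is.numeric(ahi) || length(ahi) != 1L || is.na(ahi) || ahi < 0)
    stop_invalid("'ahi' must be a single non-negative number")
  if (n_nights < 1) stop_invalid("'n_nights' must be >= 1")
  if (base_hr < 30 || base_hr > 180)
    stop_invalid("'base_hr' must lie in [30, 180] beats/min")
  if (base_bf < 5 || base_bf > 50)
    stop_invalid("'base_bf' must lie in [5, 50] breaths/min")
  if (noise_level < 0) stop_invalid("'noise_level' must be >= 0")
  structure(list(subject_id = as.character(subject_id), ahi = ahi,
                 n_nights = as.integer(n_nights), base_hr = base_hr,
                 base_bf = base_bf, noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "subject_spec")
}

#' @export
print.subject_spec <- function(x, ...) {
  cat(sprintf("<subject_spec %s> AHI %.1f/h, %d night(s), HR %g bpm, BF %g /min, noise %g\n",
              x$subject_id, x$ahi, x$n_nights, x$base_hr, x$base_bf,
              x$noise_level))
  invisible(x)
}

#' Schedule apnea events for one night
#'
#' Draws a night's worth of non-overlapping apnea events whose expected
#' count equals `ahi * night_duration / 3600`. The event count is Poisson;
#' onsets are placed by distributing the night's free (non-event) time
#' uniformly between events, which preserves the target rate exactly
#' (a thinned Poisson process would undercount at high AHI). Durations
#' respect the 10 s scoring floor.
#'
#' @param spec A [subject_spec()].
#' @param night_duration Night length in seconds (> 0).
#' @param rng_seed Integer seed; defaults to the spec's seed.
#' @param p_obstructive Probability that an event is obstructive rather
#'   than central (default 0.9, reflecting the predominance of
#'   obstructive apnea in referred populations).
#' @return A data.frame with columns `onset` (s), `duration` (s, >= 10)
#'   and `type` (`"obstructive"` or `"central"`), ordered by onset.
#' @export
schedule_apneas <- function(spec, night_duration, rng_seed = spec$seed,
                            p_obstructive = 0.9) {
  stopifnot(inherits(spec, "subject_spec"))
  if (!is.numeric(night_duration) || night_duration <= 0)
    stop_invalid("'night_duration' must be a positive duration in seconds")
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      type = character(0), stringsAsFactors = FALSE)
  if (spec$ahi == 0) return(empty)
  with_seed(rng_seed, {
    n <- rpois(1L, spec$ahi * night_duration / 3600)
    if (n == 0L) return(empty)
    duration <- 10 + pmin(rexp(n, rate = 1 / 12), 50)
    # Drop excess events (rare, short-night regime) so everything fits with
    # a small guard gap between events.
    gap_min <- 2
    repeat {
      need <- sum(duration) + gap_min * (n - 1)
      if (need <= night_duration || n == 1L) break
      n <- n - 1L
      duration <- duration[seq_len(n)]
    }
    if (sum(duration) > night_duration) {
      return(empty)
    }
    free <- night_duration - sum(duration)
    # n + 1 gaps proportional to uniform spacings
    cuts <- sort(runif(n))
    gaps <- diff(c(0, cuts, 1)) * free
    onset <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, duration[-n]))
    type <- ifelse(runif(n) < p_obstructive, "obstructive", "central")
    data.frame(onset = onset, duration = duration, type = type,
               stringsAsFactors = FALSE)
  })
}

# Piecewise apnea modulation evaluated at times t (seconds).
# Returns list(rr_mult, br_mult, amp_mult): multiplicative effects on the
# RR interval, the breath interval and the excursion amplitude.
# During an event: bradycardia (RR up), slowed breathing, amplitude drop
# (obstructive: strong reduction; central: near-total cessation).
# In the 15 s after an event: tachycardia overshoot, hyperpnoea (faster,
# deeper breaths) -- the classical cyclic-variation pattern.
apnea_modulation <- function(t, events, recovery_s = 15) {
  rr <- rep(1, length(t)); br <- rep(1, length(t)); amp <- rep(1, length(t))
  if (is.null(events) || nrow(events) == 0L) {
    return(list(rr_mult = rr, br_mult = br, amp_mult = amp))
  }
  onsets <- events$onset
  ends <- events$onset + events$duration
  idx <- findInterval(t, onsets)
  has <- idx >= 1L
  if (any(has)) {
    i <- idx[has]
    ti <- t[has]
    dur <- events$duration[i]
    # magnitude grows with event duration, saturating at 30 s
    a <- 0.12 + 0.10 * pmin(dur / 30, 1)
    in_event <- ti < ends[i]
    post <- !in_event & (ti - ends[i]) <= recovery_s
    # half-sine ramp across the event; linear decay after it
    u <- (ti - onsets[i]) / dur
    rr_h <- rep(1, length(ti)); br_h <- rr_h; amp_h <- rr_h
    rr_h[in_event] <- 1 + a[in_event] * sin(pi * pmin(pmax(u[in_event], 0), 1))
    w <- 1 - (ti[post] - ends[i][post]) / recovery_s
    rr_h[post] <- 1 - 0.6 * a[post] * w
    br_h[in_event] <- 1.45
    br_h[post] <- 1 - 0.25 * w
    obstructive <- events$type[i] == "obstructive"
    amp_h[in_event & obstructive] <- 0.15
    amp_h[in_event & !obstructive] <- 0.02
    amp_h[post] <- 1 + 0.25 * w
    rr[has] <- rr_h; br[has] <- br_h; amp[has] <- amp_h
  }
  list(rr_mult = rr, br_mult = br, amp_mult = amp)
}

#' Ground-truth RR-interval track for one night
#'
#' Generates the beat-to-beat RR series underlying an ECG record: a
#' baseline rhythm with respiratory sinus arrhythmia (modulation at the
#' breathing frequency), slower low-frequency and very-low-frequency
#' oscillations, apnea-linked bradycardia during events with a
#' tachycardia overshoot in the 15 s after each event, and seeded
#' beat-to-beat jitter scaled by `noise_level`. RR intervals are clamped
#' inside the physiological plausibility band of 333--2000 ms.
#'
#' @inheritParams schedule_apneas
#' @param events Event table from [schedule_apneas()] (may be empty).
#' @param duration Night duration in seconds.
#' @return A data.frame with columns `t` (R-peak time, s) and `rr`
#'   (following interval, ms); the last beat has `rr = NA`.
#' @export
synthesize_rr_track <- function(spec, events, duration,
                                rng_seed = spec$seed) {
  stopifnot(inherits(spec, "subject_spec"), duration > 0)
  with_seed(derive_seed(rng_seed, 101L), {
    base_rr <- 60000 / spec$base_hr
    f_resp <- spec$base_bf / 60
    phi <- runif(3, 0, 2 * pi)
    n_max <- ceiling(duration / (0.333)) + 2L
    jitter_sd <- 0.008 * spec$noise_level
    jitter <- if (jitter_sd > 0) rnorm(n_max, 0, jitter_sd) else numeric(n_max)
    t <- numeric(n_max)
    rr <- numeric(n_max)
    onsets <- events$onset
    ends <- events$onset + events$duration
    durs <- events$duration
    types <- events$type
    n_ev <- length(onsets)
    tk <- 0
    k <- 0L
    while (tk < duration) {
      k <- k + 1L
      m <- 1 +
        0.035 * sin(2 * pi * f_resp * tk + phi[1]) +
        0.025 * sin(2 * pi * 0.095 * tk + phi[2]) +
        0.020 * sin(2 * pi * 0.010 * tk + phi[3])
      if (n_ev > 0L) {
        i <- findInterval(tk, onsets)
        if (i >= 1L) {
          a <- 0.12 + 0.10 * min(durs[i] / 30, 1)
          if (tk < ends[i]) {
            u <- (tk - onsets[i]) / durs[i]
            m <- m + a * sin(pi * u)
          } else if (tk - ends[i] <= 15) {
            m <- m - 0.6 * a * (1 - (tk - ends[i]) / 15)
          }
        }
      }
      rrk <- base_rr * m * (1 + jitter[k])
      rrk <- min(max(rrk, 340), 1990)
      t[k] <- tk
      rr[k] <- rrk
      tk <- tk + rrk / 1000
    }
    out <- data.frame(t = t[seq_len(k)], rr = rr[seq_len(k)])
    out$rr[k] <- NA_real_
    out
  })
}

# PQRST template as a sum of Gaussian deflections (ECGSYN-style), sampled
# at fs over [-0.28, 0.45] s around the R peak. Amplitudes in mV.
pqrst_template <- function(fs) {
  tt <- seq(-0.28, 0.45, by = 1 / fs)
  centers <- c(P = -0.20, Q = -0.030, R = 0, S = 0.035, T = 0.22)
  amps <- c(P = 0.12, Q = -0.12, R = 1.0, S = -0.25, T = 0.30)
  widths <- c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.055)
  y <- numeric(length(tt))
  for (i in seq_along(centers)) {
    y <- y + amps[i] * exp(-((tt - centers[i])^2) / (2 * widths[i]^2))
  }
  list(t = tt, y = y, r_index = which.min(abs(tt)))
}

#' Construct a signal record
#'
#' Container for one subject-night's raw waveform. Use this to wrap
#' externally acquired signals for the quality pipelines.
#'
#' @param channel `"ecg"` or `"excursion"`.
#' @param device `"belt"` or `"psg"`.
#' @param fs Sampling rate in Hz (> 0).
#' @param samples Numeric sample vector (finite).
#' @param t0 Start time offset in seconds.
#' @param meta Optional metadata list.
#' @return Object of class `signal_record`.
#' @export
signal_record <- function(channel, device, fs, samples, t0 = 0,
                          meta = list()) {
  channel <- match.arg(channel, c("ecg", "excursion"))
  device <- match.arg(device, c("belt", "psg"))
  if (!is.numeric(fs) || fs <= 0) stop_invalid("'fs' must be > 0")
  if (!all(is.finite(samples))) stop_invalid("'samples' must be finite")
  new_signal_record(channel, device, fs, as.numeric(samples), t0, meta)
}

new_signal_record <- function(channel, device, fs, samples, t0 = 0,
                              meta = list()) {
  structure(list(channel = channel, device = device, fs = fs, t0 = t0,
                 samples = samples, meta = meta),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %s/%s, fs %g Hz, %.1f min (%d samples)\n",
              x$channel, x$device, x$fs, length(x$samples) / x$fs / 60,
              length(x$samples)))
  invisible(x)
}

#' Synthesize a whole-night ECG record
#'
#' Renders the RR track of [synthesize_rr_track()] into a sampled ECG
#' waveform by placing a PQRST complex (sum-of-Gaussians template) at each
#' beat, with beat-to-beat amplitude jitter, baseline wander and additive
#' white noise scaled by the spec's `noise_level`. Ground-truth R-peak
#' times are attached for downstream validation.
#'
#' @inheritParams synthesize_rr_track
#' @param fs Sampling rate in Hz (>= 125; template morphology is
#'   undersampled below that).
#' @param rr_track Optional precomputed track (shared between devices so
#'   belt and PSG records carry identical physiology); when `NULL` it is
#'   generated from `spec` and `events`.
#' @return A `signal_record` (channel `"ecg"`) whose `meta` holds
#'   `r_times` (s), `rr_ms` and the event table.
#' @export
synthesize_ecg <- function(spec, events, fs = 125, duration = 7 * 3600,
                           rng_seed = spec$seed, device = "belt",
                           rr_track = NULL) {
  stopifnot(inherits(spec, "subject_spec"))
  if (fs < 125)
    stop_invalid("'fs' must be >= 125 Hz for ECG (template undersampled)")
  if (is.null(rr_track))
    rr_track <- synthesize_rr_track(spec, events, duration, rng_seed)
  with_seed(derive_seed(rng_seed, 211L + (device == "psg")), {
    n <- ceiling(duration * fs)
    x <- numeric(n)
    tpl <- pqrst_template(fs)
    off <- seq_along(tpl$y) - tpl$r_index
    nb <- nrow(rr_track)
    amp <- 1 + 0.03 * spec$noise_level * rnorm(nb)
    ridx <- round(rr_track$t * fs) + 1L
    for (k in seq_len(nb)) {
      idx <- ridx[k] + off
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + amp[k] * tpl$y[ok]
    }
    if (spec$noise_level > 0) {
      ts <- seq_len(n) / fs
      wander <- 0.05 * spec$noise_level *
        sin(2 * pi * 0.25 * ts + runif(1, 0, 2 * pi))
      x <- x + wander + rnorm(n, 0, 0.015 * spec$noise_level)
    }
    new_signal_record("ecg", device, fs, x,
                      meta = list(subject_id = spec$subject_id,
                                  r_times = rr_track$t,
                                  rr_ms = rr_track$rr,
                                  events = events))
  })
}

#' Ground-truth breathing-cycle track for one night
#'
#' Generates per-cycle onset times, durations, inhale-phase durations and
#' amplitudes. Breathing slows and shallows during apnea events
#' (obstructive: amplitude cut to 15%; central: to 2%) and rebounds with
#' faster, deeper breaths over the 15 s after each event. Instantaneous
#' rates outside events stay within the 5--50 breaths/min plausibility
#' band by construction.
#'
#' @inheritParams synthesize_rr_track
#' @return A data.frame with columns `onset` (s), `duration` (s),
#'   `inhale` (s), `amplitude` (relative units).
#' @export
synthesize_breath_track <- function(spec, events, duration,
                                    rng_seed = spec$seed) {
  stopifnot(inherits(spec, "subject_spec"), duration > 0)
  with_seed(derive_seed(rng_seed, 301L), {
    base_ivl <- 60 / spec$base_bf
    phi <- runif(2, 0, 2 * pi)
    n_max <- ceiling(duration / 1.2) + 2L
    jit_sd <- 0.02 * spec$noise_level
    jit <- if (jit_sd > 0) rnorm(n_max, 0, jit_sd) else numeric(n_max)
    inh_jit <- if (jit_sd > 0) rnorm(n_max, 0, 0.01 * spec$noise_level)
      else numeric(n_max)
    onset <- numeric(n_max); dur <- numeric(n_max)
    inhale <- numeric(n_max); amp <- numeric(n_max)
    tk <- 0; k <- 0L
    while (tk < duration) {
      k <- k + 1L
      mod <- apnea_modulation(tk, events)
      m <- (1 + 0.05 * sin(2 * pi * 0.01 * tk + phi[1])) * mod$br_mult
      d <- base_ivl * m * (1 + jit[k])
      d <- min(max(d, 60 / 50 * 1.05), 60 / 5 * 0.95)
      a <- (1 + 0.10 * sin(2 * pi * 0.004 * tk + phi[2])) * mod$amp_mult
      rho <- min(max(0.38 + inh_jit[k], 0.25), 0.55)
      onset[k] <- tk; dur[k] <- d; inhale[k] <- rho * d; amp[k] <- a
      tk <- tk + d
    }
    keep <- seq_len(k)
    data.frame(onset = onset[keep], duration = dur[keep],
               inhale = inhale[keep], amplitude = amp[keep])
  })
}

#' Synthesize a whole-night thoracic-excursion record
#'
#' Renders the breathing track as a quasi-sinusoidal excursion waveform
#' with distinct inhale and exhale phase durations: each cycle runs
#' trough-to-trough with its peak at the end of the inhale phase, so both
#' onset (trough) and inhale duration are recoverable by peak detection.
#'
#' @inheritParams synthesize_ecg
#' @param fs Sampling rate in Hz (>= 10).
#' @param breath_track Optional precomputed track (shared across devices).
#' @return A `signal_record` (channel `"excursion"`) whose `meta` holds
#'   `onset_times`, `inhale_s`, `amplitude` and the event table.
#' @export
synthesize_excursion <- function(spec, events, fs = 10, duration = 7 * 3600,
                                 rng_seed = spec$seed, device = "belt",
                                 breath_track = NULL) {
  stopifnot(inherits(spec, "subject_spec"))
  if (fs < 10) stop_invalid("'fs' must be >= 10 Hz for excursion signals")
  if (is.null(breath_track))
    breath_track <- synthesize_breath_track(spec, events, duration, rng_seed)
  with_seed(derive_seed(rng_seed, 401L + (device == "psg")), {
    n <- ceiling(duration * fs)
    x <- numeric(n)
    bt <- breath_track
    for (k in seq_len(nrow(bt))) {
      i0 <- floor(bt$onset[k] * fs) + 1L
      i1 <- min(floor((bt$onset[k] + bt$duration[k]) * fs), n)
      if (i0 > n || i1 < i0) next
      ts <- (seq(i0, i1) - 1) / fs - bt$onset[k]
      rho <- bt$inhale[k] / bt$duration[k]
      u <- ts / bt$duration[k]
      phase <- ifelse(u < rho, 0.5 * u / rho, 0.5 + 0.5 * (u - rho) / (1 - rho))
      x[i0:i1] <- bt$amplitude[k] * (1 - cos(2 * pi * phase)) / 2
    }
    if (spec$noise_level > 0) {
      ts <- seq_len(n) / fs
      x <- x + 0.04 * spec$noise_level *
        sin(2 * pi * 0.002 * ts + runif(1, 0, 2 * pi)) +
        rnorm(n, 0, 0.02 * spec$noise_level)
    }
    new_signal_record("excursion", device, fs, x,
                      meta = list(subject_id = spec$subject_id,
                                  onset_times = bt$onset,
                                  inhale_s = bt$inhale,
                                  amplitude = bt$amplitude,
                                  events = events))
  })
}

#' Inject artifact episodes into a signal record
#'
#' Replaces approximately `fraction_bad` of the record with contiguous
#' blocks of high-amplitude noise plus baseline wander. Block lengths are
#' geometric (mean 30 s), matching how real belt artifacts occur as
#' sustained poor-quality stretches rather than isolated samples.
#'
#' @param rec A `signal_record`.
#' @param fraction_bad Proportion of the record to corrupt, in \[0, 1\].
#' @param rng_seed Integer seed.
#' @return The corrupted `signal_record`; `meta$artifact_mask` is a logical
#'   vector marking corrupted samples.
#' @export
inject_artifacts <- function(rec, fraction_bad, rng_seed = 1L) {
  stopifnot(inherits(rec, "signal_record"))
  if (!is.numeric(fraction_bad) || fraction_bad < 0 || fraction_bad > 1)
    stop_invalid("'fraction_bad' must lie in [0, 1]")
  if (fraction_bad == 0) return(rec)
  with_seed(derive_seed(rng_seed, 501L), {
    n <- length(rec$samples)
    fs <- rec$fs
    mask <- logical(n)
    target <- fraction_bad * n
    mean_block <- max(round(30 * fs), 2L)
    guard <- 0L
    while (sum(mask) < target && guard < 10000L) {
      guard <- guard + 1L
      len <- min(n, rgeom_block(mean_block))
      start <- sample.int(max(n - len + 1L, 1L), 1L)
      mask[start:(start + len - 1L)] <- TRUE
    }
    # trim overshoot so the corrupted share tracks fraction_bad closely
    over <- sum(mask) - round(target)
    if (over > 0) {
      idx <- which(mask)
      mask[idx[seq_len(over)]] <- FALSE
    }
    scale <- stats::sd(rec$samples)
    if (!is.finite(scale) || scale == 0) scale <- 1
    nb <- sum(mask)
    if (nb > 0) {
      ts <- which(mask) / fs
      rec$samples[mask] <- 4 * scale * rnorm(nb) +
        2 * scale * sin(2 * pi * 0.8 * ts + runif(1, 0, 2 * pi))
    }
    rec$meta$artifact_mask <- mask
    rec
  })
}

# geometric block length with given mean (in samples), floor 1 sample
rgeom_block <- function(mean_len) {
  1L + stats::rgeom(1L, prob = 1 / mean_len)
}

#' Sample apnea-hypopnea indices for a virtual cohort
#'
#' Log-normal severity distribution calibrated to a referred sleep-clinic
#' population with median AHI 33 events/h and inter-quartile range 16--58.
#'
#' @param n Number of subjects.
#' @param median_ahi Target median (default 33 events/h).
#' @param iqr Target lower/upper quartiles (default `c(16, 58)`).
#' @param rng_seed Integer seed.
#' @return Numeric vector of AHI values (events/h).
#' @export
sample_ahi <- function(n, median_ahi = 33, iqr = c(16, 58), rng_seed = 1L) {
  stopifnot(n >= 1, median_ahi > 0, length(iqr) == 2L, iqr[1] < iqr[2])
  meanlog <- log(median_ahi)
  sdlog <- log(iqr[2] / iqr[1]) / (2 * qnorm(0.75))
  with_seed(derive_seed(rng_seed, 601L), {
    pmin(rlnorm(n, meanlog, sdlog), 150)
  })
}

#' Generate a paired belt/PSG cohort
#'
#' For each virtual subject and night, one shared event schedule and one
#' shared RR/breathing ground truth are rendered into four signal records:
#' ECG and excursion, each from the belt and from the PSG. Belt records
#' receive device noise at the subject's `noise_level` (plus optional
#' artifact episodes on the belt ECG); PSG records are cleaner
#' (noise x `psg_noise_factor`) but share the identical physiology, so
#' device agreement and classification have a known ground truth.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param n_nights Nights per subject.
#' @param night_duration Night length in seconds (default 7 h).
#' @param ahi Optional vector of AHI values (length `n_subjects`); when
#'   `NULL`, drawn by [sample_ahi()].
#' @param fs_ecg,fs_excursion Sampling rates (Hz).
#' @param noise_level Belt noise multiplier.
#' @param psg_noise_factor PSG noise relative to the belt (default 0.3).
#' @param artifact_fraction Fraction of each belt ECG record corrupted by
#'   [inject_artifacts()] (default 0).
#' @param rng_seed Integer master seed.
#' @inheritParams sample_ahi
#' @return A `sleepbelt_cohort`: list with `subjects` (list of
#'   [subject_spec()]), `records` (list of `signal_record`s), and
#'   `metadata` (data.frame: subject_id, night, ahi, seed).
#' @export
generate_cohort <- function(n_subjects, n_nights = 1L,
                            night_duration = 7 * 3600, ahi = NULL,
                            median_ahi = 33, iqr = c(16, 58),
                            fs_ecg = 125, fs_excursion = 10,
                            noise_level = 1, psg_noise_factor = 0.3,
                            artifact_fraction = 0, rng_seed = 1L) {
  if (n_subjects < 1) stop_invalid("'n_subjects' must be >= 1")
  if (is.null(ahi)) {
    ahi <- sample_ahi(n_subjects, median_ahi, iqr, rng_seed)
  }
  stopifnot(length(ahi) == n_subjects)
  subjects <- vector("list", n_subjects)
  records <- list()
  meta <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", s)
    sseed <- derive_seed(rng_seed, 1000L + s)
    spec <- subject_spec(sid, ahi[s], n_nights = n_nights,
                         noise_level = noise_level, seed = sseed)
    # per-subject random effects: stable physiology across nights
    spec <- with_seed(derive_seed(sseed, 7L), {
      spec$base_hr <- min(max(60 + rnorm(1, 0, 4), 45), 90)
      spec$base_bf <- min(max(14 + rnorm(1, 0, 1.2), 10), 20)
      spec
    })
    subjects[[s]] <- spec
    for (nt in seq_len(n_nights)) {
      nseed <- derive_seed(sseed, 50L + nt)
      events <- schedule_apneas(spec, night_duration, rng_seed = nseed)
      rr_tr <- synthesize_rr_track(spec, events, night_duration, nseed)
      br_tr <- synthesize_breath_track(spec, events, night_duration, nseed)
      psg_spec <- spec
      psg_spec$noise_level <- spec$noise_level * psg_noise_factor
      for (dev in c("belt", "psg")) {
        dspec <- if (dev == "belt") spec else psg_spec
        ecg <- synthesize_ecg(dspec, events, fs = fs_ecg,
                              duration = night_duration,
                              rng_seed = derive_seed(nseed, 2L + (dev == "psg")),
                              device = dev, rr_track = rr_tr)
        if (dev == "belt" && artifact_fraction > 0) {
          ecg <- inject_artifacts(ecg, artifact_fraction,
                                  rng_seed = derive_seed(nseed, 9L))
        }
        exc <- synthesize_excursion(dspec, events, fs = fs_excursion,
                                    duration = night_duration,
                                    rng_seed = derive_seed(nseed, 4L + (dev == "psg")),
                                    device = dev, breath_track = br_tr)
        for (rec in list(ecg, exc)) {
          rec$meta$night <- nt
          rec$meta$ahi <- spec$ahi
          records[[length(records) + 1L]] <- rec
        }
      }
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = sid, night = nt, ahi = spec$ahi, seed = nseed)
    }
  }
  structure(list(subjects = subjects, records = records,
                 metadata = do.call(rbind, meta)),
            class = "sleepbelt_cohort")
}

#' @export
print.sleepbelt_cohort <- function(x, ...) {
  cat(sprintf("<sleepbelt_cohort> %d subject(s), %d record(s)\n",
              length(x$subjects), length(x$records)))
  invisible(x)
}
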