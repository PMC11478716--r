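# End-to-end orchestration: simulate -> quality filter -> features ->
# agreement / classification / repeatability, from a single config with
# one root seed, writing deterministic CSV/JSON artifacts.

#' Pipeline run configuration
#'
#' All tunable constants of the analysis in one validated list. The
#' defaults are the printed constants of the quality and variability
#' algorithms: 15-s ECG segments with r > 0.98, RR plausibility
#' 333--2000 ms with 33% maximal deviation from the segment median, 32-s
#' breathing segments with r >= 0.75, the 5--50 breaths/min band, 300-s
#' spectral windows with band edges 0.003/0.03/0.15/0.4 Hz, the 50-ms
#' successive-difference threshold, and the cohort-median AHI cut-off.
#'
#' @param n_subjects,n_nights Cohort size.
#' @param night_duration Night length in seconds.
#' @param fs_ecg,fs_excursion Sampling rates (Hz).
#' @param noise_level,artifact_fraction Belt noise and artifact burden.
#' @param median_ahi,ahi_iqr AHI distribution of the virtual cohort.
#' @param ecg_segment_s,ecg_r_threshold,rr_min,rr_max,max_dev ECG quality
#'   constants.
#' @param breath_segment_s,breath_r_threshold,min_bpm,max_bpm Breathing
#'   quality constants.
#' @param window_s,resample_hz,band_edges Spectral constants.
#' @param pnn_threshold_ms Successive-difference threshold (ms).
#' @param label_quantile AHI dichotomization quantile.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "features", "agreement", "classification",
#'   "repeatability")`.
#' @param seed Root seed; every stage derives its seeds from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 12L, n_nights = 1L,
                       night_duration = 2400, fs_ecg = 125,
                       fs_excursion = 10, noise_level = 1,
                       artifact_fraction = 0.05, median_ahi = 33,
                       ahi_iqr = c(16, 58),
                       ecg_segment_s = 15, ecg_r_threshold = 0.98,
                       rr_min = 333, rr_max = 2000, max_dev = 0.33,
                       breath_segment_s = 32, breath_r_threshold = 0.75,
                       min_bpm = 5, max_bpm = 50,
                       window_s = 300, resample_hz = 4,
                       band_edges = c(0.003, 0.03, 0.15, 0.4),
                       pnn_threshold_ms = 50, label_quantile = 0.5,
                       stages = c("simulate", "features", "agreement",
                                  "classification"),
                       seed = 1L) {
  cfg <- as.list(environment())
  known <- c("simulate", "features", "agreement", "classification",
             "repeatability")
  if (!all(stages %in% known))
    stop_invalid("unknown stage(s): %s",
                 paste(setdiff(stages, known), collapse = ", "))
  stopifnot(night_duration > 0, length(band_edges) == 4L,
            !is.unsorted(band_edges))
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' Round-trips exactly: `read_run_config(write_run_config(cfg, f))`
#' reproduces the effective parameters.
#'
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

config_hash <- function(cfg) {
  fnv1a_hash(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}

spectral_config_from <- function(cfg) {
  e <- cfg$band_edges
  spectral_config(window_s = cfg$window_s, resample_hz = cfg$resample_hz,
                  bands = list(ulf = c(0, e[1]), vlf = c(e[1], e[2]),
                               lf = c(e[2], e[3]), hf = c(e[3], e[4])))
}

# Quality-filter one subject-night-device pair of records and compute the
# 22-feature row plus quality and rate summaries. Returns NULL components
# when a channel is unusable.
process_night <- function(ecg_rec, exc_rec, cfg) {
  scfg <- spectral_config_from(cfg)
  out <- list()
  peaks <- detect_r_peaks(ecg_rec)
  hrv <- NULL; rr_flt <- NULL; qs <- NULL
  if (length(peaks$times) >= 10L) {
    qs <- segment_template_quality(ecg_rec, peaks,
                                   segment_s = cfg$ecg_segment_s,
                                   r_threshold = cfg$ecg_r_threshold,
                                   rr_min = cfg$rr_min, rr_max = cfg$rr_max,
                                   max_dev = cfg$max_dev)
    rr_flt <- suppressWarnings(filtered_rr(peaks, qs))
    if (nrow(rr_flt) >= 10L) {
      hrv <- tryCatch(
        whole_night_features(rr_flt, scfg, channel = "hrv",
                             diff_threshold = cfg$pnn_threshold_ms),
        error = function(e) NULL)
    }
  }
  breaths <- detect_breaths(exc_rec, min_cycle_s = 60 / cfg$max_bpm)
  brv <- NULL; bb_flt <- NULL; bqs <- NULL
  if (length(breaths$onset_times) >= 5L) {
    bqs <- breath_template_quality(exc_rec, breaths,
                                   segment_s = cfg$breath_segment_s,
                                   r_threshold = cfg$breath_r_threshold)
    bb_flt <- suppressWarnings(filtered_bb(breaths, bqs,
                                           min_bpm = cfg$min_bpm,
                                           max_bpm = cfg$max_bpm))
    if (nrow(bb_flt) >= 10L) {
      brv <- tryCatch(whole_night_features(bb_flt, scfg, channel = "brv"),
                      error = function(e) NULL)
    }
  }
  list(hrv = hrv, brv = brv, rr = rr_flt, bb = bb_flt,
       ecg_quality = if (!is.null(qs)) quality_summary(qs),
       breath_quality = if (!is.null(bqs))
         list(fraction_accepted = mean(bqs$verdict == "accepted")),
       mean_hr = if (!is.null(rr_flt) && nrow(rr_flt) >= 2L)
         whole_night_mean_rate(rr_flt),
       mean_br = if (!is.null(bb_flt) && nrow(bb_flt) >= 2L)
         whole_night_mean_rate(bb_flt))
}

#' Run the full analysis pipeline
#'
#' Simulates the virtual cohort, runs both device pipelines per
#' subject-night, aggregates features, and performs the enabled
#' downstream analyses. All artifacts are plain CSV/JSON and the run is
#' bit-identical given the same config (a manifest with the config hash
#' is written alongside).
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`features`,
#'   `agreement`, `classification`, `repeatability`, `manifest`).
#' @export
run_all <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  log_stage <- function(fmt, ...) {
    message(sprintf("[sleepbelt %+.1fs] %s",
                    as.numeric(difftime(Sys.time(), t_start, units = "secs")),
                    sprintf(fmt, ...)))
  }
  if (!"simulate" %in% cfg$stages)
    stop_invalid("stage 'simulate' is required: downstream stages depend ",
                 "on simulated signals")
  log_stage("simulate: %d subject(s) x %d night(s), %.0f s nights",
            cfg$n_subjects, cfg$n_nights, cfg$night_duration)
  cohort <- generate_cohort(cfg$n_subjects, n_nights = cfg$n_nights,
                            night_duration = cfg$night_duration,
                            median_ahi = cfg$median_ahi, iqr = cfg$ahi_iqr,
                            fs_ecg = cfg$fs_ecg,
                            fs_excursion = cfg$fs_excursion,
                            noise_level = cfg$noise_level,
                            artifact_fraction = cfg$artifact_fraction,
                            rng_seed = cfg$seed)
  write_cohort_metadata(cohort, file.path(out_dir, "cohort_metadata.csv"))
  res <- list(manifest = list(package = "sleepbelt",
                              version = as.character(
                                utils::packageVersion("sleepbelt")),
                              seed = cfg$seed,
                              config_hash = config_hash(cfg),
                              stages = cfg$stages))
  if (!"features" %in% cfg$stages) {
    needs <- intersect(c("agreement", "classification", "repeatability"),
                       cfg$stages)
    if (length(needs))
      stop_invalid("stage(s) %s require the 'features' stage",
                   paste(needs, collapse = ", "))
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  log_stage("features: quality filtering + HRV/BRV extraction")
  recs <- cohort$records
  key <- vapply(recs, function(r)
    paste(r$meta$subject_id, r$meta$night, r$device, sep = "|"), character(1))
  chan <- vapply(recs, function(r) r$channel, character(1))
  feat_rows <- list(); rate_rows <- list(); qual_rows <- list()
  for (k in unique(key)) {
    ecg_rec <- recs[[which(key == k & chan == "ecg")[1L]]]
    exc_rec <- recs[[which(key == k & chan == "excursion")[1L]]]
    pn <- process_night(ecg_rec, exc_rec, cfg)
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    base <- data.frame(subject_id = parts[1L],
                       night = as.integer(parts[2L]), device = parts[3L],
                       ahi = ecg_rec$meta$ahi)
    if (!is.null(pn$hrv) && !is.null(pn$brv)) {
      feat_rows[[length(feat_rows) + 1L]] <-
        cbind(base, as.data.frame(pn$hrv), as.data.frame(pn$brv))
    }
    rate_rows[[length(rate_rows) + 1L]] <-
      cbind(base, data.frame(mean_hr = pn$mean_hr %||% NA_real_,
                             mean_br = pn$mean_br %||% NA_real_))
    qual_rows[[length(qual_rows) + 1L]] <-
      cbind(base, data.frame(
        ecg_r_mean = pn$ecg_quality$r_mean %||% NA_real_,
        ecg_r_sd = pn$ecg_quality$r_sd %||% NA_real_,
        ecg_fraction_accepted =
          pn$ecg_quality$fraction_accepted %||% NA_real_,
        breath_fraction_accepted =
          pn$breath_quality$fraction_accepted %||% NA_real_))
  }
  features <- do.call(rbind, feat_rows)
  rates <- do.call(rbind, rate_rows)
  quality <- do.call(rbind, qual_rows)
  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(rates, file.path(out_dir, "rates.csv"), row.names = FALSE)
  write.csv(quality, file.path(out_dir, "quality.csv"), row.names = FALSE)
  res$features <- features
  if ("agreement" %in% cfg$stages) {
    log_stage("agreement: Bland-Altman belt vs PSG")
    agr <- list()
    for (ch in c("hr", "br")) {
      col <- paste0("mean_", ch)
      w <- rates[rates$night == 1L, c("subject_id", "device", col)]
      wide <- merge(w[w$device == "belt", c("subject_id", col)],
                    w[w$device == "psg", c("subject_id", col)],
                    by = "subject_id", suffixes = c("_belt", "_psg"))
      ba <- tryCatch(bland_altman(wide[[paste0(col, "_belt")]],
                                  wide[[paste0(col, "_psg")]]),
                     error = function(e) NULL)
      if (!is.null(ba))
        agr[[ch]] <- list(bias = ba$bias, bias_ci = ba$bias_ci,
                          loa_lower = ba$loa_lower,
                          loa_upper = ba$loa_upper, n = ba$n)
    }
    jsonlite::write_json(agr, file.path(out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA)
    res$agreement <- agr
  }
  if ("classification" %in% cfg$stages) {
    log_stage("classification: SVM + LOOCV per feature set")
    cls <- list()
    for (dev in unique(features$device)) {
      tab <- features[features$device == dev & features$night == 1L, ]
      for (fset in c("ecg", "bf", "combined")) {
        r <- tryCatch(
          classify_severity(tab, fset, quantile = cfg$label_quantile),
          error = function(e) NULL)
        if (is.null(r)) next
        cls[[paste(dev, fset, sep = "_")]] <-
          list(device = dev, feature_set = fset, auc = r$auc,
               auc_ci = r$auc_ci, sensitivity = r$sensitivity,
               specificity = r$specificity,
               confusion = as.list(r$confusion), n = r$n)
        write.csv(r$roc_points,
                  file.path(out_dir,
                            sprintf("roc_%s_%s.csv", dev, fset)),
                  row.names = FALSE)
      }
    }
    jsonlite::write_json(cls, file.path(out_dir, "classification.json"),
                         auto_unbox = TRUE, digits = NA)
    res$classification <- cls
  }
  if ("repeatability" %in% cfg$stages) {
    if (cfg$n_nights < 2L)
      stop_invalid("stage 'repeatability' requires n_nights >= 2")
    log_stage("repeatability: random-intercept models per feature")
    belt <- features[features$device == "belt", ]
    rows <- list()
    for (ch in c("hrv", "brv")) {
      for (f in feature_names) {
        col <- paste(ch, f, sep = "_")
        r <- tryCatch(
          repeatability(belt[[col]], belt$subject_id, nboot = 0L),
          error = function(e) NULL)
        if (!is.null(r))
          rows[[length(rows) + 1L]] <-
            data.frame(feature = f, channel = ch, r_pt = r$r_pt)
      }
    }
    rep_df <- do.call(rbind, rows)
    write.csv(rep_df, file.path(out_dir, "repeatability.csv"),
              row.names = FALSE)
    summ <- summarize_repeatability(rep_df)
    jsonlite::write_json(summ, file.path(out_dir,
                                         "repeatability_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    res$repeatability <- list(per_feature = rep_df, summary = summ)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("done")
  invisible(res)
}
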