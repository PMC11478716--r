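# Plain-text signal exchange: two-column CSV (time_s, value) with a JSON
# sidecar carrying channel/device/fs metadata, and cohort metadata CSV.

#' Write a signal record to CSV + JSON sidecar
#'
#' @param rec A `signal_record`.
#' @param path Output path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @return The CSV path, invisibly.
#' @export
write_signal_record <- function(rec, path) {
  stopifnot(inherits(rec, "signal_record"))
  ts <- rec$t0 + (seq_along(rec$samples) - 1L) / rec$fs
  csv <- paste0(path, ".csv")
  write.csv(data.frame(time_s = ts, value = rec$samples), csv,
            row.names = FALSE)
  side <- list(channel = rec$channel, device = rec$device, fs = rec$fs,
               t0 = rec$t0,
               subject_id = rec$meta$subject_id %||% NA,
               night = rec$meta$night %||% NA)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(csv)
}

#' Read a signal record written by [write_signal_record()]
#'
#' @param path Path without extension.
#' @return A `signal_record`.
#' @export
read_signal_record <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(paste0(path, ".csv"))
  rec <- new_signal_record(side$channel, side$device, side$fs, df$value,
                           t0 = side$t0 %||% 0)
  rec$meta$subject_id <- side$subject_id
  rec$meta$night <- side$night
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write cohort metadata CSV
#'
#' @param cohort A `sleepbelt_cohort`.
#' @param path CSV path.
#' @export
write_cohort_metadata <- function(cohort, path) {
  stopifnot(inherits(cohort, "sleepbelt_cohort"))
  write.csv(cohort$metadata, path, row.names = FALSE)
  invisible(path)
}
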