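#' Write / read a raw recording as long-format CSV
#'
#' Plain-text interchange format: one row per (time, channel, wavelength)
#' with columns `time_s, channel, wavelength_nm, intensity`. Subject
#' metadata travels in a JSON sidecar written next to the CSV.
#'
#' @param recording A `raw_recording`.
#' @param path Output CSV path (sidecar gets extension `.json`).
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  n <- dim(recording$intensity)[1]
  nch <- dim(recording$intensity)[2]
  t_s <- (seq_len(n) - 1) / recording$fs
  df <- data.frame(
    time_s = rep(t_s, times = nch * 2),
    channel = rep(rep(seq_len(nch), each = n), times = 2),
    wavelength_nm = rep(recording$wavelengths_nm, each = n * nch),
    intensity = c(recording$intensity)
  )
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(subject = recording$subject, age = recording$age,
               group = recording$group, fs = recording$fs,
               wavelengths_nm = recording$wavelengths_nm,
               total_duration_s = recording$schedule$total_duration_s)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param events_path Path of the events TSV matching the recording.
#' @return A `raw_recording` (without latent ground truth).
#' @export
read_recording_csv <- function(path, events_path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  schedule <- read_events_tsv(events_path, meta$total_duration_s)
  nch <- max(df$channel)
  wl <- sort(unique(df$wavelength_nm))
  n <- sum(df$channel == 1 & df$wavelength_nm == wl[1])
  intensity <- array(NA_real_, c(n, nch, 2))
  for (w in 1:2) {
    for (ch in seq_len(nch)) {
      sel <- df$channel == ch & df$wavelength_nm == wl[w]
      intensity[, ch, w] <- df$intensity[sel][order(df$time_s[sel])]
    }
  }
  structure(list(subject = meta$subject, age = meta$age, group = meta$group,
                 fs = meta$fs, wavelengths_nm = wl, intensity = intensity,
                 schedule = schedule, latent = NULL),
            class = "raw_recording")
}

#' Write / read an event schedule as BIDS-style events TSV
#'
#' Tab-separated with header `onset`, `duration`, `trial_type`.
#'
#' @param schedule An `event_schedule`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  df <- data.frame(onset = schedule$events$onset_s,
                   duration = schedule$events$duration_s,
                   trial_type = schedule$events$condition)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param total_duration_s Recording length (not stored in the TSV).
#' @return An `event_schedule`.
#' @export
read_events_tsv <- function(path, total_duration_s) {
  df <- utils::read.delim(path)
  structure(list(
    events = data.frame(onset_s = df$onset, duration_s = df$duration,
                        condition = df$trial_type,
                        stringsAsFactors = FALSE),
    total_duration_s = total_duration_s
  ), class = "event_schedule")
}

#' Write ground truth as JSON
#'
#' @param truth A `ground_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    group = truth$group, age = truth$age,
    amplitude = truth$amplitude, latency = truth$latency,
    width = truth$width, artifact_trials = truth$artifact_trials
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Write preprocessed hemoglobin signals as wide CSV
#'
#' Columns `time_s, ch01_HbO, ch01_HbR, ..., ch16_HbR` (uM), with a JSON
#' provenance sidecar recording the preprocessing settings.
#'
#' @param hemo A `hemo_signals`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hemo_csv <- function(hemo, path) {
  n <- nrow(hemo$HbO)
  nch <- ncol(hemo$HbO)
  out <- data.frame(time_s = (seq_len(n) - 1) / hemo$fs)
  for (ch in seq_len(nch)) {
    out[[sprintf("ch%02d_HbO", ch)]] <- hemo$HbO[, ch]
    out[[sprintf("ch%02d_HbR", ch)]] <- hemo$HbR[, ch]
  }
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(c(list(subject = hemo$subject, group = hemo$group,
                              fs = hemo$fs), hemo$provenance),
                       sub("\\.csv$", "_provenance.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hemo_csv
#' @param events_path Events TSV path (the schedule is not stored in the
#'   wide CSV).
#' @return A `hemo_signals`.
#' @export
read_hemo_csv <- function(path, events_path) {
  df <- utils::read.csv(path)
  prov <- jsonlite::read_json(sub("\\.csv$", "_provenance.json", path),
                              simplifyVector = TRUE)
  nch <- sum(grepl("_HbO$", names(df)))
  HbO <- as.matrix(df[sprintf("ch%02d_HbO", seq_len(nch))])
  HbR <- as.matrix(df[sprintf("ch%02d_HbR", seq_len(nch))])
  colnames(HbO) <- colnames(HbR) <- channel_names()[seq_len(nch)]
  total_s <- nrow(df) / prov$fs
  structure(list(subject = prov$subject, group = prov$group,
                 age = NA_real_, fs = prov$fs, HbO = HbO, HbR = HbR,
                 schedule = read_events_tsv(events_path, total_s),
                 provenance = prov),
            class = "hemo_signals")
}

#' Write the temporal feature table as CSV
#'
#' One row per subject: `subject`, `group`, then the expanded feature
#' columns.
#'
#' @param ft A [feature_table()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(ft, path) {
  df <- cbind(data.frame(subject = ft$subjects,
                         group = ifelse(ft$labels == 1, "tbi", "healthy")),
              ft$temporal)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the spatio-temporal feature matrix as long CSV
#'
#' Columns `subject, group, channel, feature, value` (empty value for
#' pruned channels).
#'
#' @inheritParams write_feature_csv
#' @export
write_spatiotemporal_csv <- function(ft, path) {
  st <- ft$spatiotemporal
  parts <- strsplit(colnames(st), ".", fixed = TRUE)
  long <- data.frame(
    subject = rep(ft$subjects, times = ncol(st)),
    group = rep(ifelse(ft$labels == 1, "tbi", "healthy"),
                times = ncol(st)),
    channel = rep(vapply(parts, `[[`, "", 1), each = nrow(st)),
    feature = rep(vapply(parts, `[[`, "", 2), each = nrow(st)),
    value = c(st)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
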