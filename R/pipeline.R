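#' Preprocess every recording of a cohort
#'
#' @param cohort A [generate_cohort()] result (or list with `recordings`).
#' @param ... Passed to [preprocess_recording()].
#' @return List of `hemo_signals`, one per subject.
#' @export
preprocess_cohort <- function(cohort, ...) {
  lapply(cohort$recordings, preprocess_recording, ...)
}

#' Build temporal and spatio-temporal feature tables for a cohort
#'
#' Runs trial extraction, the three-criterion screen, channel/subject
#' pruning and feature extraction on every subject, then assembles the
#' channel-averaged (temporal) feature table and the per-channel
#' (spatio-temporal) matrix with NA entries for dropped channels.
#' Subjects with no retained channel are excluded from both tables.
#'
#' @param hemo_list List of `hemo_signals` (one per subject).
#' @param condition Condition(s) to analyse (default High complexity).
#' @param reject Apply the trial screen (FALSE = no-rejection control).
#' @param reject_threshold Channel pruning threshold (default 0.80).
#' @param n_coeff HDFT dimensionality.
#' @return List with `temporal` (data.frame, one row per retained subject),
#'   `spatiotemporal` (subjects x (16 * columns) matrix), `labels`
#'   (0 = healthy, 1 = TBI), `subjects`, `channel_retained` matrix and
#'   `n_excluded`.
#' @export
feature_table <- function(hemo_list, condition = "HighComplexity",
                          reject = TRUE, reject_threshold = 0.80,
                          n_coeff = 3) {
  per_subj <- lapply(hemo_list, subject_features, condition = condition,
                     reject = reject, reject_threshold = reject_threshold,
                     n_coeff = n_coeff)
  keep <- vapply(per_subj, function(s) any(s$channel_retained), logical(1))
  kept <- per_subj[keep]
  n_excluded <- sum(!keep)
  if (!length(kept)) {
    return(list(temporal = NULL, spatiotemporal = NULL, labels = integer(0),
                subjects = character(0), channel_retained = NULL,
                n_excluded = n_excluded))
  }
  cols <- colnames(kept[[1]]$per_channel)
  temporal <- t(vapply(kept, function(s) {
    aggregate_subject(s$per_channel, s$channel_retained)$temporal
  }, numeric(length(cols))))
  temporal <- as.data.frame(temporal)
  st_cols <- as.vector(outer(cols, rownames(kept[[1]]$per_channel),
                             function(f, ch) paste(ch, f, sep = ".")))
  spatio <- t(vapply(kept, function(s) {
    as.vector(t(s$per_channel))
  }, numeric(length(st_cols))))
  colnames(spatio) <- st_cols
  labels <- vapply(kept, function(s) as.integer(s$group == "tbi"),
                   integer(1))
  list(temporal = temporal,
       spatiotemporal = spatio,
       labels = labels,
       subjects = vapply(kept, `[[`, character(1), "subject"),
       channel_retained = t(vapply(kept, `[[`, logical(16),
                                   "channel_retained")),
       n_excluded = n_excluded)
}
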