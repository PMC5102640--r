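#' Extract event-locked trials
#'
#' Cuts 11-s post-onset windows (half-open, onset sample included) out of
#' the preprocessed HbO/HbR signals for every channel and every event of
#' the requested condition(s). Events whose window would run past the end
#' of the recording are skipped with a warning.
#'
#' @param hemo A `hemo_signals` object from [preprocess_recording()].
#' @param condition Conditions to keep (default `"HighComplexity"`).
#' @param window_s Trial window length, seconds (default 11).
#' @return A `trial_set`: list with `trials` (channel-indexed list of
#'   3-d arrays sample x trial for HbO and HbR), `qc` (filled by
#'   [apply_trial_qc()]), `fs`, `condition`, `n_events`.
#' @export
extract_trials <- function(hemo, condition = "HighComplexity",
                           window_s = 11) {
  stopifnot(inherits(hemo, "hemo_signals"))
  ev <- hemo$schedule$events
  sel <- which(ev$condition %in% condition)
  if (!length(sel)) {
    stop("no events of condition ", paste(condition, collapse = "/"),
         " in the schedule")
  }
  fs <- hemo$fs
  wlen <- round(window_s * fs)
  n <- nrow(hemo$HbO)
  starts <- floor(ev$onset_s[sel] * fs) + 1L    # onset sample, 0-based time
  ok <- starts + wlen - 1L <= n
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) truncated by the recording end; skipped")
  }
  starts <- starts[ok]
  nch <- ncol(hemo$HbO)
  hbo <- array(NA_real_, c(wlen, length(starts), nch))
  hbr <- array(NA_real_, c(wlen, length(starts), nch))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + wlen - 1L)
    hbo[, k, ] <- hemo$HbO[idx, ]
    hbr[, k, ] <- hemo$HbR[idx, ]
  }
  structure(list(subject = hemo$subject, group = hemo$group, fs = fs,
                 condition = condition, window_s = window_s,
                 event_index = sel[ok], hbo = hbo, hbr = hbr,
                 qc = NULL),
            class = "trial_set")
}

#' Three-criterion quality verdict for a single trial
#'
#' A trial is retained only if (1) HbO and HbR are negatively correlated
#' (Pearson r < 0), (2) mean HbO exceeds mean HbR over the window
#' (oxygenation dominance), and (3) the trial-mean HbO is positive.
#' Zero-variance windows make the correlation undefined; such trials are
#' rejected with reason `"degenerate"` rather than raising an error.
#'
#' @param hbo,hbr Trial-window concentration vectors (uM).
#' @param positivity_mode `"mean"` (default; trial-mean HbO > 0) or
#'   `"all_samples"` (every sample positive).
#' @return List with logical `anticorrelation`, `oxy_dominance`,
#'   `positivity`, `retained`, numeric `r`, `mean_hbo`, `mean_hbr`, and
#'   `reason` (`""` or `"degenerate"`).
#' @export
trial_passes <- function(hbo, hbr, positivity_mode = c("mean",
                                                       "all_samples")) {
  positivity_mode <- match.arg(positivity_mode)
  m_o <- mean(hbo)
  m_r <- mean(hbr)
  if (stats::sd(hbo) == 0 || stats::sd(hbr) == 0) {
    return(list(anticorrelation = FALSE, oxy_dominance = m_o > m_r,
                positivity = m_o > 0, retained = FALSE, r = NA_real_,
                mean_hbo = m_o, mean_hbr = m_r, reason = "degenerate"))
  }
  r <- stats::cor(hbo, hbr)
  anticorr <- r < 0
  oxy <- m_o > m_r
  pos <- if (positivity_mode == "mean") m_o > 0 else all(hbo > 0)
  list(anticorrelation = anticorr, oxy_dominance = oxy, positivity = pos,
       retained = anticorr && oxy && pos, r = r, mean_hbo = m_o,
       mean_hbr = m_r, reason = "")
}

#' Apply the quality screen to every trial of a trial set
#'
#' @param trialset A [extract_trials()] result.
#' @param reject When FALSE every trial is marked retained (the
#'   no-rejection control analysis).
#' @param positivity_mode Passed to [trial_passes()].
#' @return The trial set with a `qc` data.frame (channel, trial, flags,
#'   r, means, retained).
#' @export
apply_trial_qc <- function(trialset, reject = TRUE,
                           positivity_mode = "mean") {
  stopifnot(inherits(trialset, "trial_set"))
  nch <- dim(trialset$hbo)[3]
  ntr <- dim(trialset$hbo)[2]
  rows <- vector("list", nch)
  for (ch in seq_len(nch)) {
    O <- trialset$hbo[, , ch, drop = FALSE]
    dim(O) <- dim(O)[1:2]
    R <- trialset$hbr[, , ch, drop = FALSE]
    dim(R) <- dim(R)[1:2]
    m_o <- colMeans(O)
    m_r <- colMeans(R)
    Oc <- sweep(O, 2, m_o)
    Rc <- sweep(R, 2, m_r)
    sso <- colSums(Oc^2)
    ssr <- colSums(Rc^2)
    degen <- sso == 0 | ssr == 0
    r <- rep(NA_real_, ntr)
    r[!degen] <- colSums(Oc * Rc)[!degen] /
      sqrt(sso[!degen] * ssr[!degen])
    anticorr <- !degen & r < 0
    anticorr[degen] <- FALSE
    oxy <- m_o > m_r
    pos <- if (positivity_mode == "mean") m_o > 0 else
      apply(O > 0, 2, all)
    retained <- anticorr & oxy & pos & !degen
    rows[[ch]] <- data.frame(channel = ch, trial = seq_len(ntr),
                             event_index = trialset$event_index,
                             r = r, mean_hbo = m_o, mean_hbr = m_r,
                             anticorrelation = anticorr,
                             oxy_dominance = oxy, positivity = pos,
                             retained = if (reject) retained else TRUE,
                             reason = ifelse(degen, "degenerate", ""))
  }
  trialset$qc <- do.call(rbind, rows)
  trialset$rejection_applied <- reject
  trialset
}

#' Prune channels and subjects by rejected-trial fraction
#'
#' A channel is dropped when the fraction of its rejected trials is at
#' least `reject_threshold` (boundary inclusive); a subject is dropped
#' when all 16 channels are dropped. Returns the verdicts plus a cohort
#' retention report.
#'
#' @param trialsets List of QC-applied trial sets (one per subject).
#' @param reject_threshold Rejected-fraction threshold (default 0.80).
#' @return List with `channel_retained` (subject x channel logical matrix),
#'   `subject_retained` (logical), and `report` (per-subject retained-trial
#'   counts and the per-channel cohort retention histogram).
#' @export
prune_channels_subjects <- function(trialsets, reject_threshold = 0.80) {
  ns <- length(trialsets)
  nch <- if (ns) dim(trialsets[[1]]$hbo)[3] else 16L
  channel_retained <- matrix(FALSE, ns, nch)
  retained_counts <- matrix(0L, ns, nch)
  subjects <- character(ns)
  groups <- character(ns)
  for (i in seq_len(ns)) {
    ts <- trialsets[[i]]
    stopifnot(!is.null(ts$qc))
    subjects[i] <- ts$subject
    groups[i] <- ts$group
    for (ch in seq_len(nch)) {
      q <- ts$qc[ts$qc$channel == ch, ]
      rej_frac <- if (nrow(q)) mean(!q$retained) else 1
      channel_retained[i, ch] <- rej_frac < reject_threshold
      retained_counts[i, ch] <- sum(q$retained)
    }
  }
  subject_retained <- rowSums(channel_retained) > 0
  hist_by_group <- tapply(seq_len(ns), groups, function(ix) {
    colSums(channel_retained[ix, , drop = FALSE])
  })
  list(channel_retained = channel_retained,
       subject_retained = subject_retained,
       report = list(subjects = subjects, groups = groups,
                     retained_counts = retained_counts,
                     channel_histogram = hist_by_group))
}

#' Block-average retained trials of one channel
#'
#' Pointwise arithmetic mean of HbO (and HbR) across retained trials only.
#'
#' @param trialset A QC-applied trial set.
#' @param channel Channel index.
#' @return List with vectors `HbO`, `HbR` (uM) and `n_trials` used.
#' @export
block_average <- function(trialset, channel) {
  stopifnot(!is.null(trialset$qc))
  q <- trialset$qc[trialset$qc$channel == channel, ]
  keep <- q$trial[q$retained]
  if (!length(keep)) {
    stop("channel ", channel, " has no retained trials; it should have ",
         "been pruned")
  }
  list(HbO = rowMeans(trialset$hbo[, keep, channel, drop = FALSE]),
       HbR = rowMeans(trialset$hbr[, keep, channel, drop = FALSE]),
       n_trials = length(keep))
}
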