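#' Detect the activity curve in an averaged HbO trial
#'
#' The activity curve is the positive deflection around the global maximum
#' of the averaged HbO window: the oxygenation rise and its return. The
#' peak is the first-occurring argmax; the start is the nearest sample to
#' the left of the peak where the signal is non-positive or turns back up
#' (a local minimum), falling back to the window edge; the end is found
#' symmetrically to the right.
#'
#' @param avg_hbo Averaged HbO trial window (uM).
#' @param fs Sampling rate, Hz.
#' @return An `activity_curve`: list with 1-based `start_index`,
#'   `peak_index`, `end_index`, the corresponding times (s, 0-based),
#'   `peak_amplitude` (uM) and a `degenerate` flag (all-nonpositive input).
#' @export
detect_activity_curve <- function(avg_hbo, fs) {
  n <- length(avg_hbo)
  if (n < 5) stop("window too short for curve detection (need >= 5 samples)")
  peak <- which.max(avg_hbo)
  if (avg_hbo[peak] <= 0 || max(avg_hbo) == min(avg_hbo)) {
    return(structure(list(start_index = peak, peak_index = peak,
                          end_index = peak,
                          start_time_s = (peak - 1) / fs,
                          peak_time_s = (peak - 1) / fs,
                          end_time_s = (peak - 1) / fs,
                          peak_amplitude = avg_hbo[peak],
                          degenerate = TRUE),
                     class = "activity_curve"))
  }
  start <- 1L
  if (peak > 1L) {
    for (i in (peak - 1L):1L) {
      if (avg_hbo[i] <= 0 || (i > 1L && avg_hbo[i] <= avg_hbo[i - 1L])) {
        start <- i
        break
      }
      start <- i  # reaches window edge if no stop condition fires
    }
  }
  end <- n
  if (peak < n) {
    for (i in (peak + 1L):n) {
      if (avg_hbo[i] <= 0 || (i < n && avg_hbo[i] <= avg_hbo[i + 1L])) {
        end <- i
        break
      }
      end <- i
    }
  }
  structure(list(start_index = start, peak_index = peak, end_index = end,
                 start_time_s = (start - 1) / fs,
                 peak_time_s = (peak - 1) / fs,
                 end_time_s = (end - 1) / fs,
                 peak_amplitude = avg_hbo[peak],
                 degenerate = FALSE),
            class = "activity_curve")
}

# FWHM by linear interpolation of the half-peak crossings nearest the peak;
# clips to the window edge (flagged) when a crossing is absent on a side
fwhm_seconds <- function(avg_hbo, fs, curve) {
  half <- curve$peak_amplitude / 2
  p <- curve$peak_index
  n <- length(avg_hbo)
  left_t <- 0
  clipped <- FALSE
  found <- FALSE
  if (p > 1) {
    for (i in (p - 1L):1L) {
      if (avg_hbo[i] <= half) {
        frac <- (half - avg_hbo[i]) / (avg_hbo[i + 1L] - avg_hbo[i])
        left_t <- (i - 1 + frac) / fs
        found <- TRUE
        break
      }
    }
  }
  if (!found) clipped <- TRUE            # left edge
  right_t <- (n - 1) / fs
  found <- FALSE
  if (p < n) {
    for (i in (p + 1L):n) {
      if (avg_hbo[i] <= half) {
        frac <- (avg_hbo[i - 1L] - half) / (avg_hbo[i - 1L] - avg_hbo[i])
        right_t <- (i - 2 + frac) / fs
        found <- TRUE
        break
      }
    }
  }
  if (!found) clipped <- TRUE            # right edge
  list(fwhm = right_t - left_t, clipped = clipped)
}

#' Spectral (DFT-magnitude) features of the continuous HbO signal
#'
#' Magnitudes of the discrete Fourier coefficients
#' `c_n = sum_k HbO(k) exp(-2 pi i k n / N)` at the bins nearest the target
#' frequencies inside the 0.01-0.1 Hz very-low/low-frequency oscillation
#' band. Computed on the full-length filtered channel signal: an 11-s
#' window cannot resolve this band.
#'
#' @param hbo Full-length HbO series (uM).
#' @param fs Sampling rate, Hz.
#' @param band Frequency band (Hz) the coefficients must lie in.
#' @param target_freqs Target frequencies (Hz), defaults 0.02/0.05/0.09.
#' @param n_coeff Number of coefficients (default 3).
#' @return Named numeric vector `HDFT_1..n_coeff` of magnitudes, with the
#'   selected bin frequencies as attribute `freqs_hz`.
#' @export
compute_hdft <- function(hbo, fs, band = c(0.01, 0.1),
                         target_freqs = c(0.02, 0.05, 0.09), n_coeff = 3) {
  target_freqs <- target_freqs[seq_len(n_coeff)]
  N <- length(hbo)
  if (N < 2 * fs / band[1]) {
    stop("series too short to resolve ", band[1], " Hz: need at least ",
         ceiling(2 * fs / band[1]), " samples")
  }
  spec <- stats::fft(hbo)
  bins <- round(target_freqs * N / fs)      # 0-based bin index n
  freqs <- bins * fs / N
  if (any(freqs < band[1] - 1e-12 | freqs > band[2] + 1e-12)) {
    stop("selected DFT bins fall outside the ", band[1], "-", band[2],
         " Hz band")
  }
  out <- Mod(spec[bins + 1L])
  names(out) <- sprintf("HDFT_%d", seq_len(n_coeff))
  attr(out, "freqs_hz") <- freqs
  out
}

#' Compute the eleven hemodynamic features
#'
#' Moment features use population (1/n) moments of the averaged HbO window:
#' mean `HM`, variance `HV`, Fisher skewness `HS`, excess kurtosis `HK`.
#' Curve features come from the detected activity curve: signed left/right
#' slopes `CSL`/`CSR` (uM/s), trapezoidal area `CA` (uM s), FWHM `CF` (s),
#' peak amplitude `CP` (uM), activity start time `CAS` (s). `HDFT` holds
#' the in-band DFT magnitudes of the continuous channel signal.
#'
#' @param avg_hbo Averaged HbO trial window (uM).
#' @param fs Sampling rate, Hz.
#' @param curve Optional precomputed [detect_activity_curve()] result.
#' @param hdft_input Full-length continuous HbO series for the spectral
#'   feature (NULL gives NA HDFT entries).
#' @param n_coeff Number of HDFT magnitudes.
#' @param hdft_args Extra arguments for [compute_hdft()].
#' @return Named numeric vector: HM, HV, HK, HS, CSL, CSR, CA, CF, CP,
#'   CAS, HDFT_1..n_coeff.
#' @export
compute_features <- function(avg_hbo, fs, curve = NULL, hdft_input = NULL,
                             n_coeff = 3, hdft_args = list()) {
  n <- length(avg_hbo)
  if (is.null(curve)) curve <- detect_activity_curve(avg_hbo, fs)
  hm <- mean(avg_hbo)
  m2 <- mean((avg_hbo - hm)^2)
  hs <- if (m2 > 0) mean((avg_hbo - hm)^3) / m2^1.5 else 0
  hk <- if (m2 > 0) mean((avg_hbo - hm)^4) / m2^2 - 3 else 0
  s <- curve$start_index
  p <- curve$peak_index
  e <- curve$end_index
  csl <- if (p > s) (avg_hbo[p] - avg_hbo[s]) / ((p - s) / fs) else 0
  csr <- if (e > p) (avg_hbo[e] - avg_hbo[p]) / ((e - p) / fs) else 0
  ca <- if (e > s) {
    y <- avg_hbo[s:e]
    sum((y[-1] + y[-length(y)]) / 2) / fs
  } else 0
  cf <- if (curve$degenerate) 0 else fwhm_seconds(avg_hbo, fs, curve)$fwhm
  out <- c(HM = hm, HV = m2, HK = hk, HS = hs, CSL = csl, CSR = csr,
           CA = ca, CF = cf, CP = curve$peak_amplitude,
           CAS = curve$start_time_s)
  hdft <- if (!is.null(hdft_input)) {
    do.call(compute_hdft, c(list(hbo = hdft_input, fs = fs,
                                 n_coeff = n_coeff), hdft_args))
  } else {
    stats::setNames(rep(NA_real_, n_coeff),
                    sprintf("HDFT_%d", seq_len(n_coeff)))
  }
  c(out, hdft)
}

#' Aggregate per-channel features into a subject's representative vectors
#'
#' Temporal mode: element-wise mean over retained channels (HDFT averaged
#' bin-wise). Spatio-temporal mode: the per-channel matrix with NA rows for
#' dropped channels.
#'
#' @param per_channel Numeric matrix channels x feature-columns (NA rows
#'   allowed for dropped channels).
#' @param retained_channels Logical vector, one entry per channel.
#' @return List with `temporal` (named vector) and `spatiotemporal`
#'   (the input matrix with non-retained rows forced to NA).
#' @export
aggregate_subject <- function(per_channel, retained_channels) {
  stopifnot(is.matrix(per_channel),
            nrow(per_channel) == length(retained_channels))
  if (!any(retained_channels)) {
    stop("no retained channels; the subject should have been excluded")
  }
  per_channel[!retained_channels, ] <- NA_real_
  temporal <- colMeans(per_channel[retained_channels, , drop = FALSE])
  list(temporal = temporal, spatiotemporal = per_channel)
}

#' Per-subject feature extraction from a preprocessed recording
#'
#' Glue over the QC and feature modules: extracts and screens trials,
#' prunes nothing by itself (channel pruning happens at cohort level), and
#' returns per-channel feature vectors plus channel retention.
#'
#' @param hemo A `hemo_signals` object.
#' @param condition Condition(s) to analyse.
#' @param reject Apply the trial screen (FALSE = control analysis).
#' @param reject_threshold Channel-level rejected-fraction threshold.
#' @param n_coeff HDFT dimensionality.
#' @return List with `per_channel` (16 x n_col matrix), `channel_retained`,
#'   `group`, `subject`.
#' @export
subject_features <- function(hemo, condition = "HighComplexity",
                             reject = TRUE, reject_threshold = 0.80,
                             n_coeff = 3) {
  ts <- apply_trial_qc(extract_trials(hemo, condition), reject = reject)
  nch <- ncol(hemo$HbO)
  cols <- expand_feature_columns(feature_names(), n_coeff)
  per_channel <- matrix(NA_real_, nch, length(cols),
                        dimnames = list(channel_names()[seq_len(nch)], cols))
  retained <- logical(nch)
  for (ch in seq_len(nch)) {
    q <- ts$qc[ts$qc$channel == ch, ]
    rej_frac <- if (nrow(q)) mean(!q$retained) else 1
    retained[ch] <- rej_frac < reject_threshold && any(q$retained)
    if (!retained[ch]) next
    avg <- block_average(ts, ch)
    per_channel[ch, ] <- compute_features(avg$HbO, hemo$fs,
                                          hdft_input = hemo$HbO[, ch],
                                          n_coeff = n_coeff)
  }
  list(per_channel = per_channel, channel_retained = retained,
       group = hemo$group, subject = hemo$subject)
}
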