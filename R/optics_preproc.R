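#' Optical configuration for the modified Beer-Lambert conversion
#'
#' Bundles the geometry and spectroscopy constants shared by the synthetic
#' forward model and the inversion, so round trips are self-consistent by
#' construction. Extinction coefficients default to the standard compiled
#' hemoglobin spectra at 730/850 nm (expressed in cm^-1 uM^-1); optical
#' density uses the base-10 convention by default.
#'
#' @param source_detector_distance_cm Emitter-detector separation, cm.
#' @param extinction_matrix 2 x 2 matrix, rows = wavelengths (730, 850 nm),
#'   columns = chromophores (HbO, HbR), units cm^-1 uM^-1.
#' @param od_base Logarithm base for optical density, 10 or `exp(1)`.
#' @param baseline_window_s `(start, end)` seconds of recording used as the
#'   intensity-normalization baseline.
#' @param wavelengths_nm The two measurement wavelengths.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(source_detector_distance_cm = 2.5,
                           extinction_matrix = default_extinction(),
                           od_base = 10,
                           baseline_window_s = c(0, 10),
                           wavelengths_nm = c(730, 850)) {
  stopifnot(source_detector_distance_cm > 0,
            is.matrix(extinction_matrix),
            all(dim(extinction_matrix) == c(2, 2)),
            length(wavelengths_nm) == 2,
            od_base > 0, od_base != 1,
            length(baseline_window_s) == 2,
            baseline_window_s[2] > baseline_window_s[1])
  if (!is.finite(kappa(extinction_matrix)) ||
      abs(det(extinction_matrix)) < 1e-12) {
    stop("extinction matrix is singular or ill-conditioned")
  }
  structure(list(
    source_detector_distance_cm = source_detector_distance_cm,
    extinction_matrix = extinction_matrix,
    od_base = od_base,
    baseline_window_s = baseline_window_s,
    wavelengths_nm = wavelengths_nm
  ), class = "optical_config")
}

#' Default hemoglobin extinction coefficients
#'
#' Compiled molar extinction values at 730 and 850 nm converted to
#' cm^-1 uM^-1 (base-10 convention).
#' @return 2 x 2 matrix, rows 730/850 nm, columns HbO/HbR.
#' @export
default_extinction <- function() {
  m <- matrix(c(0.390, 1.1022,    # 730 nm: HbO, HbR
                1.058, 0.6913),   # 850 nm: HbO, HbR
              nrow = 2, byrow = TRUE) / 1000
  dimnames(m) <- list(c("730", "850"), c("HbO", "HbR"))
  m
}

#' Differential pathlength factor as a function of age and wavelength
#'
#' Evaluates the general five-term DPF equation (a cubic polynomial in
#' wavelength plus a sub-linear age term) valid for the near-infrared
#' window. DPF converts the geometric source-detector distance into the
#' effective photon path length in the modified Beer-Lambert law.
#'
#' @param wavelength_nm Wavelength in nanometres, within [690, 900].
#' @param age_years Subject age in years, within (0, 100].
#' @return Dimensionless DPF (typically between 3 and 9).
#' @export
compute_dpf <- function(wavelength_nm, age_years) {
  if (any(wavelength_nm < 690 | wavelength_nm > 900)) {
    stop("wavelength must be within [690, 900] nm")
  }
  if (any(age_years <= 0 | age_years > 100)) {
    stop("age must be within (0, 100] years")
  }
  223.3 + 0.05624 * age_years^0.8493 -
    5.723e-7 * wavelength_nm^3 + 0.001245 * wavelength_nm^2 -
    0.9025 * wavelength_nm
}

#' Intensity to optical-density change
#'
#' Normalizes a raw intensity trace by the mean of its baseline window and
#' takes the negative logarithm: `dOD(t) = -log(I(t) / mean(I_baseline))`.
#'
#' @param intensity Strictly positive intensity vector.
#' @param fs Sampling rate, Hz.
#' @param baseline_window_s `(start, end)` seconds defining the baseline.
#' @param od_base Logarithm base (default 10).
#' @return Numeric vector of optical-density changes.
#' @export
intensity_to_delta_od <- function(intensity, fs,
                                  baseline_window_s = c(0, 10),
                                  od_base = 10) {
  bad <- which(!is.finite(intensity) | intensity <= 0)
  if (length(bad)) {
    stop("non-positive or non-finite intensity at sample(s) ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  idx <- baseline_indices(length(intensity), fs, baseline_window_s)
  base_mean <- mean(intensity[idx])
  -log(intensity / base_mean, base = od_base)
}

baseline_indices <- function(n, fs, baseline_window_s) {
  i0 <- floor(baseline_window_s[1] * fs) + 1L
  i1 <- min(n, ceiling(baseline_window_s[2] * fs))
  if (i0 > i1 || i0 < 1L) stop("baseline window empty within the recording")
  i0:i1
}

#' Invert the modified Beer-Lambert law
#'
#' Per sample solves the 2 x 2 linear system
#' `dOD_lambda = (eps[lambda, HbO] dHbO + eps[lambda, HbR] dHbR) * d * DPF_lambda`
#' for the chromophore concentration changes. Exact inverse of the
#' synthetic forward model under the same configuration.
#'
#' @param delta_od_730,delta_od_850 Optical-density change series at the two
#'   wavelengths (same length).
#' @param dpf_730,dpf_850 Differential pathlength factors at each wavelength.
#' @param config An [optical_config()].
#' @return List with numeric vectors `HbO` and `HbR` (uM).
#' @export
mbll_invert <- function(delta_od_730, delta_od_850, dpf_730, dpf_850,
                        config = optical_config()) {
  stopifnot(length(delta_od_730) == length(delta_od_850))
  A <- config$extinction_matrix * config$source_detector_distance_cm *
    c(dpf_730, dpf_850)   # row-wise DPF scaling
  sol <- solve(A, rbind(delta_od_730, delta_od_850))
  list(HbO = sol[1, ], HbR = sol[2, ])
}

# forward model used by the synthetic generator: concentrations -> delta-OD
mbll_forward <- function(hbo, hbr, dpf_730, dpf_850,
                         config = optical_config()) {
  A <- config$extinction_matrix * config$source_detector_distance_cm *
    c(dpf_730, dpf_850)
  od <- A %*% rbind(hbo, hbr)
  list(od_730 = od[1, ], od_850 = od[2, ])
}

# ---- Butterworth low-pass (cascaded biquads, bilinear transform) ----------

# second-order-section coefficients for an order-n Butterworth low-pass
butter_lowpass_sos <- function(order, cutoff_hz, fs) {
  stopifnot(order >= 1, cutoff_hz > 0, fs > 2 * cutoff_hz)
  wc <- tan(pi * cutoff_hz / fs)  # prewarped analog cutoff
  npairs <- order %/% 2
  sos <- matrix(0, nrow = npairs + (order %% 2), ncol = 6)
  if (npairs > 0) {
    for (k in seq_len(npairs)) {
      # conjugate pole pair of the analog prototype at angle theta
      theta <- pi * (2 * k - 1) / (2 * order)
      alpha <- 2 * sin(theta) * wc      # -2 Re(pole) * wc
      K <- wc^2
      a0 <- 1 + alpha + K
      sos[k, ] <- c(K, 2 * K, K, a0, 2 * (K - 1), 1 - alpha + K) / a0
      sos[k, 4] <- 1
    }
  }
  if (order %% 2 == 1) {
    a0 <- 1 + wc
    sos[npairs + 1, ] <- c(wc, wc, 0, a0, wc - 1, 0) / a0
    sos[npairs + 1, 4] <- 1
  }
  sos
}

# per-section steady state of the DF2T biquad for a unit-step input
sos_step_state <- function(sos) {
  k <- nrow(sos)
  zi <- matrix(0, k, 2)
  for (s in seq_len(k)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    # steady output equals DC gain g; states from the DF2T recurrence
    g <- sum(b) / sum(a)
    zi[s, 2] <- b[3] - a[3] * g
    zi[s, 1] <- b[2] - a[2] * g + zi[s, 2]
  }
  zi
}

# closed-form digital Butterworth magnitude (exact under bilinear transform)
butter_digital_gain <- function(f_hz, cutoff_hz, fs, order) {
  1 / sqrt(1 + (tan(pi * f_hz / fs) / tan(pi * cutoff_hz / fs))^(2 * order))
}

#' Butterworth IIR low-pass filter
#'
#' Order-10, 0.1 Hz cut-off by default, implemented as a cascade of
#' bilinear-transformed second-order sections with step-matched initial
#' conditions (unit DC gain; a constant input is returned unchanged).
#' The default is zero-phase (forward-backward, magnitude applied twice) so
#' trial latencies are not biased; `zero_phase = FALSE` gives the causal
#' single pass.
#'
#' @param x Signal vector.
#' @param fs Sampling rate, Hz.
#' @param cutoff_hz Cut-off frequency (-3 dB for a single pass), Hz.
#' @param order Filter order.
#' @param zero_phase Apply forward and backward (default TRUE).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff_hz = 0.1, order = 10,
                           zero_phase = TRUE) {
  sos <- butter_lowpass_sos(order, cutoff_hz, fs)
  minlen <- 3 * (2 * nrow(sos) + 1)
  if (length(x) <= minlen) {
    stop("signal too short to filter: need more than ", minlen, " samples")
  }
  zi <- sos_step_state(sos)
  y <- sos_filter(sos, x, zi * x[1])
  if (zero_phase) {
    y <- rev(sos_filter(sos, rev(y), zi * y[length(y)]))
  }
  y
}

#' Piecewise linear detrending
#'
#' Splits the signal into contiguous segments of `segment_length_s` seconds
#' and removes an independently fitted least-squares line from each segment
#' (a trailing short remainder is merged into the last full segment). Each
#' detrended segment has mean ~0.
#'
#' @param x Signal vector.
#' @param fs Sampling rate, Hz.
#' @param segment_length_s Segment length in seconds (default 60).
#' @return Detrended signal.
#' @export
detrend_piecewise <- function(x, fs, segment_length_s = 60) {
  n <- length(x)
  L <- max(2L, round(segment_length_s * fs))
  if (n < 2L) stop("signal too short to detrend (need >= 2 samples)")
  n_seg <- max(1L, n %/% L)
  bounds <- floor(seq(0L, n, length.out = n_seg + 1L))
  out <- x
  for (s in seq_len(n_seg)) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    t <- seq_along(idx)
    fit <- stats::lm.fit(cbind(1, t), x[idx])
    out[idx] <- fit$residuals
  }
  out
}

#' Raw recording to hemoglobin concentration signals
#'
#' Runs the fixed preprocessing chain on one recording: intensity
#' normalization, optical-density change, modified Beer-Lambert inversion
#' with an age/wavelength DPF, Butterworth low-pass, piecewise linear
#' detrending. Stages after the inversion can be disabled for testing.
#'
#' @param recording A `raw_recording` from the synthetic cohort module (or
#'   read from disk).
#' @param config An [optical_config()].
#' @param filter_cutoff_hz,filter_order Low-pass settings.
#' @param zero_phase Zero-phase filtering (default TRUE).
#' @param detrend_segment_s Detrending segment length, seconds.
#' @param filter,detrend Logical switches for the two final stages.
#' @return A `hemo_signals` object: list with `HbO`/`HbR` (time x 16 channel
#'   matrices, uM), `fs`, `schedule`, subject metadata and provenance.
#' @export
preprocess_recording <- function(recording, config = optical_config(),
                                 filter_cutoff_hz = 0.1, filter_order = 10,
                                 zero_phase = TRUE, detrend_segment_s = 60,
                                 filter = TRUE, detrend = TRUE) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$fs
  dpf <- c(compute_dpf(config$wavelengths_nm[1], recording$age),
           compute_dpf(config$wavelengths_nm[2], recording$age))
  n <- dim(recording$intensity)[1]
  nch <- dim(recording$intensity)[2]
  HbO <- HbR <- matrix(NA_real_, n, nch,
                       dimnames = list(NULL, channel_names()[seq_len(nch)]))
  for (ch in seq_len(nch)) {
    od1 <- intensity_to_delta_od(recording$intensity[, ch, 1], fs,
                                 config$baseline_window_s, config$od_base)
    od2 <- intensity_to_delta_od(recording$intensity[, ch, 2], fs,
                                 config$baseline_window_s, config$od_base)
    hb <- mbll_invert(od1, od2, dpf[1], dpf[2], config)
    if (filter) {
      hb$HbO <- lowpass_filter(hb$HbO, fs, filter_cutoff_hz, filter_order,
                               zero_phase)
      hb$HbR <- lowpass_filter(hb$HbR, fs, filter_cutoff_hz, filter_order,
                               zero_phase)
    }
    if (detrend) {
      hb$HbO <- detrend_piecewise(hb$HbO, fs, detrend_segment_s)
      hb$HbR <- detrend_piecewise(hb$HbR, fs, detrend_segment_s)
    }
    HbO[, ch] <- hb$HbO
    HbR[, ch] <- hb$HbR
  }
  structure(list(
    subject = recording$subject, group = recording$group,
    age = recording$age, fs = fs, HbO = HbO, HbR = HbR,
    schedule = recording$schedule,
    provenance = list(dpf = dpf, filter = filter,
                      filter_cutoff_hz = filter_cutoff_hz,
                      filter_order = filter_order, zero_phase = zero_phase,
                      detrend = detrend,
                      detrend_segment_s = detrend_segment_s,
                      od_base = config$od_base)
  ), class = "hemo_signals")
}
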