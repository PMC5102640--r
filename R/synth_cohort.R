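#' Generate a jittered event schedule
#'
#' Lays out the requested numbers of Font, Low-Complexity and
#' High-Complexity trials in random order. Every trial lasts 5 s and
#' consecutive trials are separated by an inter-stimulus interval drawn
#' uniformly from [5, 7] s; a lead-in baseline precedes the first trial.
#'
#' @param n_font,n_low,n_high Trial counts per condition.
#' @param seed Integer RNG seed; the schedule is deterministic given it.
#' @param trial_duration_s Trial length, seconds (default 5).
#' @param isi_range_s Inter-stimulus interval bounds, seconds.
#' @param lead_in_s Baseline before the first trial, seconds (default 15).
#' @param total_duration_s Recording length, seconds (default 1200). Note
#'   that the full 33/33/33 design cannot fit a 15-minute session: 99
#'   five-second trials with 5-7 s gaps need about 18.5 minutes, so the
#'   default allows 20. Must be long enough for the requested design.
#' @return An `event_schedule`: data.frame `events` with columns
#'   `onset_s`, `duration_s`, `condition`, plus `total_duration_s`.
#' @export
generate_schedule <- function(n_font, n_low, n_high, seed,
                              trial_duration_s = 5,
                              isi_range_s = c(5, 7),
                              lead_in_s = 15,
                              total_duration_s = 1200) {
  stopifnot(n_font >= 0, n_low >= 0, n_high >= 0)
  n <- n_font + n_low + n_high
  if (n < 1) stop("at least one trial is required")
  set.seed(seed)
  conditions <- sample(rep(c("Font", "LowComplexity", "HighComplexity"),
                           c(n_font, n_low, n_high)))
  isi <- stats::runif(n - 1, isi_range_s[1], isi_range_s[2])
  onsets <- lead_in_s + c(0, cumsum(trial_duration_s + isi))
  needed <- onsets[n] + trial_duration_s + isi_range_s[1]
  if (needed > total_duration_s) {
    stop(sprintf(paste0("requested design does not fit: needs at least ",
                        "%.1f s but total_duration_s = %.1f s"),
                 needed, total_duration_s))
  }
  structure(list(
    events = data.frame(onset_s = onsets,
                        duration_s = rep(trial_duration_s, n),
                        condition = conditions,
                        stringsAsFactors = FALSE),
    total_duration_s = total_duration_s
  ), class = "event_schedule")
}

#' Default group effect specification for the synthetic cohort
#'
#' Describes how healthy and TBI hemodynamics differ: healthy subjects get a
#' larger and narrower high-complexity response, strongest over the left
#' frontopolar channels (1-8 in the synthetic montage); TBI responses are
#' weaker, broader and spatially diffuse. Amplitudes are per-condition peak
#' concentration changes in uM. Between-subject variability has two parts:
#' a subject-level multiplicative gain (log-normal, `subject_gain_sdlog`)
#' standing in for optode-coupling and anatomical differences that affect
#' all channels together, and an additive per-channel SD (`amplitude_sd`)
#' that averages out across the montage.
#'
#' @param healthy_amplitude,tbi_amplitude Named per-condition peak dHbO (uM).
#' @param left_boost Multiplier applied to healthy left-hemisphere channels.
#' @param healthy_width,tbi_width HRF stretch factors.
#' @param amplitude_sd Per-channel amplitude SD (uM).
#' @param subject_gain_sdlog SD of the log subject gain (default 0.4).
#' @param artifact_rate Fraction of trials hit by a motion artifact.
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(healthy_amplitude = c(Font = 0.1,
                                              LowComplexity = 0.3,
                                              HighComplexity = 0.8),
                        tbi_amplitude = c(Font = 0.1,
                                          LowComplexity = 0.2,
                                          HighComplexity = 0.4),
                        left_boost = 1.5,
                        healthy_width = 1.0,
                        tbi_width = 1.4,
                        amplitude_sd = 0.3,
                        subject_gain_sdlog = 0.4,
                        artifact_rate = 0.05) {
  structure(list(healthy_amplitude = healthy_amplitude,
                 tbi_amplitude = tbi_amplitude,
                 left_boost = left_boost,
                 healthy_width = healthy_width,
                 tbi_width = tbi_width,
                 amplitude_sd = amplitude_sd,
                 subject_gain_sdlog = subject_gain_sdlog,
                 artifact_rate = artifact_rate),
            class = "effect_spec")
}

#' Zero-effect specification (null cohort)
#'
#' Both groups share identical response parameters and no artifacts, so any
#' downstream classification accuracy above chance is a false positive.
#' @param amplitude Common per-condition amplitude (uM).
#' @return An [effect_spec()].
#' @export
null_effect_spec <- function(amplitude = c(Font = 0.1, LowComplexity = 0.3,
                                           HighComplexity = 0.6)) {
  effect_spec(healthy_amplitude = amplitude, tbi_amplitude = amplitude,
              left_boost = 1, healthy_width = 1, tbi_width = 1,
              artifact_rate = 0)
}

#' Default noise parameters for the synthetic forward model
#'
#' Physiological and instrumental nuisance components: white noise,
#' per-channel linear drift, low-frequency oscillations inside the
#' 0.01-0.1 Hz band, a Mayer-wave-like ~0.1 Hz component and a ~0.25 Hz
#' respiratory wave, plus the motion-artifact spike magnitude. Cardiac
#' pulsation (~1 Hz) is deliberately omitted: at the 2 Hz sampling rate it
#' would alias unpredictably.
#'
#' @param white_sd White-noise SD on dHbO (uM).
#' @param drift_slope_range Uniform bounds for the drift slope (uM per
#'   minute).
#' @param lfo_amplitude Amplitude of each in-band oscillation (uM).
#' @param lfo_freqs Oscillation frequencies (Hz), inside 0.01-0.1.
#' @param mayer_amplitude,mayer_freq ~0.1 Hz wave amplitude (uM) and
#'   frequency.
#' @param resp_amplitude,resp_freq Respiratory wave amplitude (uM) and
#'   frequency.
#' @param artifact_magnitude Motion-artifact spike amplitude (uM).
#' @param hbr_ratio HbR anticorrelation ratio r in `HbR = -r HbO`.
#' @param hbr_noise_sd Independent HbR noise SD (uM).
#' @param baseline_intensity Detector baseline I0 (arbitrary units, > 0).
#' @return List of class `noise_params`.
#' @export
noise_params <- function(white_sd = 0.05,
                         drift_slope_range = c(-0.05, 0.05),
                         lfo_amplitude = 0.05,
                         lfo_freqs = c(0.02, 0.05, 0.09),
                         mayer_amplitude = 0.05, mayer_freq = 0.1,
                         resp_amplitude = 0.03, resp_freq = 0.25,
                         artifact_magnitude = 2,
                         hbr_ratio = 1 / 3,
                         hbr_noise_sd = 0.02,
                         baseline_intensity = 1000) {
  if (baseline_intensity <= 0) stop("baseline intensity must be positive")
  structure(list(white_sd = white_sd,
                 drift_slope_range = drift_slope_range,
                 lfo_amplitude = lfo_amplitude, lfo_freqs = lfo_freqs,
                 mayer_amplitude = mayer_amplitude, mayer_freq = mayer_freq,
                 resp_amplitude = resp_amplitude, resp_freq = resp_freq,
                 artifact_magnitude = artifact_magnitude,
                 hbr_ratio = hbr_ratio, hbr_noise_sd = hbr_noise_sd,
                 baseline_intensity = baseline_intensity),
            class = "noise_params")
}

#' Zero-noise parameters
#'
#' All nuisance components switched off; used for round-trip and
#' parameter-recovery tests.
#' @return A [noise_params()] with every stochastic component at zero.
#' @export
zero_noise_params <- function() {
  noise_params(white_sd = 0, drift_slope_range = c(0, 0), lfo_amplitude = 0,
               mayer_amplitude = 0, resp_amplitude = 0,
               artifact_magnitude = 0, hbr_noise_sd = 0)
}

#' Ground truth for one synthetic subject
#'
#' @param group `"healthy"` or `"tbi"`.
#' @param age Age in years.
#' @param amplitude 16 x 3 matrix of per-channel, per-condition response
#'   amplitudes (uM); columns Font/LowComplexity/HighComplexity.
#' @param latency,width Per-channel HRF latency shifts (s) and stretch
#'   factors (length 16).
#' @param artifact_trials Integer indices of events hit by an artifact.
#' @return List of class `ground_truth`.
#' @export
ground_truth <- function(group, age, amplitude, latency = rep(0, 16),
                         width = rep(1, 16), artifact_trials = integer(0)) {
  stopifnot(group %in% c("healthy", "tbi"),
            is.matrix(amplitude), nrow(amplitude) == 16,
            ncol(amplitude) == 3,
            all(is.finite(amplitude)),
            length(latency) == 16, length(width) == 16)
  colnames(amplitude) <- c("Font", "LowComplexity", "HighComplexity")
  structure(list(group = group, age = age, amplitude = amplitude,
                 latency = latency, width = width,
                 artifact_trials = as.integer(artifact_trials)),
            class = "ground_truth")
}

#' Simulate a raw dual-wavelength recording for one subject
#'
#' Builds the latent hemodynamics channel by channel -- a sum of
#' HRF-shaped responses at the scheduled onsets plus oscillations, drift
#' and white noise -- couples HbR as `-r * HbO` (sign-flipped on artifact
#' trials, which also receive additive spikes), and pushes the latent
#' concentrations through the forward modified Beer-Lambert model to
#' strictly positive detector intensities `I = I0 * base^(-dOD)`.
#'
#' @param schedule An [generate_schedule()] result.
#' @param truth A [ground_truth()].
#' @param noise A [noise_params()].
#' @param config An [optical_config()] (shared with the inversion).
#' @param fs Sampling rate, Hz (default 2).
#' @param subject Subject identifier.
#' @return A `raw_recording`: intensity array (time x 16 channel x 2
#'   wavelength), metadata, the schedule and the latent `HbO`/`HbR`.
#' @export
simulate_subject <- function(schedule, truth, noise = noise_params(),
                             config = optical_config(), fs = 2,
                             subject = "S01") {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(truth, "ground_truth"))
  n <- round(schedule$total_duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  ev <- schedule$events
  dpf <- c(compute_dpf(config$wavelengths_nm[1], truth$age),
           compute_dpf(config$wavelengths_nm[2], truth$age))
  intensity <- array(NA_real_, c(n, 16, 2))
  HbO <- HbR <- matrix(0, n, 16)
  artifact <- rep(FALSE, nrow(ev))
  artifact[truth$artifact_trials] <- TRUE
  for (ch in 1:16) {
    hbo <- numeric(n)
    hbr_extra <- numeric(n)
    for (k in seq_len(nrow(ev))) {
      amp <- truth$amplitude[ch, ev$condition[k]]
      # HRF support is ~35 s; evaluating only there saves most of the work
      i0 <- max(1L, floor(ev$onset_s[k] * fs))
      i1 <- min(n, ceiling((ev$onset_s[k] + truth$latency[ch] +
                              40 * truth$width[ch]) * fs))
      idx <- i0:i1
      resp <- amp * canonical_hrf(t[idx] - ev$onset_s[k],
                                  latency = truth$latency[ch],
                                  width = truth$width[ch])
      if (artifact[k]) {
        # motion artifact: additive spike + locally sign-flipped coupling
        win <- idx[t[idx] < ev$onset_s[k] + 11]
        spike <- noise$artifact_magnitude *
          exp(-((t[win] - ev$onset_s[k] - 1)^2) / 0.5)
        hbo[idx] <- hbo[idx] + resp
        hbo[win] <- hbo[win] + spike
        hbr_extra[win] <- hbr_extra[win] +
          2 * noise$hbr_ratio * (resp[seq_along(win)] + spike)
      } else {
        hbo[idx] <- hbo[idx] + resp
      }
    }
    if (noise$lfo_amplitude > 0) {
      for (f in noise$lfo_freqs) {
        hbo <- hbo + noise$lfo_amplitude *
          sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      }
    }
    if (noise$mayer_amplitude > 0) {
      hbo <- hbo + noise$mayer_amplitude *
        sin(2 * pi * noise$mayer_freq * t + stats::runif(1, 0, 2 * pi))
    }
    if (noise$resp_amplitude > 0) {
      hbo <- hbo + noise$resp_amplitude *
        sin(2 * pi * noise$resp_freq * t + stats::runif(1, 0, 2 * pi))
    }
    slope <- stats::runif(1, noise$drift_slope_range[1],
                          noise$drift_slope_range[2])
    hbo <- hbo + slope * t / 60
    if (noise$white_sd > 0) hbo <- hbo + stats::rnorm(n, 0, noise$white_sd)
    hbr <- -noise$hbr_ratio * hbo + hbr_extra
    if (noise$hbr_noise_sd > 0) {
      hbr <- hbr + stats::rnorm(n, 0, noise$hbr_noise_sd)
    }
    od <- mbll_forward(hbo, hbr, dpf[1], dpf[2], config)
    intensity[, ch, 1] <- noise$baseline_intensity *
      config$od_base^(-od$od_730)
    intensity[, ch, 2] <- noise$baseline_intensity *
      config$od_base^(-od$od_850)
    HbO[, ch] <- hbo
    HbR[, ch] <- hbr
  }
  structure(list(subject = subject, age = truth$age, group = truth$group,
                 fs = fs, wavelengths_nm = config$wavelengths_nm,
                 intensity = intensity, schedule = schedule,
                 latent = list(HbO = HbO, HbR = HbR)),
            class = "raw_recording")
}

# draw one subject's ground truth from the effect specification
draw_ground_truth <- function(group, spec, n_font, n_low, n_high) {
  age_mean <- if (group == "healthy") 30.8 else 37.8
  age_sd <- if (group == "healthy") 8.06 else 11.6
  age <- 0
  while (age < 18 || age > 55) age <- stats::rnorm(1, age_mean, age_sd)
  base_amp <- if (group == "healthy") spec$healthy_amplitude else
    spec$tbi_amplitude
  width0 <- if (group == "healthy") spec$healthy_width else spec$tbi_width
  amp <- matrix(rep(base_amp, each = 16), nrow = 16)
  if (group == "healthy" && spec$left_boost != 1) {
    amp[1:8, ] <- amp[1:8, ] * spec$left_boost
  }
  gain <- exp(stats::rnorm(1, 0, spec$subject_gain_sdlog))
  amp <- amp * gain + matrix(stats::rnorm(48, 0, spec$amplitude_sd), 16, 3)
  amp[amp < 0] <- 0
  n_trials <- n_font + n_low + n_high
  n_art <- stats::rbinom(1, n_trials, spec$artifact_rate)
  art <- if (n_art > 0) sort(sample.int(n_trials, n_art)) else integer(0)
  ground_truth(group, age, amp,
               latency = rep(0, 16),
               width = rep(width0, 16) * exp(stats::rnorm(16, 0, 0.05)),
               artifact_trials = art)
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-subject ground truth from the effect specification (group
#' amplitudes, shape, lateralization, artifact rate, ages from
#' group-specific truncated normals), gives each subject an independent
#' jittered schedule, and simulates raw recordings. Reproducible: the same
#' seed yields a bit-identical cohort.
#'
#' @param n_healthy,n_tbi Group sizes (defaults 31 and 30).
#' @param spec An [effect_spec()].
#' @param seed Integer RNG seed.
#' @param noise A [noise_params()].
#' @param n_font,n_low,n_high Trial design (defaults 33/33/33).
#' @param config An [optical_config()].
#' @param fs Sampling rate, Hz.
#' @return A `cohort`: list with `recordings` (list of `raw_recording`),
#'   `truths` (list of `ground_truth`) and the call parameters.
#' @export
generate_cohort <- function(n_healthy = 31, n_tbi = 30,
                            spec = effect_spec(), seed = 1,
                            noise = noise_params(),
                            n_font = 33, n_low = 33, n_high = 33,
                            config = optical_config(), fs = 2) {
  stopifnot(n_healthy >= 0, n_tbi >= 0, n_healthy + n_tbi > 0)
  groups <- rep(c("healthy", "tbi"), c(n_healthy, n_tbi))
  recordings <- vector("list", length(groups))
  truths <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    # per-subject sub-seed keeps subjects independent yet reproducible
    schedule <- generate_schedule(n_font, n_low, n_high,
                                  seed = (seed * 1013L + i) %% 2147483647L)
    truths[[i]] <- draw_ground_truth(groups[i], spec, n_font, n_low, n_high)
    recordings[[i]] <- simulate_subject(
      schedule, truths[[i]], noise, config, fs,
      subject = sprintf("%s%02d", ifelse(groups[i] == "healthy", "H", "T"),
                        i))
  }
  structure(list(recordings = recordings, truths = truths,
                 n_healthy = n_healthy, n_tbi = n_tbi, seed = seed),
            class = "cohort")
}
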