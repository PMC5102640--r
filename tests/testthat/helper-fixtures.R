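# Shared fixtures, all built in code at test time.

# a short schedule + clean zero-noise subject used by several files
make_clean_recording <- function(amplitude = 1, n_high = 6, seed = 11,
                                 width = rep(1, 16)) {
  sched <- generate_schedule(0, 0, n_high, seed = seed,
                             total_duration_s = 200)
  truth <- ground_truth("healthy", 30,
                        matrix(amplitude, 16, 3), width = width)
  simulate_subject(sched, truth, zero_noise_params())
}

# small noisy cohort for pipeline-level tests
make_test_cohort <- function(n_per_group = 6, seed = 3,
                             spec = effect_spec(), n_trials = 12) {
  generate_cohort(n_per_group, n_per_group, spec = spec, seed = seed,
                  n_font = n_trials, n_low = n_trials, n_high = n_trials)
}

# synthetic feature table with a group effect planted on named columns
# (delta in units of the within-group SD, which is 1)
make_planted_table <- function(n0 = 31, n1 = 30,
                               features = c("HM", "HV", "CSL", "CA",
                                            "CF", "CAS"),
                               planted = c("CA", "CF"), delta = 2,
                               seed = 1) {
  set.seed(seed)
  n <- n0 + n1
  X <- matrix(rnorm(n * length(features)), n, length(features),
              dimnames = list(NULL, features))
  labels <- rep(c(0L, 1L), c(n0, n1))
  X[labels == 1L, planted] <- X[labels == 1L, planted] + delta
  list(features = as.data.frame(X), labels = labels, planted = planted)
}

# O(N^2) direct evaluation of the DFT sum c_n = sum_k x_k e^{-2 pi i k n / N}
direct_dft_coef <- function(x, n_bin) {
  N <- length(x)
  k <- 0:(N - 1)
  sum(x * exp(-2i * pi * k * n_bin / N))
}

# exhaustive-threshold ROC and trapezoidal AUC (independent of roc_points)
brute_force_roc_auc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(c(Inf, ths), function(th) {
    pos <- scores >= th
    c(fpr = sum(pos & labels == 0) / sum(labels == 0),
      tpr = sum(pos & labels == 1) / sum(labels == 1))
  }, numeric(2)))
  pts <- pts[order(pts[, "fpr"], pts[, "tpr"]), , drop = FALSE]
  sum(diff(pts[, "fpr"]) * (pts[-1, "tpr"] + pts[-nrow(pts), "tpr"]) / 2)
}
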