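test_that("detect_activity_curve finds peak and boundaries", {
  fs <- 2
  # symmetric triangle 0...1...0 over 22 samples
  tri <- c(seq(0, 1, length.out = 11), seq(1, 0, length.out = 12)[-1])
  cv <- detect_activity_curve(tri, fs)
  expect_equal(cv$peak_index, 11)
  expect_equal(cv$start_index, 1)
  expect_equal(cv$end_index, 22)
  # Gaussian bump peaking at 6 s
  t <- (0:21) / fs
  g <- exp(-(t - 6)^2 / 2)
  cvg <- detect_activity_curve(g, fs)
  expect_lte(abs(cvg$peak_time_s - 6), 1 / fs)
  # all-nonpositive signal flags a degenerate curve
  cvd <- detect_activity_curve(-g, fs)
  expect_true(cvd$degenerate)
  expect_equal(cvd$start_index, cvd$end_index)
  expect_error(detect_activity_curve(g[1:3], fs), "too short")
})

test_that("curve boundaries match an exhaustive scan of the stop rules", {
  fs <- 2
  # bump with a shallow secondary wiggle
  t <- (0:21) / fs
  x <- exp(-(t - 5)^2 / 3) + 0.15 * exp(-(t - 9.5)^2 / 0.4) - 0.05
  cv <- detect_activity_curve(x, fs)
  # brute-force: peak is first argmax; start/end are the samples nearest
  # the peak satisfying (value <= 0) or (local turn) on each side
  p <- which.max(x)
  lstop <- which(vapply(seq_len(length(x)), function(i) {
    i < p && (x[i] <= 0 || (i > 1 && x[i] <= x[i - 1]))
  }, logical(1)))
  rstop <- which(vapply(seq_len(length(x)), function(i) {
    i > p && (x[i] <= 0 || (i < length(x) && x[i] <= x[i + 1]))
  }, logical(1)))
  expect_equal(cv$peak_index, p)
  expect_equal(cv$start_index, if (length(lstop)) max(lstop) else 1L)
  expect_equal(cv$end_index, if (length(rstop)) min(rstop) else length(x))
})

test_that("compute_features matches moment and closed-form oracles", {
  fs <- 2
  # constant signal: HM only, degenerate curve
  fv <- compute_features(rep(0.7, 22), fs)
  expect_equal(fv[["HM"]], 0.7)
  expect_equal(fv[["HV"]], 0)
  expect_equal(fv[["CA"]], 0)
  # Gaussian bump: FWHM = 2 sqrt(2 ln 2) sigma
  t <- (0:43) / fs
  sigma <- 1.5
  g <- 2 * exp(-(t - 10)^2 / (2 * sigma^2))
  fvg <- compute_features(g, fs)
  expect_equal(fvg[["CF"]], 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 0.5 / (2 * sqrt(2 * log(2)) * sigma))
  expect_equal(fvg[["CP"]], 2)
  # random series: brute-force moment oracle
  set.seed(4)
  x <- rnorm(22, 0.3, 0.2)
  fx <- compute_features(x, fs)
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  expect_equal(fx[["HM"]], mu)
  expect_equal(fx[["HV"]], m2)
  expect_equal(fx[["HS"]], m3 / m2^1.5)
  expect_equal(fx[["HK"]], m4 / m2^2 - 3)
  # slopes agree with the two-point definition on the detected curve
  cv <- detect_activity_curve(x, fs)
  if (cv$peak_index > cv$start_index) {
    expect_equal(fx[["CSL"]],
                 (x[cv$peak_index] - x[cv$start_index]) /
                   (cv$peak_time_s - cv$start_time_s))
  }
})

test_that("compute_hdft equals the direct O(N^2) DFT sum", {
  fs <- 2
  # constant series: DC N*m, in-band magnitudes ~ 0
  m <- 0.4
  N <- 400
  hd <- compute_hdft(rep(m, N), fs)
  expect_lt(max(hd), 1e-9)
  expect_equal(Mod(direct_dft_coef(rep(m, N), 0)), N * m)
  # unit sine exactly at an in-band bin: magnitude N/2 there
  n_bin <- round(0.05 * N / fs)        # bin 10 -> exactly 0.05 Hz
  k <- 0:(N - 1)
  sine <- sin(2 * pi * n_bin * k / N)
  hd2 <- compute_hdft(sine, fs)
  expect_equal(hd2[["HDFT_2"]], N / 2, tolerance = 1e-9)
  # random series vs the direct evaluation at every selected bin
  set.seed(9)
  x <- rnorm(N)
  hd3 <- compute_hdft(x, fs)
  bins <- round(c(0.02, 0.05, 0.09) * N / fs)
  direct <- vapply(bins, function(b) Mod(direct_dft_coef(x, b)),
                   numeric(1))
  expect_equal(as.numeric(hd3), direct, tolerance = 1e-8)
  expect_error(compute_hdft(rnorm(100), fs), "too short")
})

test_that("full-spectrum Parseval identity holds", {
  set.seed(10)
  x <- rnorm(512)
  cn <- fft(x)
  expect_equal(sum(Mod(cn)^2) / length(x), sum(x^2), tolerance = 1e-8)
})

test_that("feature scale equivariance and time-shift invariance", {
  fs <- 2
  t <- (0:21) / fs
  x <- exp(-(t - 5)^2 / 3) + 0.02
  long <- rep(x, 20) + 0.01   # stand-in continuous series for HDFT
  a <- 3.7
  f1 <- compute_features(x, fs, hdft_input = long)
  f2 <- compute_features(a * x, fs, hdft_input = a * long)
  lin <- c("HM", "CP", "CSL", "CSR", "CA", "HDFT_1", "HDFT_2", "HDFT_3")
  expect_equal(unname(f2[lin]), unname(a * f1[lin]), tolerance = 1e-10)
  expect_equal(f2[["HV"]], a^2 * f1[["HV"]], tolerance = 1e-10)
  expect_equal(f2[c("HS", "HK", "CF", "CAS")], f1[c("HS", "HK", "CF",
                                                    "CAS")],
               tolerance = 1e-10)
  # shifting the bump moves CAS and leaves CF, CP (within one sample)
  tt <- (0:43) / fs
  b1 <- exp(-(tt - 8)^2 / 2) - 0.001    # zero-crossing baseline
  b2 <- exp(-(tt - 11)^2 / 2) - 0.001
  g1 <- compute_features(b1, fs)
  g2 <- compute_features(b2, fs)
  expect_equal(g2[["CAS"]] - g1[["CAS"]], 3, tolerance = 1 / fs)
  expect_equal(g2[["CP"]], g1[["CP"]], tolerance = 1e-6)
  expect_equal(g2[["CF"]], g1[["CF"]], tolerance = 1 / fs)
})

test_that("aggregate_subject averages retained channels element-wise", {
  cols <- expand_feature_columns(feature_names())
  M <- matrix(rnorm(16 * length(cols)), 16,
              dimnames = list(channel_names(), cols))
  # one retained channel: temporal equals that row
  keep1 <- c(TRUE, rep(FALSE, 15))
  expect_equal(aggregate_subject(M, keep1)$temporal, M[1, ])
  # two channels with CP 0.4 / 0.8 average to 0.6
  M2 <- M
  M2[1, "CP"] <- 0.4
  M2[2, "CP"] <- 0.8
  keep2 <- c(TRUE, TRUE, rep(FALSE, 14))
  expect_equal(aggregate_subject(M2, keep2)$temporal[["CP"]], 0.6)
  # 12 of 16 channels: brute-force column means over exactly those 12
  keep12 <- rep(c(TRUE, FALSE), c(12, 4))
  agg <- aggregate_subject(M, keep12)
  expect_equal(agg$temporal,
               apply(M[1:12, ], 2, function(col) sum(col) / 12))
  expect_true(all(is.na(agg$spatiotemporal[13:16, ])))
  expect_error(aggregate_subject(M, rep(FALSE, 16)), "no retained")
})
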