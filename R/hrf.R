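#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF (response peak near 6 s, undershoot near 16 s,
#' undershoot ratio 1/6), rescaled so its maximum is 1. `latency` shifts the
#' response in time and `width` stretches it, so group- and channel-level
#' shape effects can be planted in synthetic subjects.
#'
#' @param t Time since stimulus onset, seconds (vector; values < 0 give 0).
#' @param latency Additional onset delay in seconds (default 0).
#' @param width Temporal stretch factor (default 1; > 1 widens the response).
#' @return Numeric vector of unit-peak response values.
#' @export
canonical_hrf <- function(t, latency = 0, width = 1) {
  stopifnot(width > 0)
  u <- (t - latency) / width
  h <- numeric(length(u))
  pos <- u > 0
  x <- u[pos]
  h[pos] <- stats::dgamma(x, shape = 6, rate = 1) -
    stats::dgamma(x, shape = 16, rate = 1) / 6
  # unit peak of the unshifted kernel (argmax 4.9985 s, value 0.1754412)
  h / 0.175441201232
}
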