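#' Canonical double-gamma haemodynamic response function
#'
#' The same kernel is used by the phantom generator and by the GLM design
#' builder, so that a noise-free simulated response is recovered exactly.
#' The response gamma peaks at `peak_s` seconds, the undershoot gamma at
#' `undershoot_s`, with a peak/undershoot amplitude ratio of `ratio`.
#'
#' @param t_s numeric vector of times (s) at which to evaluate the kernel.
#' @param peak_s mode of the positive lobe (default 6 s).
#' @param undershoot_s mode of the undershoot lobe (default 16 s).
#' @param ratio positive-to-undershoot amplitude ratio (default 6).
#' @return Numeric vector of kernel values (unnormalized).
#' @export
hrf_double_gamma <- function(t_s, peak_s = 6, undershoot_s = 16, ratio = 6) {
  assert_that(peak_s > 0 && undershoot_s > peak_s && ratio > 0,
              "invalid HRF parameters")
  h <- stats::dgamma(t_s, shape = peak_s + 1, rate = 1) -
    stats::dgamma(t_s, shape = undershoot_s + 1, rate = 1) / ratio
  h[t_s < 0] <- 0
  h
}
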