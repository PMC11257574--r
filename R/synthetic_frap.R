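#' Synthetic FRAP trace with known kinetics
#'
#' Forward-simulates a half-bleach FRAP acquisition: the bleached-ROI
#' signal follows `m1 + m2 * exp(-m3 * x)` after the bleach (x = 0 at
#' the first post-bleach frame) with a flat pre-bleach level of 100;
#' every frame is attenuated by acquisition photobleaching
#' `exp(-acquisition_bleach_rate * frame)`, offset by a constant
#' background, and optionally perturbed by Gaussian noise on the
#' bleached ROI. The reference ROI (an unbleached cell) carries the
#' same acquisition decay, so the correction pipeline inverts the
#' drift exactly on noiseless traces.
#'
#' With `m1 + m2 = 0` (the default shape: bleached to 0), the planted
#' parameters are already on the normalized percent scale; in general
#' the normalized-scale parameters are returned in the ground truth
#' (`m1_norm = -m2_norm`, `m2_norm = 100 m2 / (100 - m1 - m2)`).
#'
#' @param m1 recovery plateau (percent of pre-bleach; default 80).
#' @param m2 amplitude (negative for recovery; default -80).
#' @param m3 off-rate in 1/s (default 0.1).
#' @param dt frame interval in seconds (acquisition designs: 0.33 or
#'   10).
#' @param n_pre pre-bleach frames (default 5).
#' @param n_post post-bleach frames (150 for the fast design, 70 for
#'   the slow one).
#' @param acquisition_bleach_rate per-frame acquisition bleaching rate
#'   (default 0).
#' @param background_level constant background intensity (default 0).
#' @param noise_sd Gaussian noise sd on the bleached ROI (default 0).
#' @param reference_level unbleached-cell intensity (default 150).
#' @param seed RNG seed (noise only).
#' @return list with `trace` (a [frap_trace()]) and `truth` (planted
#'   parameters, normalized-scale parameters, clean normalized
#'   post-bleach series, `t_half`).
#' @export
make_frap_trace <- function(m1 = 80, m2 = -80, m3 = 0.1, dt = 0.33,
                            n_pre = 5L, n_post = 150L,
                            acquisition_bleach_rate = 0,
                            background_level = 0, noise_sd = 0,
                            reference_level = 150, seed = 1L) {
  if (m3 <= 0) stop("m3 must be > 0")
  set.seed(seed)
  n <- n_pre + n_post
  frame <- seq_len(n) - 1L
  times <- frame * dt
  x_post <- (seq_len(n_post) - 1L) * dt
  signal <- c(rep(100, n_pre), m1 + m2 * exp(-m3 * x_post))
  decay <- exp(-acquisition_bleach_rate * frame)
  bleach <- signal * decay + background_level
  if (noise_sd > 0) bleach <- bleach + stats::rnorm(n, 0, noise_sd)
  reference <- reference_level * decay + background_level
  trace <- frap_trace(times, bleach, reference,
                      rep(background_level, n), n_prebleach = n_pre)
  k <- 100 / (100 - m1 - m2)
  m2n <- m2 * k
  truth <- list(
    m1 = m1, m2 = m2, m3 = m3,
    m1_norm = -m2n, m2_norm = m2n, t_half = log(2) / m3,
    clean_normalized = (signal[(n_pre + 1):n] - (m1 + m2)) * k,
    dt = dt, n_pre = n_pre, n_post = n_post,
    acquisition_bleach_rate = acquisition_bleach_rate,
    background_level = background_level, noise_sd = noise_sd, seed = seed
  )
  list(trace = trace, truth = truth)
}
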