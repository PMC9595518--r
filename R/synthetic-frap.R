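#' Parameters for the FRAP series simulator
#'
#' Single-exponential recovery after an instantaneous bleach.  Defaults
#' emulate centrosomal photobleaching: ~0.7 s frame interval, ~50%
#' bleach depth and slow, partial recovery over tens of seconds.
#'
#' @param n_pre Pre-bleach frames.
#' @param n_post Post-bleach frames.
#' @param dt Frame interval, s.
#' @param plateau Pre-bleach intensity (arbitrary units, background-free).
#' @param bleach_depth Fraction of intensity lost at the bleach,
#'   in `(0, 1)`.
#' @param recovery_rate Recovery rate constant, 1/s.
#' @param mobile_fraction Fraction of the bleached signal that recovers,
#'   in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise (intensity units).
#' @param background Additive background (intensity units).
#' @param seed Integer RNG seed, or `NULL`.
#' @return Validated list of class `frap_sim_params`.
#' @export
frap_sim_params <- function(n_pre = 5, n_post = 43, dt = 0.7,
                            plateau = 100, bleach_depth = 0.5,
                            recovery_rate = 0.05, mobile_fraction = 0.4,
                            noise_sd = 0, background = 10, seed = NULL) {
  n_pre <- check_count(n_pre, "n_pre")
  n_post <- check_count(n_post, "n_post")
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(plateau, "plateau", positive = TRUE)
  check_fraction(bleach_depth, "bleach_depth", open_left = TRUE,
                 open_right = TRUE)
  check_scalar(recovery_rate, "recovery_rate", positive = TRUE)
  check_fraction(mobile_fraction, "mobile_fraction")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(background, "background", nonneg = TRUE)
  structure(as.list(environment()), class = "frap_sim_params")
}

#' Simulate a raw FRAP intensity series
#'
#' Pre-bleach frames sit at `plateau`; the bleach (at t = 0) drops the
#' signal by `bleach_depth`; recovery follows
#' `plateau * (1 - bleach_depth + mobile_fraction * bleach_depth *
#' (1 - exp(-recovery_rate t)))`.  Background and Gaussian noise are
#' added on top.  Deterministic under `params$seed`.
#'
#' @param params A [frap_sim_params()].
#' @return Data frame of class `frap_raw` with columns `time_s` (bleach
#'   at 0; pre-bleach times negative) and `intensity`; the generating
#'   parameters are attached as attribute `"ground_truth"`.
#' @export
#' @examples
#' raw <- simulate_frap(frap_sim_params(noise_sd = 1, seed = 1))
#' head(raw)
simulate_frap <- function(params) {
  stopifnot(inherits(params, "frap_sim_params"))
  p <- params
  maybe_set_seed(p$seed)
  t_pre <- -(p$n_pre:1) * p$dt
  t_post <- (0:(p$n_post - 1)) * p$dt
  sig_pre <- rep(p$plateau, p$n_pre)
  sig_post <- p$plateau * (1 - p$bleach_depth +
    p$mobile_fraction * p$bleach_depth * (1 - exp(-p$recovery_rate * t_post)))
  y <- c(sig_pre, sig_post) + p$background
  if (p$noise_sd > 0) y <- y + rnorm(length(y), 0, p$noise_sd)
  out <- data.frame(time_s = c(t_pre, t_post), intensity = y)
  structure(out, class = c("frap_raw", "data.frame"), ground_truth = p)
}
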