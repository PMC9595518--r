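#' Parameters for the FCS trace simulator
#'
#' Defines a population of Brownian fluorescent emitters diffusing through
#' a 3D Gaussian observation volume, the generative model underlying
#' confocal FCS.  Defaults emulate a calibration measurement of a fast
#' organic dye (D ~ 521 um^2/s) in a confocal volume with a 225 nm lateral
#' waist and structural parameter 5.
#'
#' @param mean_particles_in_volume Expected number of emitters in the
#'   effective volume `pi^{3/2} w0^3 k` (dimensionless).
#' @param w0 Lateral 1/e^2 waist of the detection profile, um.
#' @param k Structural parameter (axial/lateral extent ratio).
#' @param D Diffusion coefficient, um^2/s.
#' @param brightness Detected counts per second for one emitter at the
#'   beam centre.
#' @param triplet_fraction Stationary dark-state (triplet) fraction,
#'   in `[0, 1)`.
#' @param triplet_lifetime Dark-state relaxation time, s.
#' @param duration Trace length, s.
#' @param sampling_frequency Bin rate, Hz.
#' @param background_rate Uncorrelated background, counts/s.
#' @param bleach_rate Exponential decay rate of per-particle brightness,
#'   1/s (0 disables bleaching).
#' @param box_multiplier Simulation-box side in units of `w0` laterally
#'   (and `k*w0` axially); must be >= 5 so the box dwarfs the
#'   detection volume.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return A validated list of class `fcs_sim_params`.
#' @export
#' @examples
#' p <- fcs_sim_params(duration = 0.05, seed = 1)
#' tr <- simulate_fcs_trace(p)
fcs_sim_params <- function(mean_particles_in_volume = 10,
                           w0 = 0.225, k = 5, D = 521.46,
                           brightness = 30000,
                           triplet_fraction = 0,
                           triplet_lifetime = 3e-6,
                           duration = 10,
                           sampling_frequency = 1e5,
                           background_rate = 500,
                           bleach_rate = 0,
                           box_multiplier = 5,
                           seed = NULL) {
  check_scalar(mean_particles_in_volume, "mean_particles_in_volume",
               nonneg = TRUE)
  check_scalar(w0, "w0", positive = TRUE)
  check_scalar(k, "k", positive = TRUE)
  check_scalar(D, "D", positive = TRUE)
  check_scalar(brightness, "brightness", positive = TRUE)
  check_fraction(triplet_fraction, "triplet_fraction", open_right = TRUE)
  check_scalar(triplet_lifetime, "triplet_lifetime", positive = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(sampling_frequency, "sampling_frequency", positive = TRUE)
  check_scalar(background_rate, "background_rate", nonneg = TRUE)
  check_scalar(bleach_rate, "bleach_rate", nonneg = TRUE)
  check_scalar(box_multiplier, "box_multiplier", positive = TRUE)
  if (box_multiplier < 5)
    stop_param("box_multiplier must be >= 5")
  structure(as.list(environment()), class = "fcs_sim_params")
}

#' Effective confocal volume from waist and structural parameter
#'
#' `V = pi^{3/2} w0^3 k`, returned in litres (1 um^3 = 1e-15 L).
#'
#' @param w0 Lateral waist, um.
#' @param k Structural parameter.
#' @return Effective volume in litres.
#' @export
#' @examples
#' effective_volume_litres(0.225, 5) # ~3.17e-16 L = 0.317 fL
effective_volume_litres <- function(w0, k) {
  check_scalar(w0, "w0", positive = TRUE)
  check_scalar(k, "k", positive = TRUE)
  pi^1.5 * w0^3 * k * 1e-15
}

#' Simulate an FCS photon-count trace
#'
#' Draws a Poisson number of Brownian emitters in a periodic box around a
#' 3D Gaussian detection profile and integrates shot-noise-limited photon
#' counts per bin, with optional two-state (triplet-like) blinking and
#' exponential photobleaching.  Deterministic under `params$seed`.
#'
#' The per-bin expected count is
#' `sum_i B exp(-2(x_i^2+y_i^2)/w0^2 - 2 z_i^2/(k w0)^2) dt + bg dt`,
#' Poisson-sampled; the long-time mean rate is
#' `B * N_eff * 2^{-3/2} + bg` where `N_eff` is the expected number of
#' emitters in the effective volume.
#'
#' @param params An [fcs_sim_params()] object.
#' @return An [intensity_trace()] with attribute `"ground_truth"` holding
#'   the generating parameters and the realized particle number.
#' @export
simulate_fcs_trace <- function(params) {
  stopifnot(inherits(params, "fcs_sim_params"))
  p <- params
  maybe_set_seed(p$seed)
  dt <- 1 / p$sampling_frequency
  n_bins <- max(2L, floor(p$duration * p$sampling_frequency))
  L <- p$box_multiplier * p$w0          # lateral box side, um
  Lz <- p$box_multiplier * p$k * p$w0   # axial box side, um
  v_eff_um3 <- pi^1.5 * p$w0^3 * p$k
  density <- p$mean_particles_in_volume / v_eff_um3   # per um^3
  n_particles <- rpois(1L, density * L * L * Lz)
  counts <- if (n_particles > 0L) {
    sim_fcs_counts_cpp(n_particles, n_bins, dt,
                       sqrt(2 * p$D * dt), L, Lz, p$w0, p$k,
                       p$brightness, p$background_rate,
                       p$triplet_fraction, p$triplet_lifetime,
                       p$bleach_rate)
  } else {
    rpois(n_bins, p$background_rate * dt)
  }
  tr <- intensity_trace(counts, dt, label = "simulated")
  attr(tr, "ground_truth") <- list(params = p, n_particles = n_particles,
                                   tau_d = p$w0^2 / (4 * p$D))
  tr
}
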