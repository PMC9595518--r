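#' Parameters for the bead-track simulator
#'
#' 2D tracer-bead trajectories with Gaussian localization noise, in one
#' of three modes: `brownian` (free diffusion), `immobile` (beads fixed
#' to the substrate, as used to measure the tracking noise floor) or
#' `drifting` (diffusion plus constant velocity).  Defaults emulate
#' condensate microrheology: 10 s frame interval, 60-frame movies and a
#' bead diffusivity of 1.7e-4 um^2/s.
#'
#' @param n_tracks Number of tracks.
#' @param n_frames Frames per track (>= 2).
#' @param dt Frame interval, s.
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param localization_sigma Per-axis Gaussian localization noise, um.
#' @param drift_velocity Length-2 per-axis drift velocity, um/s
#'   (used in `drifting` mode).
#' @param mode One of `"brownian"`, `"immobile"`, `"drifting"`.
#' @param seed Integer RNG seed, or `NULL`.
#' @return Validated list of class `track_sim_params`.
#' @export
track_sim_params <- function(n_tracks = 51, n_frames = 60, dt = 10,
                             D = 1.7e-4, localization_sigma = 0.02,
                             drift_velocity = c(0, 0),
                             mode = c("brownian", "immobile", "drifting"),
                             seed = NULL) {
  n_tracks <- check_count(n_tracks, "n_tracks")
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(D, "D", nonneg = TRUE)
  check_scalar(localization_sigma, "localization_sigma", nonneg = TRUE)
  if (length(drift_velocity) != 2L || any(!is.finite(drift_velocity)))
    stop_param("drift_velocity must be a finite length-2 vector")
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "track_sim_params")
}

#' Simulate bead tracks
#'
#' True per-axis increments are `Normal(v dt, sqrt(2 D dt))` (`immobile`
#' fixes the true position); reported positions add independent
#' `Normal(0, localization_sigma)` noise per axis and frame.
#' Deterministic under `params$seed`.
#'
#' @param params A [track_sim_params()].
#' @return A `track_set`: list of tracks, each a list with `track_id`,
#'   `frames` (0-based), `positions` (n x 2 matrix, um) and `dt` (s);
#'   the true (noise-free) positions are kept in `true_positions`.
#' @export
#' @examples
#' ts <- simulate_tracks(track_sim_params(n_tracks = 3, seed = 1))
#' length(ts)
simulate_tracks <- function(params) {
  stopifnot(inherits(params, "track_sim_params"))
  p <- params
  maybe_set_seed(p$seed)
  step_sd <- sqrt(2 * p$D * p$dt)
  drift <- if (p$mode == "drifting") p$drift_velocity * p$dt else c(0, 0)
  tracks <- lapply(seq_len(p$n_tracks), function(id) {
    origin <- runif(2, 0, 50)
    if (p$mode == "immobile") {
      true_pos <- matrix(origin, p$n_frames, 2, byrow = TRUE)
    } else {
      inc <- matrix(rnorm(2 * (p$n_frames - 1), mean = rep(drift,
                    each = p$n_frames - 1), sd = step_sd),
                    ncol = 2)
      steps <- rbind(c(0, 0), apply(inc, 2, cumsum))
      true_pos <- sweep(steps, 2, origin, `+`)
      dimnames(true_pos) <- NULL
    }
    obs <- true_pos
    if (p$localization_sigma > 0)
      obs <- obs + matrix(rnorm(2 * p$n_frames, 0, p$localization_sigma),
                          ncol = 2)
    new_track(id, 0:(p$n_frames - 1), obs, p$dt,
              true_positions = true_pos)
  })
  structure(tracks, class = "track_set", dt = p$dt, params = p)
}

#' Construct a single track
#'
#' @param track_id Identifier.
#' @param frames Strictly increasing integer frame indices (0-based).
#' @param positions n x 2 matrix of (x, y) positions in um.
#' @param dt Frame interval, s.
#' @param true_positions Optional noise-free positions (simulations).
#' @return Object of class `bead_track`.
#' @export
new_track <- function(track_id, frames, positions, dt,
                      true_positions = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop_param("positions must be n x 2")
  if (length(frames) != nrow(positions))
    stop_param("frames and positions must have equal length")
  if (any(diff(frames) <= 0)) stop_param("frames must be strictly increasing")
  if (any(!is.finite(positions))) stop_param("positions must be finite")
  check_scalar(dt, "dt", positive = TRUE)
  structure(list(track_id = track_id, frames = as.integer(frames),
                 positions = unname(positions), dt = dt,
                 true_positions = true_positions),
            class = "bead_track")
}
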