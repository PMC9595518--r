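#' Time-averaged mean squared displacement of a track
#'
#' `MSD(tau) = <[x(t+tau)-x(t)]^2 + [y(t+tau)-y(t)]^2>`, averaged over
#' all ordered pairs of time points at each delay (overlapping windows);
#' `n_pairs = length - lag`.
#'
#' @param track A [new_track()] object.
#' @param max_lag Largest delay in frames (default: length - 1).
#' @return Object of class `msd_curve`: data frame with `tau` (s),
#'   `msd` (um^2), `n_pairs`; the frame interval is attached as
#'   attribute `"dt"`.
#' @export
#' @examples
#' tr <- new_track(1, 0:9, cbind(0:9, 0), dt = 1)
#' compute_msd(tr)  # ballistic: msd = tau^2
compute_msd <- function(track, max_lag = NULL) {
  stopifnot(inherits(track, "bead_track"))
  n <- nrow(track$positions)
  if (n < 2L) stop_param("track must have at least 2 points")
  if (any(diff(track$frames) != 1L))
    stop_param("MSD requires consecutively tracked frames")
  if (is.null(max_lag)) max_lag <- n - 1L
  max_lag <- min(check_count(max_lag, "max_lag"), n - 1L)
  x <- track$positions[, 1]; y <- track$positions[, 2]
  lag <- seq_len(max_lag)
  msd <- vapply(lag, function(j) {
    dx <- x[(1 + j):n] - x[1:(n - j)]
    dy <- y[(1 + j):n] - y[1:(n - j)]
    mean(dx^2 + dy^2)
  }, 1.0)
  structure(data.frame(tau = lag * track$dt, msd = msd, n_pairs = n - lag),
            class = c("msd_curve", "data.frame"), dt = track$dt)
}

#' Ensemble-mean MSD across tracks
#'
#' Pointwise weighted mean of per-track time-averaged MSDs, weighted by
#' the number of displacement pairs contributing at each delay.
#'
#' @param tracks A `track_set` or list of `bead_track`s with a common
#'   frame interval.
#' @param max_lag Largest delay in frames.
#' @return An `msd_curve` with summed `n_pairs`.
#' @export
ensemble_msd <- function(tracks, max_lag = NULL) {
  stopifnot(length(tracks) >= 1L)
  curves <- lapply(tracks, compute_msd, max_lag = max_lag)
  dt <- attr(curves[[1]], "dt")
  taus <- sort(unique(unlist(lapply(curves, function(cc) cc$tau))))
  msd <- wt <- numeric(length(taus))
  for (cc in curves) {
    i <- match(cc$tau, taus)
    msd[i] <- msd[i] + cc$msd * cc$n_pairs
    wt[i] <- wt[i] + cc$n_pairs
  }
  structure(data.frame(tau = taus, msd = msd / wt, n_pairs = wt),
            class = c("msd_curve", "data.frame"), dt = dt)
}

#' Drift-correct a set of tracks
#'
#' `ensemble` mode subtracts the per-frame mean displacement over all
#' tracks present in consecutive frame pairs (common-mode stage/sample
#' drift); `per_track_velocity` subtracts each track's least-squares
#' linear position trend.  With a single track, `ensemble` falls back to
#' `per_track_velocity` with a warning.  The applied mode is recorded in
#' attribute `"drift_mode"`.
#'
#' @param tracks A `track_set` or list of `bead_track`s.
#' @param mode `"none"`, `"ensemble"` or `"per_track_velocity"`.
#' @return The corrected track list (same classes and attributes).
#' @export
drift_correct <- function(tracks,
                          mode = c("ensemble", "per_track_velocity",
                                   "none")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    attr(tracks, "drift_mode") <- "none"
    return(tracks)
  }
  if (mode == "ensemble" && length(tracks) < 2L) {
    warning("ensemble drift correction needs >= 2 tracks; using per_track_velocity")
    mode <- "per_track_velocity"
  }
  out <- if (mode == "ensemble") .drift_ensemble(tracks)
         else lapply(tracks, .drift_velocity)
  attributes(out) <- attributes(tracks)
  attr(out, "drift_mode") <- mode
  out
}

.drift_velocity <- function(tr) {
  t <- tr$frames * tr$dt
  for (ax in 1:2) {
    fit <- lm(tr$positions[, ax] ~ t)
    tr$positions[, ax] <- tr$positions[, ax] -
      (coef(fit)[2] * t)          # remove the velocity, keep the origin
  }
  tr
}

.drift_ensemble <- function(tracks) {
  frames <- sort(unique(unlist(lapply(tracks, function(tr) tr$frames))))
  # mean displacement into each frame, over tracks present in both frames
  disp <- matrix(0, length(frames), 2)
  for (i in seq_along(frames)[-1]) {
    f0 <- frames[i - 1]; f1 <- frames[i]
    d <- do.call(rbind, lapply(tracks, function(tr) {
      j0 <- match(f0, tr$frames); j1 <- match(f1, tr$frames)
      if (is.na(j0) || is.na(j1)) return(NULL)
      tr$positions[j1, ] - tr$positions[j0, ]
    }))
    if (!is.null(d)) disp[i, ] <- colMeans(d)
  }
  cum <- apply(disp, 2, cumsum)
  lapply(tracks, function(tr) {
    i <- match(tr$frames, frames)
    tr$positions <- tr$positions - cum[i, , drop = FALSE]
    tr
  })
}

#' Filter tracks by length and directed-motion exclusion
#'
#' Discards tracks with fewer than `min_length` consecutively tracked
#' spots (a track of exactly `min_length` is kept).  With
#' `exclude_directed = TRUE`, tracks showing rapid directional transport
#' rather than diffusion are also removed, using an explicit automated
#' rule: straightness index (net displacement / path length) > 0.6 AND
#' fitted anomaly exponent alpha > 1.5.
#'
#' @param tracks A `track_set` or list of `bead_track`s.
#' @param min_length Minimum number of spots (default 60).
#' @param exclude_directed Apply the directed-motion rule.
#' @param straightness_max Straightness threshold of the rule.
#' @param alpha_max Alpha threshold of the rule.
#' @return Filtered track list with attribute `"rejections"`: data frame
#'   (`track_id`, `reason`) logging every removal.
#' @export
filter_tracks <- function(tracks, min_length = 60L,
                          exclude_directed = FALSE,
                          straightness_max = 0.6, alpha_max = 1.5) {
  min_length <- check_count(min_length, "min_length", min = 2L)
  keep <- logical(length(tracks))
  rej <- list()
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (nrow(tr$positions) < min_length) {
      rej[[length(rej) + 1L]] <- data.frame(track_id = tr$track_id,
                                           reason = "too_short")
      next
    }
    if (isTRUE(exclude_directed)) {
      steps <- diff(tr$positions)
      path <- sum(sqrt(rowSums(steps^2)))
      net <- sqrt(sum((tr$positions[nrow(tr$positions), ] -
                         tr$positions[1, ])^2))
      straight <- if (path > 0) net / path else 0
      a <- tryCatch(fit_alpha(compute_msd(tr)), error = function(e) NA_real_)
      if (straight > straightness_max && !is.na(a) && a > alpha_max) {
        rej[[length(rej) + 1L]] <- data.frame(track_id = tr$track_id,
                                             reason = "directed_motion")
        next
      }
    }
    keep[i] <- TRUE
  }
  out <- tracks[keep]
  attributes(out) <- c(attributes(tracks)[setdiff(names(attributes(tracks)),
                                                  "names")],
                       list(rejections = if (length(rej))
                         do.call(rbind, rej)
                         else data.frame(track_id = character(),
                                         reason = character())))
  class(out) <- class(tracks)
  out
}

#' Diffusion coefficient from the short-delay MSD
#'
#' Weighted straight-line fit (weights = pair counts) of MSD against
#' delay over the first `fraction` of delays; `D = slope / 4`.  The
#' intercept is free so static localization error (which offsets the MSD
#' by 4 sigma^2) does not bias D.  A negative fitted slope is reported
#' as `D = 0` with `flagged = TRUE`.
#'
#' @param msd An `msd_curve`.
#' @param fraction Fraction of delays to fit (default 0.25).
#' @return List with `D` (um^2/s), `slope`, `intercept` (um^2),
#'   `fit_fraction`, `n_delays`, `flagged`.
#' @export
#' @examples
#' m <- structure(data.frame(tau = 1:20, msd = 4 * 0.1 * (1:20) + 0.01,
#'                           n_pairs = 20:1),
#'                class = c("msd_curve", "data.frame"))
#' fit_diffusion(m)$D  # 0.1
fit_diffusion <- function(msd, fraction = 0.25) {
  stopifnot(inherits(msd, "msd_curve"))
  check_fraction(fraction, "fraction", open_left = TRUE)
  n_fit <- max(3L, floor(nrow(msd) * fraction))
  if (n_fit > nrow(msd))
    stop_param("too few delays for the requested fit fraction")
  d <- msd[seq_len(n_fit), ]
  fit <- lm(msd ~ tau, data = d, weights = d$n_pairs)
  slope <- unname(coef(fit)[2])
  flagged <- slope < 0
  list(D = max(slope, 0) / 4, slope = slope,
       intercept = unname(coef(fit)[1]),
       fit_fraction = fraction, n_delays = n_fit, flagged = flagged)
}

#' Anomalous diffusion exponent from a log-log MSD fit
#'
#' Least-squares slope of `log(MSD)` against `log(tau)` over the first
#' `fraction` of delays; alpha = 1 indicates Brownian diffusion in a
#' viscous fluid, alpha = 2 ballistic transport.
#'
#' @param msd An `msd_curve` with positive MSD over the fitted range.
#' @param fraction Fraction of delays to fit (default 0.25).
#' @return The exponent alpha.
#' @export
fit_alpha <- function(msd, fraction = 0.25) {
  stopifnot(inherits(msd, "msd_curve"))
  check_fraction(fraction, "fraction", open_left = TRUE)
  n_fit <- max(3L, floor(nrow(msd) * fraction))
  n_fit <- min(n_fit, nrow(msd))
  d <- msd[seq_len(n_fit), ]
  if (any(d$msd <= 0))
    stop(errorCondition("MSD must be positive over the fitted range",
                        class = c("condensorheo_degenerate_error",
                                  "error", "condition")))
  unname(coef(lm(log(msd) ~ log(tau), data = d))[2])
}

#' Stokes-Einstein viscosity from a diffusion coefficient
#'
#' `eta = kB T / (6 pi D R)` with `kB = 1.380649e-23 J/K`; `D` is
#' converted from um^2/s to m^2/s internally.  If `D` does not exceed
#' `noise_floor`, the result is flagged: apparent motion at or below the
#' immobilized-bead level cannot be interpreted as diffusion.
#'
#' @param D Diffusion coefficient, um^2/s (> 0).
#' @param R Bead radius, m (default 87.5e-9: nominal 175 nm
#'   polystyrene beads).
#' @param T_k Temperature, K (default 310.15: imaging at 37 C).
#' @param noise_floor Apparent D of immobilized beads, um^2/s.
#' @return Object of class `viscosity_result`: `eta` (Pa s), `D`, `R`,
#'   `T_k`, `noise_floor`, `below_noise_floor`.
#' @export
#' @examples
#' stokes_einstein(1.7e-4, R = 87.5e-9, T_k = 310.15)$eta  # ~15.3 Pa s
stokes_einstein <- function(D, R = 87.5e-9, T_k = 310.15,
                            noise_floor = 1.5e-6) {
  check_scalar(D, "D", positive = TRUE)
  check_scalar(R, "R", positive = TRUE)
  check_scalar(T_k, "T_k", positive = TRUE)
  check_scalar(noise_floor, "noise_floor", nonneg = TRUE)
  D_si <- D * 1e-12                      # um^2/s -> m^2/s
  eta <- .const$boltzmann * T_k / (6 * pi * D_si * R)
  structure(list(eta = eta, D = D, R = R, T_k = T_k,
                 noise_floor = noise_floor,
                 below_noise_floor = D <= noise_floor),
            class = "viscosity_result")
}

#' @export
print.viscosity_result <- function(x, ...) {
  cat(sprintf("<viscosity_result> eta = %.4g Pa s (D = %.3g um^2/s, R = %.3g m, T = %.4g K)%s\n",
              x$eta, x$D, x$R, x$T_k,
              if (x$below_noise_floor) "  [BELOW NOISE FLOOR]" else ""))
  invisible(x)
}

#' Invert Stokes-Einstein: diffusion coefficient from a viscosity
#'
#' @param eta Viscosity, Pa s.
#' @param R Bead radius, m.
#' @param T_k Temperature, K.
#' @return D in um^2/s.
#' @export
stokes_einstein_D <- function(eta, R = 87.5e-9, T_k = 310.15) {
  check_scalar(eta, "eta", positive = TRUE)
  check_scalar(R, "R", positive = TRUE)
  check_scalar(T_k, "T_k", positive = TRUE)
  .const$boltzmann * T_k / (6 * pi * eta * R) * 1e12
}

#' Tracking noise floor from immobilized beads
#'
#' Pooled short-delay diffusion fit over tracks of beads dried to the
#' substrate.  Their ensemble MSD is a plateau of `4 sigma^2` set by
#' localization error, so the fitted slope-based D is the apparent
#' diffusion one would measure for a perfectly still particle — the
#' floor below which measured D values are not interpretable.
#'
#' @param tracks Immobile-bead tracks (`track_set` or list).
#' @param fraction Fit fraction passed to [fit_diffusion()].
#' @return List with `D_floor` (um^2/s, >= 0), `intercept` (um^2; the
#'   localization plateau) and `n_tracks`.
#' @export
noise_floor_from_immobile <- function(tracks, fraction = 0.25) {
  if (length(tracks) < 1L) stop_param("need at least one immobile track")
  pooled <- ensemble_msd(tracks)
  fit <- fit_diffusion(pooled, fraction)
  list(D_floor = fit$D, intercept = fit$intercept,
       n_tracks = length(tracks))
}
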