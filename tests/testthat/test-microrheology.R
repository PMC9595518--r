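test_that("MSD equals the brute-force double-loop oracle", {
  set.seed(12)
  for (n in c(5, 10, 60, 100)) {
    pos <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))
    tr <- new_track(1, 0:(n - 1), pos, dt = 2)
    msd <- compute_msd(tr)
    expect_equal(msd$msd, oracle_msd(pos, 2), tolerance = 1e-12)
    expect_equal(msd$n_pairs, n - seq_len(n - 1))
    expect_equal(msd$tau, 2 * seq_len(n - 1))
  }
})

test_that("MSD is invariant under rigid motion and zero for stationary tracks", {
  set.seed(13)
  pos <- cbind(cumsum(rnorm(30)), cumsum(rnorm(30)))
  tr <- new_track(1, 0:29, pos, dt = 1)
  msd0 <- compute_msd(tr)$msd
  # translation
  expect_equal(compute_msd(new_track(1, 0:29, pos + 100, 1))$msd, msd0,
               tolerance = 1e-10)
  # rotation by 37 degrees
  th <- 37 * pi / 180
  rot <- pos %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  expect_equal(compute_msd(new_track(1, 0:29, rot, 1))$msd, msd0,
               tolerance = 1e-10)
  still <- new_track(1, 0:9, matrix(3, 10, 2), 1)
  expect_true(all(compute_msd(still)$msd == 0))
})

test_that("diffusion fit recovers slope/4 with a free intercept", {
  tau <- 1:40
  mk <- function(msd) structure(data.frame(tau = tau, msd = msd,
                                           n_pairs = 41 - tau),
                                class = c("msd_curve", "data.frame"),
                                dt = 1)
  expect_equal(fit_diffusion(mk(4 * 0.1 * tau))$D, 0.1, tolerance = 1e-12)
  f <- fit_diffusion(mk(4 * 0.1 * tau + 0.01))
  expect_equal(f$D, 0.1, tolerance = 1e-12)
  expect_equal(f$intercept, 0.01, tolerance = 1e-10)
  neg <- fit_diffusion(mk(1 - 0.01 * tau))
  expect_equal(neg$D, 0)
  expect_true(neg$flagged)
})

test_that("alpha fit identifies diffusive and ballistic scaling", {
  tau <- 1:40
  mk <- function(msd) structure(data.frame(tau = tau, msd = msd,
                                           n_pairs = 41 - tau),
                                class = c("msd_curve", "data.frame"),
                                dt = 1)
  expect_equal(fit_alpha(mk(0.4 * tau)), 1, tolerance = 1e-12)
  expect_equal(fit_alpha(mk(0.4 * tau^2)), 2, tolerance = 1e-12)
  expect_error(fit_alpha(mk(c(0, 0.4 * tau[-1]))),
               class = "condensorheo_degenerate_error")
})

test_that("length filter is strict below 60 and keeps exactly 60", {
  mk <- function(n, id) new_track(id, 0:(n - 1),
                                  matrix(rnorm(2 * n), ncol = 2), 10)
  set.seed(14)
  ts <- structure(list(mk(59, 1), mk(60, 2), mk(61, 3)),
                  class = "track_set", dt = 10)
  out <- filter_tracks(ts, min_length = 60)
  expect_equal(vapply(out, function(tr) tr$track_id, 1), c(2, 3))
  rej <- attr(out, "rejections")
  expect_equal(rej$track_id, 1)
  expect_equal(rej$reason, "too_short")
})

test_that("directed-motion rule rejects ballistic but keeps brownian tracks", {
  drift <- simulate_tracks(track_sim_params(n_tracks = 1, n_frames = 60,
                                            dt = 10, D = 0,
                                            localization_sigma = 0.001,
                                            drift_velocity = c(0.01, 0),
                                            mode = "drifting", seed = 7))
  out <- filter_tracks(drift, min_length = 60, exclude_directed = TRUE)
  expect_length(out, 0)
  expect_equal(attr(out, "rejections")$reason, "directed_motion")
  brown <- simulate_tracks(track_sim_params(n_tracks = 100, n_frames = 60,
                                            dt = 10, D = 1.7e-4,
                                            localization_sigma = 0.02,
                                            seed = 8))
  kept <- filter_tracks(brown, min_length = 60, exclude_directed = TRUE)
  expect_gte(length(kept), 95)
})

test_that("drift correction removes common and per-track drift", {
  # common constant drift over many tracks, ensemble mode
  p0 <- track_sim_params(n_tracks = 60, n_frames = 60, dt = 10,
                         D = 1e-3, localization_sigma = 0, seed = 9)
  ts0 <- simulate_tracks(p0)
  v <- c(0.002, -0.001)
  drifted <- lapply(ts0, function(tr) {
    tr$positions <- tr$positions +
      outer(tr$frames * tr$dt, v)
    tr
  })
  class(drifted) <- "track_set"; attr(drifted, "dt") <- 10
  corr <- drift_correct(drifted, mode = "ensemble")
  m0 <- ensemble_msd(ts0); mc <- ensemble_msd(corr)
  q <- m0$tau <= 150
  expect_lt(max(abs(mc$msd[q] - m0$msd[q]) / m0$msd[q]), 0.05)
  # single ballistic track, per-track velocity mode
  ball <- new_track(1, 0:59, outer(0:59, c(0.1, 0.05)), 10)
  bc <- drift_correct(list(ball), mode = "per_track_velocity")
  expect_lt(max(compute_msd(bc[[1]])$msd), 1e-18)
  # ensemble mode with one track falls back with a warning
  expect_warning(drift_correct(list(ball), mode = "ensemble"))
})

test_that("Stokes-Einstein converts D to viscosity with SI constants", {
  v <- stokes_einstein(1.7e-4, R = 87.5e-9, T_k = 310.15)
  manual <- 1.380649e-23 * 310.15 / (6 * pi * 1.7e-16 * 87.5e-9)
  expect_equal(v$eta, manual, tolerance = 1e-12)
  expect_false(v$below_noise_floor)
  # proportionality
  expect_equal(stokes_einstein(3.4e-4)$eta, v$eta / 2, tolerance = 1e-9)
  # inverse: water viscosity at 21 C gives D ~ 2.46 um^2/s
  D_water <- stokes_einstein_D(1.0e-3, R = 87.5e-9, T_k = 294.15)
  expect_equal(D_water, 2.46, tolerance = 0.01)
  # round trip identity
  expect_equal(stokes_einstein_D(v$eta, 87.5e-9, 310.15), 1.7e-4,
               tolerance = 1e-12)
  # noise-floor flagging
  expect_true(stokes_einstein(1e-6)$below_noise_floor)
})

test_that("noise floor from immobile beads is near zero with a 4 sigma^2 plateau", {
  still <- simulate_tracks(track_sim_params(n_tracks = 20, n_frames = 60,
                                            dt = 10, localization_sigma = 0,
                                            mode = "immobile", seed = 10))
  expect_equal(noise_floor_from_immobile(still)$D_floor, 0)
  noisy <- simulate_tracks(track_sim_params(n_tracks = 50, n_frames = 60,
                                            dt = 10,
                                            localization_sigma = 0.02,
                                            mode = "immobile", seed = 11))
  nf <- noise_floor_from_immobile(noisy)
  expect_lt(nf$D_floor, 1e-5)
  expect_equal(nf$intercept, 4 * 0.02^2, tolerance = 0.3)
})
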