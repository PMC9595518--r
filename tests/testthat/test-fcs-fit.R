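test_that("triplet model fit is exact on a noiseless model curve", {
  tau <- 10^seq(-6.5, -1, length.out = 60)
  truth <- list(N = 10, tau_d = 25e-6, theta_t = 0.2, tau_t = 2e-6, k = 5)
  cc <- model_curve(tau, do.call(fcs_model_triplet, c(list(tau), truth)))
  fit <- fit_triplet_diffusion(cc)
  expect_true(fit$converged)
  for (nm in names(truth))
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-6)
  expect_lt(fit$goodness$rss, 1e-10)
})

test_that("with theta_t pinned to zero the zero-lag amplitude is 1/N", {
  tau <- 10^seq(-6, -1, length.out = 50)
  cc <- model_curve(tau, fcs_model_triplet(tau, N = 7, tau_d = 1e-4,
                                           theta_t = 0, k = 5))
  fit <- fit_triplet_diffusion(cc, fixed = list(theta_t = 0, tau_t = 1e-6))
  g0 <- fcs_model_triplet(1e-12, fit$params$N, fit$params$tau_d,
                          fit$params$theta_t, fit$params$tau_t,
                          fit$params$k)
  expect_equal(g0, 1 / fit$params$N, tolerance = 1e-6)
  expect_equal(fit$params$N, 7, tolerance = 1e-6)
})

test_that("anomalous model fit is exact and nests simple diffusion", {
  tau <- 10^seq(-6, 0, length.out = 60)
  truth <- list(N = 4, tau_d = 1e-3, alpha = 0.8, theta_t = 0.1,
                tau_t = 5e-5, k = 5)
  cc <- model_curve(tau, fcs_model_anomalous(tau, truth$N, truth$tau_d,
                                             truth$alpha, truth$theta_t,
                                             truth$tau_t, truth$k))
  fit <- fit_anomalous_blinking(cc)
  expect_true(fit$converged)
  for (nm in names(truth))
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-5)

  # nesting: alpha = 1, no blinking -> same shape as the simple
  # diffusion factor; both fits agree on N and tau_d
  cc1 <- model_curve(tau, fcs_model_anomalous(tau, N = 6, tau_d = 2e-4,
                                              alpha = 1, theta_t = 0, k = 5))
  fa <- fit_anomalous_blinking(cc1, fixed = list(alpha = 1, theta_t = 0,
                                                 tau_t = 1e-6))
  ft <- fit_triplet_diffusion(cc1, fixed = list(theta_t = 0,
                                                tau_t = 1e-6))
  expect_equal(fa$params$N, ft$params$N, tolerance = 1e-6)
  expect_equal(fa$params$tau_d, ft$params$tau_d, tolerance = 1e-6)
})

test_that("simulated dye trace recovers tau_D = w0^2/(4 D) within 15%", {
  p <- fcs_sim_params(mean_particles_in_volume = 5, D = 521.46,
                      duration = 0.5, sampling_frequency = 1e6,
                      brightness = 50000, background_rate = 0, seed = 11)
  tr <- simulate_fcs_trace(p)
  cc <- compute_autocorrelation(tr, base_frequency = 1e6)
  fit <- fit_triplet_diffusion(cc, fixed = list(theta_t = 0,
                                                tau_t = 1e-6, k = 5))
  tau_d_true <- 0.225^2 / (4 * 521.46)      # 24.3 us
  expect_true(fit$converged)
  expect_lt(abs(fit$params$tau_d - tau_d_true) / tau_d_true, 0.15)
})

test_that("G amplitude scales as 1/N across emitter densities", {
  fit_n <- function(N, seed) {
    p <- fcs_sim_params(mean_particles_in_volume = N, D = 20,
                        duration = 5, sampling_frequency = 5e3,
                        brightness = 30000, background_rate = 0,
                        seed = seed)
    cc <- compute_autocorrelation(simulate_fcs_trace(p), 5e3)
    fit <- fit_triplet_diffusion(cc, fixed = list(theta_t = 0,
                                                  tau_t = 1e-5, k = 5))
    fit$params$N
  }
  n1 <- fit_n(5, 31)
  n2 <- fit_n(10, 32)
  expect_lt(abs(n1 / 5 - 1), 0.25)
  expect_lt(abs(n2 / 10 - 1), 0.25)
  expect_lt(abs(n2 / n1 - 2), 0.5)
})

test_that("degenerate curves are rejected with parameter errors", {
  tau <- 10^seq(-6, -5, length.out = 10)   # less than two decades
  cc <- model_curve(tau, fcs_model_triplet(tau, 10, 1e-4))
  expect_error(fit_triplet_diffusion(cc),
               class = "condensorheo_param_error")
  cc2 <- model_curve(10^seq(-6, -1, length.out = 5),
                     rep(0.1, 5))          # fewer than 8 lags
  expect_error(fit_triplet_diffusion(cc2),
               class = "condensorheo_param_error")
})
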