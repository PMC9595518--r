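test_that("min-max normalization maps extrema to exactly 0 and 100", {
  raw <- data.frame(time_s = c(-1, 0, 1, 2), intensity = c(4, 1, 2.5, 4))
  s <- normalize_frap(raw, background = 0)
  expect_equal(s$intensity, c(100, 0, 50, 100))
  # invariance under a common shift of signal and background
  s2 <- normalize_frap(transform(raw, intensity = intensity + 33),
                       background = 33)
  expect_equal(s2$intensity, s$intensity)
  # degenerate constant series
  expect_error(normalize_frap(data.frame(time_s = -1:2,
                                         intensity = rep(5, 4)), 0),
               class = "condensorheo_degenerate_error")
  expect_error(normalize_frap(raw[raw$time_s >= 0, ], 0),
               class = "condensorheo_param_error")
})

test_that("generator edge cases behave as closed forms predict", {
  # immobile pool: post-bleach series constant
  raw0 <- simulate_frap(frap_sim_params(mobile_fraction = 0, noise_sd = 0,
                                        seed = 1))
  post <- raw0$intensity[raw0$time_s >= 0]
  expect_lt(diff(range(post)), 1e-12)
  # fully mobile pool: asymptote returns to the pre-bleach plateau
  raw1 <- simulate_frap(frap_sim_params(mobile_fraction = 1, noise_sd = 0,
                                        recovery_rate = 0.5, n_post = 200,
                                        seed = 1))
  expect_equal(max(raw1$intensity[raw1$time_s > 50]),
               raw1$intensity[1], tolerance = 1e-6)
  # normalized asymptote equals 100 * mobile_fraction
  p <- frap_sim_params(mobile_fraction = 0.4, noise_sd = 0,
                       recovery_rate = 0.2, n_post = 300, seed = 1)
  s <- normalize_frap(simulate_frap(p), background = p$background)
  late <- s$intensity[s$time_s > 100]
  expect_equal(mean(late), 40, tolerance = 0.5)
})

test_that("halftime fit inverts the closed form t1/2 = ln2 / k", {
  t <- seq(0, 60, 0.5)
  s <- structure(data.frame(time_s = c(-2, -1, t),
                            intensity = c(100, 100,
                                          100 * (1 - exp(-0.1 * t)))),
                 class = c("frap_series", "data.frame"))
  fit <- recovery_halftime(s)
  expect_equal(fit$k, 0.1, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) / 0.1, tolerance = 1e-5)
  expect_equal(fit$A, 100, tolerance = 1e-4)
})

test_that("rate and mobile fraction are recovered from 30 noisy curves", {
  p0 <- frap_sim_params(noise_sd = 2)   # 2% of the plateau
  curves <- lapply(1:30, function(i) {
    p <- frap_sim_params(noise_sd = 2, seed = 1000 + i)
    normalize_frap(simulate_frap(p), background = p$background)
  })
  m <- mean_recovery(curves)
  expect_equal(nrow(m), length(curves[[1]]$time_s))
  fit <- recovery_halftime(data.frame(time_s = m$time_s,
                                      intensity = m$mean))
  expect_lt(abs(fit$k - p0$recovery_rate) / p0$recovery_rate, 0.10)
  expect_lt(abs(fit$mobile_fraction - p0$mobile_fraction) /
              p0$mobile_fraction, 0.10)
})

test_that("fitted rate is monotone in the generator recovery rate", {
  ks <- vapply(c(0.02, 0.05, 0.12), function(kr) {
    p <- frap_sim_params(recovery_rate = kr, noise_sd = 1, seed = 77)
    s <- normalize_frap(simulate_frap(p), background = p$background)
    recovery_halftime(s)$k
  }, 1.0)
  expect_true(all(diff(ks) > 0))
})

test_that("mean recovery pools curves pointwise with dispersion", {
  a <- data.frame(time_s = c(-1, 0, 1), intensity = c(0, 0, 0))
  b <- data.frame(time_s = c(-1, 0, 1), intensity = c(100, 100, 100))
  m <- mean_recovery(list(a, b))
  expect_equal(m$mean, c(50, 50, 50))
  expect_equal(m$sd, rep(sd(c(0, 100)), 3))
  # identical curves: zero dispersion
  m2 <- mean_recovery(list(a, a, a))
  expect_equal(m2$mean, a$intensity)
  expect_true(all(m2$sd == 0))
  expect_error(mean_recovery(list()), class = "condensorheo_param_error")
  # CLT: mean of 30 noisy curves within 3 SEM of the noiseless curve
  p_clean <- frap_sim_params(noise_sd = 0)
  clean <- normalize_frap(simulate_frap(p_clean),
                          background = p_clean$background)
  curves <- lapply(1:30, function(i) {
    p <- frap_sim_params(noise_sd = 2, seed = 400 + i)
    normalize_frap(simulate_frap(p), background = p$background)
  })
  m3 <- mean_recovery(curves)
  sem <- m3$sd / sqrt(m3$n)
  # min-max pinning biases each noisy curve near its extrema (the noisy
  # minimum is mapped to exactly 0), so the unbiased-CLT band applies
  # away from the bleach point; allow that bias explicitly
  away <- m3$time_s >= 5
  inside <- abs(m3$mean - clean$intensity) <= 3 * sem + 1.5
  expect_true(all(inside[away]))
  expect_lt(sqrt(mean((m3$mean - clean$intensity)^2)), 3)
})
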