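# Independent reference implementations used to validate the package's
# estimators on small inputs.

# Brute-force time-averaged MSD by explicit double loop.
oracle_msd <- function(positions, dt) {
  n <- nrow(positions)
  vapply(seq_len(n - 1), function(j) {
    s <- 0
    for (t in seq_len(n - j))
      s <- s + sum((positions[t + j, ] - positions[t, ])^2)
    s / (n - j)
  }, 1.0)
}

# Textbook two-sample t statistics.
oracle_t_unpaired <- function(a, b) {
  sp <- sqrt(var(a) / length(a) + var(b) / length(b))
  (mean(a) - mean(b)) / sp
}
oracle_t_paired <- function(a, b) {
  d <- a - b
  mean(d) / (sd(d) / sqrt(length(d)))
}

# Numeric-integration oracle for the mean detection efficiency of a 3D
# Gaussian profile averaged over the simulation box (midpoint rule).
oracle_box_mean_profile <- function(w0, k, box_multiplier, n_grid = 201) {
  L <- box_multiplier * w0
  Lz <- box_multiplier * k * w0
  gx <- seq(-L / 2, L / 2, length.out = n_grid)
  gz <- seq(-Lz / 2, Lz / 2, length.out = n_grid)
  fx <- mean(exp(-2 * gx^2 / w0^2))        # separable profile
  fz <- mean(exp(-2 * gz^2 / (k * w0)^2))
  fx * fx * fz
}

# Noiseless correlation curve synthesized directly from a model function.
model_curve <- function(tau, g, n_pairs = 1000) {
  structure(data.frame(lag = tau, G = g, n_pairs = rep(n_pairs,
                                                       length(tau))),
            class = c("fcs_correlation", "data.frame"),
            base_frequency = 1 / min(tau), mean_rate = NA_real_)
}

# Rasterized filled ellipse mask (semi-axes in pixels).
ellipse_mask <- function(nr, nc, cx, cy, a, b, theta = 0) {
  m <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    u <- (r - cx) * cos(theta) + (cc - cy) * sin(theta)
    v <- -(r - cx) * sin(theta) + (cc - cy) * cos(theta)
    if ((u / a)^2 + (v / b)^2 <= 1) m[r, cc] <- 1L
  }
  m
}

# Synthetic Gaussian blob image for spot-detection tests.
blob_image <- function(nr, nc, centers, sigma = 2, amplitude = 100,
                       offset = 5) {
  img <- matrix(offset, nr, nc)
  for (i in seq_len(nrow(centers)))
    img <- img + amplitude * exp(-((row(img) - centers[i, 1])^2 +
                                   (col(img) - centers[i, 2])^2) /
                                   (2 * sigma^2))
  img
}
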