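#' Multiple-tau autocorrelation of an intensity trace
#'
#' Estimates the normalized fluorescence autocorrelation
#' `G(tau) = <dI(t) dI(t+tau)> / <I>^2` on a semilogarithmic
#' (multiple-tau) lag ladder.  The trace is first rebinned to
#' `base_frequency`; the smallest reported lag is one rebinned interval.
#' Each lag uses the symmetrically normalized estimator
#' `G = mean(I_t I_{t+j}) / (mean_head * mean_tail) - 1`, which matches
#' the direct all-pairs estimator exactly at lags evaluated at full time
#' resolution; lags evaluated on coarse-grained levels carry the usual
#' small triangular-averaging bias of multiple-tau correlators.
#'
#' @param trace An [intensity_trace()].
#' @param base_frequency Rebinning frequency in Hz; must not exceed the
#'   trace sampling rate.  Typical values: 1e6 for fast dye calibration,
#'   1e5 for cellular measurements.
#' @param m Lags per correlator level (even; default 16).
#' @return Object of class `fcs_correlation`: data frame with columns
#'   `lag` (s), `G`, `n_pairs`, plus attributes `base_frequency` and
#'   `mean_rate` (counts/s).
#' @export
#' @examples
#' tr <- simulate_fcs_trace(fcs_sim_params(duration = 0.2, seed = 1))
#' cc <- compute_autocorrelation(tr, base_frequency = 1e5)
#' head(cc)
compute_autocorrelation <- function(trace, base_frequency = 1e5, m = 16L) {
  stopifnot(inherits(trace, "fcs_trace"))
  check_scalar(base_frequency, "base_frequency", positive = TRUE)
  m <- check_count(m, "m", min = 2L)
  if (m %% 2L != 0L) stop_param("m must be even")
  fs <- 1 / trace$bin_width
  if (base_frequency > fs * (1 + 1e-9))
    stop_param("base_frequency exceeds the trace sampling rate")
  factor <- round(fs / base_frequency)
  if (abs(fs / base_frequency - factor) > 1e-6)
    stop_param("sampling rate must be an integer multiple of base_frequency")
  counts <- rebin_counts(trace$counts, factor)
  if (mean(counts) == 0)
    stop(errorCondition("mean intensity is zero; G(tau) is undefined",
                        class = c("condensorheo_normalization_error",
                                  "error", "condition")))
  if (length(counts) < 2L + 1L)
    stop_param("trace too short for the smallest lag")
  res <- multitau_cpp(as.numeric(counts), as.integer(m))
  bin <- factor * trace$bin_width
  out <- data.frame(lag = res$lag_bins * bin, G = res$G,
                    n_pairs = res$n_pairs)
  structure(out,
            class = c("fcs_correlation", "data.frame"),
            base_frequency = base_frequency,
            mean_rate = mean(counts) / bin)
}

#' Average correlation curves with pair-count weights
#'
#' Combines repeated readings taken at the same position (e.g. four 10-s
#' acquisitions) into one curve: each curve is correlated separately and
#' G is averaged pointwise with `n_pairs` weights, which is robust to
#' slow drift between readings.
#'
#' @param curves List of `fcs_correlation` objects on identical lag grids.
#' @return A single `fcs_correlation` with summed `n_pairs`.
#' @export
average_correlations <- function(curves) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, TRUE, "fcs_correlation")))
  lag <- curves[[1]]$lag
  for (cc in curves)
    if (length(cc$lag) != length(lag) ||
        max(abs(cc$lag - lag) / lag) > 1e-9)
      stop_param("curves must share one lag grid")
  w <- vapply(curves, function(cc) cc$n_pairs, numeric(length(lag)))
  g <- vapply(curves, function(cc) cc$G, numeric(length(lag)))
  if (length(lag) == 1L) { w <- matrix(w, 1); g <- matrix(g, 1) }
  wsum <- rowSums(w)
  out <- data.frame(lag = lag, G = rowSums(g * w) / wsum, n_pairs = wsum)
  structure(out, class = c("fcs_correlation", "data.frame"),
            base_frequency = attr(curves[[1]], "base_frequency"),
            mean_rate = mean(vapply(curves, attr, 1.0, "mean_rate")))
}

#' Background and bleaching correction of an intensity trace
#'
#' Subtracts the expected background per bin and, optionally, removes a
#' slow monotone bleaching trend.  The trend `f(t)` is fitted to the
#' coarsely binned count rate (two-component exponential, falling back to
#' single-exponential and then to a constant on convergence failure) and
#' fluctuations are rescaled as
#' `I'(t) = (I(t) - f(t)) / sqrt(f(t)/f(0)) + f(0)`,
#' which restores a stationary mean and variance so the correlator sees
#' fluctuations rather than the decay.
#'
#' @param trace An [intensity_trace()].
#' @param background_rate Uncorrelated background in counts/s (subtracted
#'   as `background_rate * bin_width` per bin).  Determined in practice
#'   from cells without fluorophore.
#' @param detrend If `TRUE`, fit and remove a bleaching trend.
#' @param n_segments Number of coarse segments used for trend fitting.
#' @return The corrected `fcs_trace`, with attributes `trend` (fitted
#'   values per bin, or `NULL`), `trend_model` (`"none"`, `"constant"`,
#'   `"exp1"` or `"exp2"`) and `background_clipped` (`TRUE` if the
#'   requested background exceeded the mean rate and was clipped).
#' @export
correct_trace <- function(trace, background_rate = 0, detrend = FALSE,
                          n_segments = 100L) {
  stopifnot(inherits(trace, "fcs_trace"))
  check_scalar(background_rate, "background_rate", nonneg = TRUE)
  clipped <- FALSE
  bg_bin <- background_rate * trace$bin_width
  if (bg_bin > mean(trace$counts)) {
    warning("background exceeds the mean count rate; clipping to the mean")
    bg_bin <- mean(trace$counts)
    clipped <- TRUE
  }
  counts <- trace$counts - bg_bin
  trend <- NULL
  model <- "none"
  if (isTRUE(detrend)) {
    fitted <- fit_bleach_trend(counts, trace$bin_width, n_segments)
    trend <- fitted$trend
    model <- fitted$model
    f0 <- trend[1]
    if (f0 > 0 && all(trend > 0)) {
      counts <- (counts - trend) / sqrt(trend / f0) + f0
    }
  }
  out <- intensity_trace(pmax(counts, 0), trace$bin_width,
                         t0 = trace$times[1], label = trace$label)
  # keep sub-zero excursions: clipping individual bins would bias G, so
  # only means are protected; restore the unclipped values
  out$counts <- counts
  attr(out, "trend") <- trend
  attr(out, "trend_model") <- model
  attr(out, "background_clipped") <- clipped
  out
}

# Fit a monotone bleaching trend to a coarsely binned count rate.
# Returns per-original-bin fitted values and the model that converged.
fit_bleach_trend <- function(counts, bin_width, n_segments) {
  n <- length(counts)
  n_segments <- min(as.integer(n_segments), n)
  seg <- floor(n / n_segments)
  y <- rebin_counts(counts, seg) / seg            # mean counts per bin
  t_seg <- (seq_along(y) - 0.5) * seg * bin_width
  t_all <- (seq_len(n) - 0.5) * bin_width
  total_t <- n * bin_width
  d <- data.frame(t = t_seg, y = y)
  y0 <- mean(head(y, max(3, length(y) %/% 10)))
  y1 <- mean(tail(y, max(3, length(y) %/% 10)))
  try2 <- try(minpack.lm::nlsLM(
    y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2), data = d,
    start = list(a1 = 0.7 * y0, tau1 = total_t / 2,
                 a2 = 0.3 * y0, tau2 = total_t / 8),
    lower = c(0, total_t * 1e-3, 0, total_t * 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (!inherits(try2, "try-error")) {
    f <- predict(try2, newdata = data.frame(t = t_all))
    return(list(trend = f, model = "exp2"))
  }
  try1 <- try(minpack.lm::nlsLM(
    y ~ a1 * exp(-t / tau1), data = d,
    start = list(a1 = y0, tau1 = total_t / 2),
    lower = c(0, total_t * 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (!inherits(try1, "try-error")) {
    f <- predict(try1, newdata = data.frame(t = t_all))
    return(list(trend = f, model = "exp1"))
  }
  list(trend = rep(mean(counts), n), model = "constant")
}

#' Direct all-pairs autocorrelation estimator
#'
#' Brute-force O(T^2) reference estimator of `G(tau)` at explicit integer
#' lags, with the same symmetric normalization as
#' [compute_autocorrelation()].  Intended for validation on short traces.
#'
#' @param counts Numeric count vector (already at the analysis bin width).
#' @param lags Integer lags in bins.
#' @param bin_width Bin width in seconds.
#' @return Data frame with `lag` (s), `G`, `n_pairs`.
#' @export
direct_autocorrelation <- function(counts, lags, bin_width = 1) {
  n <- length(counts)
  lags <- vapply(lags, check_count, 1L, name = "lag")
  res <- lapply(lags, function(j) {
    if (j >= n) return(NULL)
    h <- counts[seq_len(n - j)]
    t <- counts[seq_len(n - j) + j]
    data.frame(lag = j * bin_width,
               G = mean(h * t) / (mean(h) * mean(t)) - 1,
               n_pairs = n - j)
  })
  do.call(rbind, res)
}
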