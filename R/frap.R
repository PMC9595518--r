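#' Normalize a FRAP recovery series
#'
#' Background-subtracts the raw intensities and maps the series minimum
#' to 0% and maximum to 100% linearly, so curves from cells of different
#' brightness are comparable.  The minimum is in practice the first
#' post-bleach frame and the maximum the pre-bleach level.
#'
#' @param raw Data frame with columns `time_s` (bleach at 0, pre-bleach
#'   negative) and `intensity`, with at least one pre-bleach point.
#' @param background Background intensity to subtract.
#' @param control Optional control series (same time base) measured with
#'   identical settings but no bleach; when given, the background-
#'   subtracted signal is divided by the control to remove acquisition
#'   bleaching before min-max scaling.
#' @return Data frame of class `frap_series`: `time_s`, `intensity`
#'   (percent, extrema at exactly 0 and 100) and `raw`.
#' @export
#' @examples
#' raw <- data.frame(time_s = c(-1, 0, 1, 2),
#'                   intensity = c(4, 1, 2.5, 4))
#' normalize_frap(raw, background = 0)$intensity  # 100 0 50 100
normalize_frap <- function(raw, background = 0, control = NULL) {
  stopifnot(is.data.frame(raw),
            all(c("time_s", "intensity") %in% names(raw)))
  if (nrow(raw) < 3L) stop_param("series needs at least 3 points")
  if (!any(raw$time_s < 0)) stop_param("series needs a pre-bleach point")
  if (is.unsorted(raw$time_s)) stop_param("times must be increasing")
  check_scalar(background, "background", finite = TRUE)
  y <- raw$intensity - background
  if (!is.null(control)) {
    stopifnot(is.data.frame(control),
              all(c("time_s", "intensity") %in% names(control)))
    ctrl <- stats::approx(control$time_s, control$intensity - background,
                          xout = raw$time_s, rule = 2)$y
    if (any(ctrl <= 0)) stop_param("control series must stay positive")
    y <- y / (ctrl / ctrl[1])
  }
  rng <- range(y)
  if (diff(rng) == 0)
    stop(errorCondition("series is constant: normalization degenerate",
                        class = c("condensorheo_degenerate_error",
                                  "error", "condition")))
  # scale before multiplying so the extrema are exactly 0 and 100
  frac <- (y - rng[1]) / (rng[2] - rng[1])
  structure(data.frame(time_s = raw$time_s,
                       intensity = 100 * frac,
                       raw = raw$intensity),
            class = c("frap_series", "data.frame"),
            background = background)
}

#' Mean FRAP recovery curve across cells
#'
#' Pointwise mean and standard deviation over normalized series.  Series
#' on different time bases are linearly interpolated onto the time grid
#' of the first.
#'
#' @param series_list List of `frap_series` (or data frames with
#'   `time_s`, `intensity`).
#' @return Data frame with `time_s`, `mean`, `sd`, `n`.
#' @export
mean_recovery <- function(series_list) {
  if (!length(series_list)) stop_param("empty series collection")
  base_t <- series_list[[1]]$time_s
  y <- vapply(series_list, function(s) {
    stopifnot(all(c("time_s", "intensity") %in% names(s)))
    if (length(s$time_s) == length(base_t) &&
        all(abs(s$time_s - base_t) < 1e-9)) s$intensity
    else stats::approx(s$time_s, s$intensity, xout = base_t, rule = 2)$y
  }, numeric(length(base_t)))
  if (length(base_t) == 1L) y <- matrix(y, 1)
  data.frame(time_s = base_t,
             mean = rowMeans(y),
             sd = apply(y, 1, sd),
             n = length(series_list))
}

#' Recovery rate and half-time from a normalized FRAP series
#'
#' Fits a single-exponential recovery
#' `y0 + A (1 - exp(-k t))` to the post-bleach (t >= 0) points of a
#' normalized series; `t_half = ln 2 / k`.  The offset `y0` is a
#' nuisance parameter: min-max normalization pins the *noisiest* extreme
#' point to 0, so the true post-bleach level sits slightly above zero
#' and forcing the fit through the origin would bias `k` upward.  The
#' mobile fraction is reported as `A / (prebleach - y0)`, the recovered
#' amplitude over the realized bleach depth, which cancels the scale
#' inflation that noisy extrema impose on min-max normalized data.
#'
#' @param series A [normalize_frap()] result (intensity in percent,
#'   pre-bleach points at negative times).
#' @return List with `k` (1/s), `t_half` (s), `A` (amplitude, percent),
#'   `y0` (post-bleach baseline, percent), `mobile_fraction`,
#'   `converged`.
#' @export
#' @examples
#' t <- seq(0, 60, 0.5)
#' s <- structure(data.frame(time_s = c(-1, t),
#'                           intensity = c(100, 100 * (1 - exp(-0.1 * t)))),
#'                class = c("frap_series", "data.frame"))
#' recovery_halftime(s)$t_half  # ln(2)/0.1 = 6.93 s
recovery_halftime <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("time_s", "intensity") %in% names(series)))
  post <- series[series$time_s >= 0, ]
  if (nrow(post) < 3L) stop_param("need >= 3 post-bleach points")
  pre <- series$intensity[series$time_s < 0]
  a0 <- max(post$intensity) - min(post$intensity)
  if (a0 <= 0) a0 <- 50
  t_half_guess <- post$time_s[which.min(abs(post$intensity -
                                              min(post$intensity) - a0 / 2))]
  k0 <- if (t_half_guess > 0) log(2) / t_half_guess else
    1 / max(post$time_s)
  fit <- try(minpack.lm::nlsLM(
    intensity ~ y0 + A * (1 - exp(-k * time_s)),
    data = post,
    start = list(y0 = min(post$intensity), A = a0, k = k0),
    lower = c(0, 0, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(k = NA_real_, t_half = NA_real_, A = NA_real_,
                y0 = NA_real_, mobile_fraction = NA_real_,
                converged = FALSE))
  cf <- coef(fit)
  depth <- if (length(pre)) mean(pre) - unname(cf["y0"]) else NA_real_
  list(k = unname(cf["k"]), t_half = log(2) / unname(cf["k"]),
       A = unname(cf["A"]), y0 = unname(cf["y0"]),
       mobile_fraction = if (!is.na(depth) && depth > 0)
         unname(cf["A"]) / depth else NA_real_,
       converged = TRUE)
}
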