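# Small argument checkers shared across the package.  All raise
# classed conditions so callers/tests can distinguish parameter errors
# from numerical failures.

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("condensorheo_param_error",
                                             "error", "condition")))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_param(name, " must be a single non-missing number")
  if (finite && !is.finite(x)) stop_param(name, " must be finite")
  if (positive && x <= 0) stop_param(name, " must be > 0")
  if (nonneg && x < 0) stop_param(name, " must be >= 0")
  invisible(x)
}

check_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  check_scalar(x, name)
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok)
    stop_param(name, " must lie in ", if (open_left) "(" else "[", "0, 1",
               if (open_right) ")" else "]")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar(x, name)
  if (x != round(x) || x < min)
    stop_param(name, " must be an integer >= ", min)
  invisible(as.integer(x))
}

# Optional seeding: all simulators call this so a params$seed pins the RNG.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    check_scalar(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
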