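#' Construct an intensity trace
#'
#' A photon-count time series on uniform bins, the raw input to FCS
#' correlation analysis.
#'
#' @param counts Numeric vector of photon counts per bin (>= 0).
#' @param bin_width Bin width in seconds.
#' @param t0 Time of the first bin centre in seconds.
#' @param label Free-text label carried through analysis outputs.
#' @return An object of class `fcs_trace` with fields `times` (s),
#'   `counts`, `bin_width` (s) and `label`.
#' @export
#' @examples
#' tr <- intensity_trace(rpois(100, 5), bin_width = 1e-5)
#' mean_count_rate(tr)
intensity_trace <- function(counts, bin_width, t0 = 0, label = "") {
  if (length(counts) < 2L) stop_param("a trace needs at least 2 bins")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_param("counts must be finite and >= 0")
  check_scalar(bin_width, "bin_width", positive = TRUE)
  structure(
    list(times = t0 + (seq_along(counts) - 1) * bin_width,
         counts = as.numeric(counts),
         bin_width = bin_width,
         label = label),
    class = "fcs_trace")
}

#' @export
print.fcs_trace <- function(x, ...) {
  cat(sprintf("<fcs_trace> %d bins of %.3g s (%.3g s total), mean rate %.4g counts/s%s\n",
              length(x$counts), x$bin_width,
              length(x$counts) * x$bin_width, mean_count_rate(x),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' Mean count rate of a trace
#'
#' @param trace An [intensity_trace()].
#' @return Mean photon rate in counts/s.
#' @export
mean_count_rate <- function(trace) {
  stopifnot(inherits(trace, "fcs_trace"))
  mean(trace$counts) / trace$bin_width
}

# Sum consecutive bins by an integer factor (drops the remainder).
rebin_counts <- function(counts, factor) {
  factor <- check_count(factor, "rebin factor")
  if (factor == 1L) return(counts)
  n <- (length(counts) %/% factor) * factor
  colSums(matrix(counts[seq_len(n)], nrow = factor))
}
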