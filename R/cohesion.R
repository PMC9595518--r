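#' Distance between two marker foci
#'
#' Euclidean centroid distance in the dimensionality supplied (2D or
#' 3D).  A cell with a single focus has no distance (the centrioles are
#' unresolved/joined): returns `NA`.
#'
#' @param centroids Matrix with one row per focus and 2 or 3 coordinate
#'   columns (um).
#' @return Distance in um, or `NA` for a single focus.
#' @export
#' @examples
#' foci_distance(rbind(c(0, 0), c(3, 4)))  # 5
foci_distance <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (!ncol(centroids) %in% 2:3)
    stop_param("centroids must have 2 or 3 coordinate columns")
  if (any(!is.finite(centroids))) stop_param("coordinates must be finite")
  n <- nrow(centroids)
  if (n == 1L) return(NA_real_)
  if (n > 2L)
    stop(errorCondition(
      paste0("ambiguous: ", n, " foci present; expected 1 or 2"),
      class = c("condensorheo_ambiguity_error", "error", "condition")))
  sqrt(sum((centroids[1, ] - centroids[2, ])^2))
}

#' Classify centrosome splitting across a cell population
#'
#' A cell is scored split when two marker foci are present and their
#' centroid distance strictly exceeds `threshold` (default 1.6 um; a
#' distance of exactly 1.6 um is not split).
#'
#' @param records List of per-cell records, each a list with `cell_id`
#'   and `centroids` (matrix of 1 or 2 foci).
#' @param threshold Split distance threshold, um.
#' @return Object of class `cohesion_summary`: `threshold`, `n_cells`,
#'   `n_split`, `percent_split`, and `per_cell` data frame (`cell_id`,
#'   `n_foci`, `distance`, `split`).
#' @export
#' @examples
#' recs <- list(list(cell_id = "a", centroids = rbind(c(0, 0), c(0, 2))),
#'              list(cell_id = "b", centroids = rbind(c(0, 0))))
#' classify_split(recs)$percent_split  # 50
classify_split <- function(records, threshold = 1.6) {
  if (!length(records)) stop_param("empty record collection")
  check_scalar(threshold, "threshold", positive = TRUE)
  per_cell <- do.call(rbind, lapply(records, function(r) {
    cen <- as.matrix(r$centroids)
    d <- foci_distance(cen)
    data.frame(cell_id = as.character(r$cell_id),
               n_foci = nrow(cen),
               distance = d,
               split = !is.na(d) && d > threshold)
  }))
  structure(list(threshold = threshold,
                 n_cells = nrow(per_cell),
                 n_split = sum(per_cell$split),
                 percent_split = 100 * sum(per_cell$split) / nrow(per_cell),
                 per_cell = per_cell),
            class = "cohesion_summary")
}

#' @export
print.cohesion_summary <- function(x, ...) {
  cat(sprintf("<cohesion_summary> %d/%d cells split (> %.2g um): %.1f%%\n",
              x$n_split, x$n_cells, x$threshold, x$percent_split))
  invisible(x)
}

#' Per-cell focus-distance time series
#'
#' Orders records of one or more cells by time and returns the focus
#' centroid distance at each time point (`NA` where only a single focus
#' is present).
#'
#' @param records List of per-cell, per-timepoint records: each a list
#'   with `cell_id`, `time_s` and `centroids`.
#' @return Named list (by cell) of data frames with `time_s`,
#'   `distance`, `n_foci`.
#' @export
distance_timeseries <- function(records) {
  if (!length(records)) return(list())
  ids <- vapply(records, function(r) as.character(r$cell_id), "")
  out <- lapply(split(records, ids), function(rs) {
    d <- do.call(rbind, lapply(rs, function(r) {
      cen <- as.matrix(r$centroids)
      data.frame(time_s = r$time_s, distance = foci_distance(cen),
                 n_foci = nrow(cen))
    }))
    d[order(d$time_s), , drop = FALSE]
  })
  out
}

#' Compare split percentages between replicate groups
#'
#' Two-sided t test (paired or unpaired) on replicate-level percent
#' split values.  A paired design with zero-variance differences is
#' degenerate (the t statistic is undefined) and is reported as such
#' rather than raising.
#'
#' @param group_a,group_b Numeric vectors of replicate percent-split
#'   values (paired groups must have equal length >= 2).
#' @param paired Logical.
#' @return List with `statistic`, `p_value`, `df`, `paired`,
#'   `degenerate`.
#' @export
#' @examples
#' compare_replicates(c(10, 20, 30), c(35, 45, 60), paired = TRUE)
compare_replicates <- function(group_a, group_b, paired = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_param("need at least 2 replicates per group")
  if (paired && length(group_a) != length(group_b))
    stop_param("paired groups must have equal length")
  res <- tryCatch(t.test(group_a, group_b, paired = paired),
                  error = function(e) NULL)
  if (is.null(res))
    return(list(statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                paired = paired, degenerate = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter), paired = paired, degenerate = FALSE)
}
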