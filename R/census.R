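#' Shape statistics of a labelled patch
#'
#' Fits the second-moment-equivalent ellipse to each labelled component:
#' the covariance matrix of member voxel coordinates (plus the 1/12
#' per-axis variance of a unit pixel, so a single pixel behaves as a
#' square rather than a point) gives major and minor axis lengths
#' `4 sqrt(lambda_1)` and `4 sqrt(lambda_2)` and the aspect ratio
#' `major/minor >= 1`.
#'
#' @param mask Integer label matrix (0 background).
#' @param pixel_um Pixel size in um (isotropic in-plane).
#' @return Data frame with `label`, `area` (voxels), `major_axis` (um),
#'   `minor_axis` (um), `aspect_ratio`.
#' @export
#' @examples
#' m <- matrix(0L, 21, 21); m[9:13, 5:17] <- 1L
#' shape_stats(m)
shape_stats <- function(mask, pixel_um = 1) {
  stopifnot(is.matrix(mask))
  check_scalar(pixel_um, "pixel_um", positive = TRUE)
  labels <- sort(setdiff(unique(as.integer(mask)), 0L))
  rows <- lapply(labels, function(l) {
    idx <- which(mask == l, arr.ind = TRUE)
    n <- nrow(idx)
    cv <- if (n > 1) stats::cov(idx) * (n - 1) / n else matrix(0, 2, 2)
    cv <- cv + diag(1 / 12, 2)       # finite pixel extent
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    major <- 4 * sqrt(ev[1]) * pixel_um
    minor <- 4 * sqrt(ev[2]) * pixel_um
    data.frame(label = l, area = n, major_axis = major,
               minor_axis = minor, aspect_ratio = major / minor)
  })
  if (!length(rows))
    return(data.frame(label = integer(), area = integer(),
                      major_axis = numeric(), minor_axis = numeric(),
                      aspect_ratio = numeric()))
  do.call(rbind, rows)
}

#' Census of cytoplasmic condensate patches across cells
#'
#' Counts labelled patches per cell, reports the fraction of cells
#' containing more than one patch, and computes per-patch shape
#' statistics ([shape_stats()]).
#'
#' @param cell_masks Named list of integer label matrices, one per cell
#'   (labels are per-cell patch ids; 0 background).
#' @param pixel_um Pixel size in um for the axis lengths.
#' @return Object of class `condensate_census`: `per_cell` data frame
#'   (`cell`, `n_patches`), `fraction_multi` (fraction of cells with
#'   more than one patch), `percent_multi`, and `patches` (per-patch
#'   shape table with a `cell` column).
#' @export
#' @examples
#' masks <- list(a = matrix(0L, 5, 5), b = {
#'   m <- matrix(0L, 5, 5); m[1:2, 1:2] <- 1L; m[4:5, 4:5] <- 2L; m
#' })
#' condensate_census(masks)$percent_multi
condensate_census <- function(cell_masks, pixel_um = 1) {
  stopifnot(is.list(cell_masks), length(cell_masks) >= 1L)
  nm <- names(cell_masks)
  if (is.null(nm)) nm <- as.character(seq_along(cell_masks))
  per_cell <- data.frame(
    cell = nm,
    n_patches = vapply(cell_masks, function(m)
      length(setdiff(unique(as.integer(m)), 0L)), 1L))
  rownames(per_cell) <- NULL
  patches <- do.call(rbind, lapply(seq_along(cell_masks), function(i) {
    s <- shape_stats(cell_masks[[i]], pixel_um)
    if (nrow(s)) cbind(cell = nm[i], s) else NULL
  }))
  frac <- mean(per_cell$n_patches > 1L)
  structure(list(per_cell = per_cell, fraction_multi = frac,
                 percent_multi = 100 * frac, patches = patches),
            class = "condensate_census")
}

#' @export
print.condensate_census <- function(x, ...) {
  cat(sprintf("<condensate_census> %d cells, %.1f%% with >1 patch\n",
              nrow(x$per_cell), x$percent_multi))
  invisible(x)
}
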