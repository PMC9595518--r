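#' Voxel geometry
#'
#' Records the voxel size of a confocal image and the derived voxel
#' volume in litres.  Defaults match typical calibrated-imaging
#' acquisition: 100 nm lateral, 400 nm axial.
#'
#' @param dx,dy Lateral voxel size, um.
#' @param dz Axial voxel size, um.
#' @return Object of class `voxel_geometry` with `dx`, `dy`, `dz` (um)
#'   and `volume_l` (litres; `dx*dy*dz * 1e-15`).
#' @export
#' @examples
#' voxel_geometry()$volume_l  # 4e-18 L
voxel_geometry <- function(dx = 0.1, dy = 0.1, dz = 0.4) {
  check_scalar(dx, "dx", positive = TRUE)
  check_scalar(dy, "dy", positive = TRUE)
  check_scalar(dz, "dz", positive = TRUE)
  vol <- dx * dy * dz * 1e-15
  if (vol <= 0)
    stop(errorCondition("voxel volume must be positive",
                        class = c("condensorheo_geometry_error",
                                  "error", "condition")))
  structure(list(dx = dx, dy = dy, dz = dz, volume_l = vol),
            class = "voxel_geometry")
}

#' Mean intensity in a window centred on a point
#'
#' Averages a square voxel window centred on an FCS measurement position,
#' pairing an image intensity with the concentration measured there.  For
#' an even window of size `w` the window covers indices
#' `[c - w/2, c + w/2 - 1]` on each axis (anchor at the flooring voxel).
#'
#' @param image Numeric matrix (x by y is rows by columns).
#' @param position Length-2 integer voxel coordinates (row, column),
#'   1-based.
#' @param window Window side in voxels (default 6).
#' @return Mean intensity in the window.
#' @export
#' @examples
#' img <- matrix(7, 20, 20)
#' sample_image_at_point(img, c(10, 10))
sample_image_at_point <- function(image, position, window = 6L) {
  stopifnot(is.matrix(image), is.numeric(image))
  window <- check_count(window, "window")
  if (length(position) != 2L) stop_param("position must be length 2")
  pos <- as.integer(round(position))
  lo_off <- window %/% 2L
  hi_off <- window - lo_off - 1L
  r <- (pos[1] - lo_off):(pos[1] + hi_off)
  c_ <- (pos[2] - lo_off):(pos[2] + hi_off)
  if (min(r) < 1L || min(c_) < 1L || max(r) > nrow(image) ||
      max(c_) > ncol(image))
    stop(errorCondition("sampling window overlaps the image border",
                        class = c("condensorheo_bounds_error",
                                  "error", "condition")))
  mean(image[r, c_])
}

#' Fit the intensity-to-concentration calibration line
#'
#' Ordinary least squares of image intensity against FCS-measured
#' cytoplasmic concentration over a population of cells.  The slope is
#' the experiment-specific conversion factor; the free intercept absorbs
#' camera offset/background.  A warning flag is raised when
#' `r_squared < 0.9`, indicating the acquisition may have left the
#' detector's linear range.
#'
#' @param pairs Data frame with columns `intensity` and `C_nM`.
#' @return Object of class `calibration_line`: `slope` (intensity per
#'   nM), `intercept`, `r_squared`, `n_points`, `linear_range_ok`.
#' @export
#' @examples
#' d <- data.frame(C_nM = 1:12, intensity = 3 * (1:12) + 10)
#' fit_calibration_line(d)$slope
fit_calibration_line <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("intensity", "C_nM") %in% names(pairs)))
  pairs <- pairs[complete.cases(pairs[c("intensity", "C_nM")]), ]
  if (nrow(pairs) < 2L)
    stop_param("need at least 2 calibration points")
  if (length(unique(pairs$C_nM)) < 2L)
    stop(errorCondition("all concentrations identical: degenerate design",
                        class = c("condensorheo_degenerate_error",
                                  "error", "condition")))
  fit <- lm(intensity ~ C_nM, data = pairs)
  ss_tot <- sum((pairs$intensity - mean(pairs$intensity))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 0
  ok <- r2 >= 0.9
  if (!ok)
    warning("calibration r^2 < 0.9: check the detector's linear range")
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n_points = nrow(pairs),
                 linear_range_ok = ok),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("<calibration_line> intensity = %.4g * C_nM + %.4g (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Convert an intensity image to a concentration map
#'
#' Applies `C = (intensity - intercept) / slope` per voxel.  Voxels whose
#' calibrated concentration is negative (noise below the fitted
#' background) are clipped to zero and counted.
#'
#' @param image Numeric matrix of intensities.
#' @param line A [fit_calibration_line()] result.
#' @param geometry A [voxel_geometry()].
#' @return Object of class `concentration_image`: `C_nM` (matrix, nM),
#'   `geometry`, `n_clipped` (voxels clipped at zero) and `provenance`.
#' @export
image_to_concentration <- function(image, line, geometry = voxel_geometry()) {
  stopifnot(is.matrix(image), inherits(line, "calibration_line"),
            inherits(geometry, "voxel_geometry"))
  if (line$slope == 0) stop_param("calibration slope must be nonzero")
  C <- (image - line$intercept) / line$slope
  n_clipped <- sum(C < 0)
  C[C < 0] <- 0
  structure(list(C_nM = C, geometry = geometry, n_clipped = n_clipped,
                 provenance = list(slope = line$slope,
                                   intercept = line$intercept)),
            class = "concentration_image")
}

#' Expected molecules per voxel at a given concentration
#'
#' `N = NA * C * dp` with `dp` the voxel volume in litres.  At the
#' centriolar scale (~862 nM in a 0.1 x 0.1 x 0.4 um voxel) this is
#' ~2.1 molecules per voxel.
#'
#' @param C_nM Concentration in nM (scalar, vector or matrix, >= 0).
#' @param geometry A [voxel_geometry()].
#' @return Expected molecule count per voxel (same shape as `C_nM`).
#' @export
#' @examples
#' molecules_per_voxel(862, voxel_geometry(0.1, 0.1, 0.4)) # ~2.08
molecules_per_voxel <- function(C_nM, geometry = voxel_geometry()) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (any(C_nM < 0, na.rm = TRUE)) stop_param("C_nM must be >= 0")
  .const$avogadro * (C_nM * 1e-9) * geometry$volume_l
}

#' Copy number of labelled structures
#'
#' Sums molecules per voxel over each labelled structure of a mask
#' (e.g. segmented centrioles) and reports the per-cell mean over its
#' structures.  Empty labels are flagged, not dropped.
#'
#' @param conc_image A [image_to_concentration()] result.
#' @param mask Integer label matrix aligned to the image (0 background).
#' @return Object of class `copy_number_result`: `per_structure` data
#'   frame (`label`, `mask_size`, `mean_C_nM`, `copies`, `empty`) and
#'   `cell_mean` (mean copies over non-empty structures).
#' @export
copy_number <- function(conc_image, mask) {
  stopifnot(inherits(conc_image, "concentration_image"),
            is.matrix(mask))
  if (!all(dim(mask) == dim(conc_image$C_nM)))
    stop_param("mask must match the image dimensions")
  labels <- sort(setdiff(unique(as.integer(mask)), 0L))
  mol <- molecules_per_voxel(conc_image$C_nM, conc_image$geometry)
  rows <- lapply(labels, function(l) {
    sel <- mask == l
    n <- sum(sel)
    data.frame(label = l, mask_size = n,
               mean_C_nM = if (n) mean(conc_image$C_nM[sel]) else NA_real_,
               copies = if (n) sum(mol[sel]) else 0,
               empty = n == 0L)
  })
  per_structure <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), mask_size = integer(),
               mean_C_nM = numeric(), copies = numeric(), empty = logical())
  nonempty <- per_structure[!per_structure$empty, , drop = FALSE]
  structure(list(per_structure = per_structure,
                 cell_mean = if (nrow(nonempty)) mean(nonempty$copies)
                             else NA_real_),
            class = "copy_number_result")
}

#' Otsu threshold
#'
#' Classic between-class-variance maximizing threshold, used to segment
#' bright structures (centrioles, condensates) from a concentration map
#' within a region of interest.
#'
#' @param x Numeric vector or matrix of values.
#' @param n_breaks Histogram resolution.
#' @return Threshold value; values strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_breaks = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v) || diff(range(v)) == 0) return(max(v, 0))
  h <- hist(v, breaks = seq(min(v), max(v), length.out = n_breaks + 1L),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' @importFrom graphics hist
NULL

#' Threshold-based segmentation into labelled structures
#'
#' Thresholds an image (Otsu by default) and labels 8-connected
#' foreground components, discarding components smaller than
#' `min_size` voxels.
#'
#' @param image Numeric matrix (intensity or concentration).
#' @param threshold Threshold value, or `NULL` for Otsu.
#' @param min_size Minimum component size in voxels.
#' @return Integer label matrix (0 = background).
#' @export
segment_structures <- function(image, threshold = NULL, min_size = 4L) {
  stopifnot(is.matrix(image))
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  lab <- label_components_cpp(image > threshold)
  sizes <- tabulate(lab)
  drop <- which(sizes < min_size)
  if (length(drop)) lab[lab %in% drop] <- 0L
  # relabel densely
  keep <- sort(setdiff(unique(as.integer(lab)), 0L))
  if (length(keep)) {
    map <- integer(max(keep))
    map[keep] <- seq_along(keep)
    lab[lab > 0L] <- map[lab[lab > 0L]]
  }
  lab
}
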