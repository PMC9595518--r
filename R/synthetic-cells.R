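#' Parameters for the calibration-cell image simulator
#'
#' Describes a population of cells whose cytosolic fluorescence is linear
#' in a known concentration — the ground truth needed to validate the
#' intensity-to-concentration calibration.  Defaults emulate the
#' calibration experiment: 12 cells spanning tens to hundreds of nM of
#' cytosolic fluorophore, two bright centriolar foci per cell
#' (~862 nM, ~160 copies each), and cytoplasmic condensate patches in
#' cells whose cytosolic concentration exceeds ~110 nM.
#'
#' @param n_cells Number of cells.
#' @param concentration_range Length-2 numeric, min/max cytosolic
#'   concentration (nM); cells are spaced linearly across it.
#' @param gain Intensity units per nM.
#' @param intensity_offset Additive camera offset (intensity units).
#' @param noise_sd Gaussian read-noise standard deviation (intensity
#'   units).
#' @param focus_concentration Local concentration inside centriolar
#'   foci, nM.
#' @param focus_copies Target molecule count per planted focus.
#' @param n_foci Foci per cell (1 or 2).
#' @param condensate_threshold Cytosolic concentration (nM) above which
#'   cytoplasmic patches are planted.
#' @param image_size Image side in voxels.
#' @param voxel A [voxel_geometry()].
#' @param seed Integer RNG seed, or `NULL`.
#' @return Validated list of class `calibration_sim_params`.
#' @export
calibration_sim_params <- function(n_cells = 12,
                                   concentration_range = c(10, 400),
                                   gain = 2, intensity_offset = 50,
                                   noise_sd = 10,
                                   focus_concentration = 862,
                                   focus_copies = 160,
                                   n_foci = 2,
                                   condensate_threshold = 110,
                                   image_size = 64L,
                                   voxel = voxel_geometry(),
                                   seed = NULL) {
  n_cells <- check_count(n_cells, "n_cells")
  if (length(concentration_range) != 2L ||
      concentration_range[1] >= concentration_range[2])
    stop_param("concentration_range must be c(min, max) with min < max")
  check_scalar(gain, "gain", positive = TRUE)
  check_scalar(intensity_offset, "intensity_offset", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(focus_concentration, "focus_concentration", positive = TRUE)
  check_scalar(focus_copies, "focus_copies", positive = TRUE)
  n_foci <- check_count(n_foci, "n_foci")
  if (n_foci > 2L) stop_param("n_foci must be 1 or 2")
  check_scalar(condensate_threshold, "condensate_threshold", positive = TRUE)
  image_size <- check_count(image_size, "image_size", min = 16L)
  stopifnot(inherits(voxel, "voxel_geometry"))
  structure(as.list(environment()), class = "calibration_sim_params")
}

# Pixel set of a filled ellipse; returns an index matrix (row, col)
.ellipse_pixels <- function(nr, nc, cx, cy, a, b, theta = 0) {
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dx <- g$r - cx; dy <- g$c - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  g[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]
}

#' Simulate FCS-calibration cell images
#'
#' Generates one image per cell: a cytosolic plateau with intensity
#' `gain * C + intensity_offset` plus Gaussian noise, clipped at zero;
#' compact circular foci planted at a known local concentration whose
#' integrated molecule count is recorded exactly; and, for cells whose
#' cytosolic concentration exceeds `condensate_threshold`, one or more
#' elliptical cytoplasmic patches.  Ground truth (per-cell concentration,
#' per-focus planted copies, masks) is returned alongside the images.
#'
#' @param params A [calibration_sim_params()].
#' @return Object of class `calibration_sim`: `cells` (list with
#'   `image`, `C_cytosol_nM`, `C_true_nM` map, `cell_mask`,
#'   `focus_mask`, `patch_mask`, `focus_copies_true`), `truth` data
#'   frame (`cell`, `C_cytosol_nM`, `n_patches`, `focus_copies`),
#'   and `params`.
#' @export
#' @examples
#' sim <- simulate_calibration_cells(calibration_sim_params(seed = 1))
#' sim$truth
simulate_calibration_cells <- function(params) {
  stopifnot(inherits(params, "calibration_sim_params"))
  p <- params
  maybe_set_seed(p$seed)
  n <- p$image_size
  conc <- seq(p$concentration_range[1], p$concentration_range[2],
              length.out = p$n_cells)
  mol_per_vox_focus <- molecules_per_voxel(p$focus_concentration, p$voxel)
  n_vox_focus <- max(1L, round(p$focus_copies / mol_per_vox_focus))
  cells <- vector("list", p$n_cells)
  for (i in seq_len(p$n_cells)) {
    C_true <- matrix(0, n, n)
    cell_mask <- matrix(FALSE, n, n)
    cpx <- .ellipse_pixels(n, n, n / 2, n / 2, n * 0.42, n * 0.34,
                           theta = (i %% 7) * pi / 7)
    cell_mask[as.matrix(cpx)] <- TRUE
    C_true[cell_mask] <- conc[i]
    # two compact foci near the cell centre (centriole pair)
    focus_mask <- matrix(0L, n, n)
    centres <- list(c(n / 2 - 6, n / 2 - 5), c(n / 2 + 6, n / 2 + 5))
    for (fi in seq_len(p$n_foci)) {
      ctr <- centres[[fi]]
      g <- expand.grid(r = seq_len(n), c = seq_len(n))
      d2 <- (g$r - ctr[1])^2 + (g$c - ctr[2])^2
      sel <- order(d2)[seq_len(n_vox_focus)]
      focus_mask[cbind(g$r[sel], g$c[sel])] <- fi
      C_true[cbind(g$r[sel], g$c[sel])] <- p$focus_concentration
    }
    # cytoplasmic condensate patches above the threshold concentration
    patch_mask <- matrix(0L, n, n)
    if (conc[i] > p$condensate_threshold) {
      n_patch <- 1L + rpois(1L, 1.2)
      for (pi_ in seq_len(n_patch)) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, n * 0.18, n * 0.3)
        cx <- n / 2 + rad * cos(ang); cy <- n / 2 + rad * sin(ang)
        a <- runif(1, 2, 4); b <- a / runif(1, 1, 2.5)
        px <- .ellipse_pixels(n, n, cx, cy, a, b, runif(1, 0, pi))
        px <- px[cell_mask[as.matrix(px)] & focus_mask[as.matrix(px)] == 0L, ,
                 drop = FALSE]
        if (nrow(px)) {
          patch_mask[as.matrix(px)] <- pi_
          C_true[as.matrix(px)] <- max(2 * p$condensate_threshold,
                                       1.3 * conc[i])
        }
      }
    }
    image <- p$gain * C_true + p$intensity_offset
    if (p$noise_sd > 0)
      image <- image + matrix(rnorm(n * n, 0, p$noise_sd), n, n)
    image[image < 0] <- 0
    cells[[i]] <- list(image = image, C_cytosol_nM = conc[i],
                       C_true_nM = C_true, cell_mask = cell_mask,
                       focus_mask = focus_mask, patch_mask = patch_mask,
                       focus_copies_true = n_vox_focus * mol_per_vox_focus)
  }
  truth <- data.frame(
    cell = seq_len(p$n_cells),
    C_cytosol_nM = conc,
    n_patches = vapply(cells, function(cl)
      length(setdiff(unique(as.integer(cl$patch_mask)), 0L)), 1L),
    focus_copies = vapply(cells, function(cl) cl$focus_copies_true, 1.0))
  structure(list(cells = cells, truth = truth, params = p),
            class = "calibration_sim")
}
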