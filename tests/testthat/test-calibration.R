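test_that("window sampling averages the centred window and guards bounds", {
  img <- matrix(7, 20, 20)
  expect_equal(sample_image_at_point(img, c(10, 10)), 7)
  # half-0 / half-10 region: 6x6 window covering rows 7..12 of a split
  img2 <- matrix(0, 20, 20)
  img2[10:20, ] <- 10   # window [c-3, c+2] on row axis: rows 7..12
  expect_equal(sample_image_at_point(img2, c(10, 10), window = 6), 5)
  expect_error(sample_image_at_point(img, c(2, 10)),
               class = "condensorheo_bounds_error")
  expect_error(sample_image_at_point(img, c(10, 19)),
               class = "condensorheo_bounds_error")
})

test_that("calibration line is exact on noiseless points and validates input", {
  d <- data.frame(C_nM = seq(2, 40, length.out = 12),
                  intensity = 3 * seq(2, 40, length.out = 12) + 10)
  line <- fit_calibration_line(d)
  expect_equal(line$slope, 3, tolerance = 1e-12)
  expect_equal(line$intercept, 10, tolerance = 1e-10)
  expect_equal(line$r_squared, 1, tolerance = 1e-12)
  expect_true(line$linear_range_ok)
  expect_error(fit_calibration_line(d[1, ]),
               class = "condensorheo_param_error")
  expect_error(fit_calibration_line(data.frame(C_nM = c(5, 5),
                                               intensity = c(1, 2))),
               class = "condensorheo_degenerate_error")
})

test_that("conversion-factor recovery from simulated cells is within 5%", {
  p <- calibration_sim_params(n_cells = 12, gain = 2,
                              noise_sd = 8,   # ~5% of mid-range signal
                              condensate_threshold = 1e6,  # no patches
                              seed = 17)
  sim <- simulate_calibration_cells(p)
  pairs <- do.call(rbind, lapply(sim$cells, function(cl)
    data.frame(intensity = sample_image_at_point(cl$image, c(16, 32)),
               C_nM = cl$C_cytosol_nM)))
  line <- fit_calibration_line(pairs)
  expect_lt(abs(line$slope - 2) / 2, 0.05)
})

test_that("concentration mapping inverts the generator exactly at zero noise", {
  p <- calibration_sim_params(noise_sd = 0, condensate_threshold = 1e6,
                              seed = 2)
  sim <- simulate_calibration_cells(p)
  pairs <- do.call(rbind, lapply(sim$cells, function(cl)
    data.frame(intensity = sample_image_at_point(cl$image, c(16, 32)),
               C_nM = cl$C_cytosol_nM)))
  line <- fit_calibration_line(pairs)
  cl <- sim$cells[[6]]
  ci <- image_to_concentration(cl$image, line, p$voxel)
  sel <- cl$cell_mask & cl$focus_mask == 0L
  expect_lt(max(abs(ci$C_nM[sel] - cl$C_cytosol_nM)), 1e-9 *
              max(1, cl$C_cytosol_nM))
  # intensity equal to the intercept maps to zero
  flat <- matrix(line$intercept, 8, 8)
  expect_true(all(image_to_concentration(flat, line, p$voxel)$C_nM == 0))
  # negative concentrations are clipped and counted
  dark <- matrix(line$intercept - 5 * line$slope, 4, 4)
  out <- image_to_concentration(dark, line, p$voxel)
  expect_equal(out$n_clipped, 16)
  expect_true(all(out$C_nM == 0))
})

test_that("planted 862 nM foci are recovered within 10% under noise", {
  p <- calibration_sim_params(noise_sd = 8, condensate_threshold = 1e6,
                              seed = 23)
  sim <- simulate_calibration_cells(p)
  pairs <- do.call(rbind, lapply(sim$cells, function(cl)
    data.frame(intensity = sample_image_at_point(cl$image, c(16, 32)),
               C_nM = cl$C_cytosol_nM)))
  line <- fit_calibration_line(pairs)
  cl <- sim$cells[[3]]
  ci <- image_to_concentration(cl$image, line, p$voxel)
  focus_mean <- mean(ci$C_nM[cl$focus_mask > 0L])
  expect_lt(abs(focus_mean - 862) / 862, 0.10)
})

test_that("molecules per voxel follows N = NA C dp and is linear", {
  g <- voxel_geometry(0.1, 0.1, 0.4)
  expect_equal(molecules_per_voxel(862, g), 2.08, tolerance = 0.002)
  expect_equal(molecules_per_voxel(0, g), 0)
  expect_equal(molecules_per_voxel(862, voxel_geometry(0.1, 0.1, 0.8)),
               2 * molecules_per_voxel(862, g), tolerance = 1e-12)
  expect_equal(molecules_per_voxel(200, g),
               2 * molecules_per_voxel(100, g), tolerance = 1e-12)
})

test_that("copy number sums voxels, averages structures, flags empties", {
  g <- voxel_geometry(0.1, 0.1, 0.4)
  # uniform concentration giving exactly 2 molecules per voxel
  C2 <- 2 / (physical_constants()$avogadro * g$volume_l) * 1e9
  img <- matrix(C2, 20, 20)
  ci <- structure(list(C_nM = img, geometry = g, n_clipped = 0L,
                       provenance = list()),
                  class = "concentration_image")
  mask <- matrix(0L, 20, 20)
  mask[1:8, 1:10] <- 1L            # 80 voxels
  res <- copy_number(ci, mask)
  expect_equal(res$per_structure$copies, 160, tolerance = 1e-9)
  # per-cell mean of two centrioles
  mask2 <- mask
  mask2[15:20, 15:20] <- 2L
  res2 <- copy_number(ci, mask2)
  expect_equal(res2$cell_mean, mean(res2$per_structure$copies))
  # additivity under mask partition
  part <- mask
  part[1:4, 1:10] <- 3L
  res3 <- copy_number(ci, part)
  expect_equal(sum(res3$per_structure$copies),
               res$per_structure$copies[1], tolerance = 1e-12)
})

test_that("planted focus copies are recovered through segmentation", {
  p <- calibration_sim_params(noise_sd = 0, focus_copies = 150,
                              condensate_threshold = 1e6, seed = 5)
  sim <- simulate_calibration_cells(p)
  pairs <- do.call(rbind, lapply(sim$cells, function(cl)
    data.frame(intensity = sample_image_at_point(cl$image, c(16, 32)),
               C_nM = cl$C_cytosol_nM)))
  line <- fit_calibration_line(pairs)
  cl <- sim$cells[[2]]
  ci <- image_to_concentration(cl$image, line, p$voxel)
  res <- copy_number(ci, cl$focus_mask)      # generous (exact) mask
  expect_lt(abs(res$cell_mean - 150) / 150, 0.02)
  # Otsu segmentation of the map finds the same foci
  lab <- segment_structures(ci$C_nM)
  expect_gte(length(setdiff(unique(as.integer(lab)), 0L)), p$n_foci)
})

test_that("cells express condensate patches only above the threshold", {
  p <- calibration_sim_params(n_cells = 6, concentration_range = c(50, 200),
                              condensate_threshold = 110, noise_sd = 0,
                              seed = 31)
  sim <- simulate_calibration_cells(p)
  low <- sim$truth$C_cytosol_nM <= 110
  expect_true(all(sim$truth$n_patches[low] == 0))
  expect_true(all(sim$truth$n_patches[sim$truth$C_cytosol_nM > 110] >= 1))
  # clipping keeps intensities non-negative even with heavy noise
  p2 <- calibration_sim_params(noise_sd = 200, seed = 3)
  sim2 <- simulate_calibration_cells(p2)
  expect_true(all(sim2$cells[[1]]$image >= 0))
})
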