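test_that("ROI statistics use population SD over eroded valid regions", {
  lab <- matrix(0L, 20, 20)
  lab[5:14, 5:14] <- 1L
  sig <- matrix(0, 20, 20)
  ## after 3-voxel square erosion the region is rows/cols 8:11 (16 voxels)
  sig[8:11, 8:11] <- c(1, 1, 2, 2)
  maps <- dlept:::new_ept_maps(sig, sig * 10 + 1, "H-EPT",
                               matrix(TRUE, 20, 20), 0.002)
  st <- roi_statistics(maps, lab, erosion = 3)
  expect_equal(st$sigma_mean, 1.5)
  expect_equal(st$sigma_sd, 0.5)     # population convention
  expect_equal(st$n_voxels, 16)
  ## ground-truth maps yield exactly the assigned values with zero SD
  head <- build_head_model(seed = 5)
  truth <- dlept:::new_ept_maps(head$sigma_map, head$epsr_map, "H-EPT",
                                head$mask, head$spacing)
  st2 <- roi_statistics(truth, head$label_grid, erosion = 3)
  expect_equal(st2$sigma_sd, rep(0, nrow(st2)))
  p <- head$properties
  expect_equal(st2$sigma_mean,
               p$sigma[match(st2$label, p$label)])
  ## regions vanishing under erosion are dropped with warnings
  lab2 <- lab; lab2[5:14, 5:14] <- 2L; lab2[5:10, 5:14] <- 1L
  w <- testthat::capture_warnings(roi_statistics(maps, lab2, erosion = 3))
  expect_true(any(grepl("vanished|omitted", w)))
})

test_that("NRMSE follows its closed forms", {
  truth <- matrix(2, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(nrmse(truth, truth, mask), 0)
  expect_equal(nrmse(truth + 0.3, truth, mask), 0.15)   # c / mean(truth)
  expect_equal(nrmse(1.05 * truth, truth, mask), 0.05)
  expect_error(nrmse(truth, truth - 2, mask), "zero mean")
  expect_error(nrmse(truth, truth, mask & FALSE), "empty")
})

test_that("relative error matches hand-computed comparisons", {
  expect_equal(relative_error(0.34, 0.34), 0)
  expect_equal(relative_error(0.56, 0.59), 100 * 0.03 / 0.59)
  expect_equal(round(relative_error(0.56, 0.59), 1), 5.1)
  expect_equal(round(relative_error(1.83, 2.14), 1), 14.5)
  expect_error(relative_error(1, 0), "zero truth")
})

test_that("SNR sweep shows reconstruction spread shrinking with SNR", {
  fx <- phantom_small()
  tab <- snr_sweep(hept_reconstruct, fx$acq, fx$model$label_grid,
                   snr_levels = c(45, 90), seeds = 1:3)
  agg <- stats::aggregate(tab["sigma_sd"], by = list(snr = tab$snr),
                          FUN = mean)
  expect_gt(agg$sigma_sd[agg$snr == 45], agg$sigma_sd[agg$snr == 90])
  ## a noiseless entry reproduces the noise-free baseline
  tab0 <- snr_sweep(hept_reconstruct, fx$acq, fx$model$label_grid,
                    snr_levels = Inf, phase_sd = 0, seeds = 1)
  maps0 <- hept_reconstruct(fx$acq)
  st0 <- roi_statistics(maps0, fx$model$label_grid)
  expect_equal(tab0$sigma_mean, st0$sigma_mean)
})
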