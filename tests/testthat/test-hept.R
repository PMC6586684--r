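mu0 <- 4e-7 * pi
eps0 <- 8.8541878128e-12
omega0 <- 2 * pi * larmor_frequency()

test_that("Savitzky-Golay kernel is an exact Laplacian for quadratics", {
  k <- build_noise_robust_kernel(c(7, 7), spacing = 1)
  co <- dlept:::grid_coords(c(21, 21), 1)
  conv_center <- function(f) dlept:::conv2_same(f, k$weights)[11, 11]
  expect_equal(conv_center(co$x^2 + co$y^2), 4, tolerance = 1e-10)
  expect_equal(conv_center(co$x^2), 2, tolerance = 1e-10)
  expect_equal(conv_center(co$x * 0 + 3), 0, tolerance = 1e-10)
  ## annihilates linear and bilinear fields exactly
  expect_equal(conv_center(co$x), 0, tolerance = 1e-10)
  expect_equal(conv_center(co$y), 0, tolerance = 1e-10)
  expect_equal(conv_center(co$x * co$y), 0, tolerance = 1e-10)
  ## spacing scaling: weights in 1/m^2
  k2 <- build_noise_robust_kernel(c(7, 7), spacing = 0.002)
  expect_equal(k2$weights, k$weights_index / 0.002^2)
  expect_error(build_noise_robust_kernel(c(6, 6)), "odd")
})

test_that("7x7 kernel amplifies noise less than the 5-point stencil", {
  h <- 0.002
  k <- build_noise_robust_kernel(c(7, 7), h)
  five_point <- matrix(0, 3, 3)
  five_point[2, ] <- c(1, -4, 1) / h^2
  five_point[c(1, 3), 2] <- 1 / h^2
  expect_lt(kernel_noise_factor(k), kernel_noise_factor(five_point))
})

test_that("H-EPT recovers the phantom from the noiseless analytic field", {
  ph <- build_phantom_model(0.12, 0.88, 80)
  ora <- analytic_cylinder_field(0.06, 0.88, 80)
  acq <- make_acquisition(ora, ph, "mask")
  maps <- hept_reconstruct(acq)
  roi <- erode_rois(ph$label_grid, 3) == 4 & maps$valid_mask
  expect_rel_error(mean(maps$sigma_map[roi]), 0.88, 0.05)
  expect_rel_error(mean(maps$epsr_map[roi]), 80, 0.05)
  ## valid voxels are confined to the eroded interior
  expect_true(all(which(maps$valid_mask) %in% which(ph$mask)))
})

test_that("H-EPT is invariant to a complex scale of the field", {
  fx <- phantom_small()
  acq <- fx$acq
  maps1 <- hept_reconstruct(acq)
  acq2 <- acq
  acq2$magnitude <- acq$magnitude * 3.7
  acq2$phase <- acq$phase + 1.234
  maps2 <- hept_reconstruct(acq2)
  expect_equal(maps1$sigma_map, maps2$sigma_map, tolerance = 1e-12)
  expect_equal(maps1$epsr_map, maps2$epsr_map, tolerance = 1e-12)
})

test_that("H-EPT matches the closed form for an exponential field", {
  ## B = exp(-(alpha + i beta) x): Lap B / B = (alpha + i beta)^2, so
  ## eps_r = (beta^2 - alpha^2) / (mu0 eps0 omega^2) and
  ## sigma = 2 alpha beta / (mu0 omega) under the e^{+i omega t} convention.
  alpha <- 6; beta <- 28
  n <- 64; h <- 0.004
  co <- dlept:::grid_coords(c(n, n), h)
  B <- exp(-(alpha + 1i * beta) * co$x)
  mask <- matrix(TRUE, n, n)
  acq <- structure(list(magnitude = Mod(B), phase = Arg(B),
                        aux = mask * 1, aux_type = "mask", b1p_clean = B,
                        mask = mask, spacing = h, omega = omega0,
                        snr = Inf, phase_sd = 0), class = "acquisition")
  maps <- hept_reconstruct(acq)
  interior <- matrix(FALSE, n, n); interior[10:55, 10:55] <- TRUE
  interior <- interior & maps$valid_mask
  ## the least-squares kernel slightly attenuates harmonics over its 7x7
  ## footprint, so agreement is to discretization accuracy (~2%)
  expect_rel_error(mean(maps$sigma_map[interior]),
                   2 * alpha * beta / (mu0 * omega0), 0.03)
  expect_rel_error(mean(maps$epsr_map[interior]),
                   (beta^2 - alpha^2) / (mu0 * eps0 * omega0^2), 0.03)
})

test_that("noise amplification of H-EPT grows with 1/SNR", {
  ## full-resolution grid: noise dominates the discretization bias there
  fx <- phantom_full()
  roi <- erode_rois(fx$model$label_grid, 3) == 4
  ## both thermal-noise sources scale together with the SNR level
  sds <- vapply(c(30, 60, 90, 180), function(snr) {
    s <- vapply(1:3, function(seed) {
      nacq <- corrupt_acquisition(fx$acq,
                                  noise_spec(snr, 9e-3 * 90 / snr, seed))
      maps <- hept_reconstruct(nacq)
      r <- roi & maps$valid_mask
      stats::sd(maps$sigma_map[r])
    }, numeric(1))
    mean(s)
  }, numeric(1))
  ## monotone in 1/SNR and roughly linear: doubling SNR ~ halves the SD
  expect_true(all(diff(sds) < 0))
  ratio <- sds[1] / sds[4]   # SNR 30 vs 180: 6x noise
  expect_gt(ratio, 3)
})

test_that("ROI erosion shrinks regions and drops vanishing ones", {
  lab <- matrix(0L, 40, 40)
  lab[10:30, 10:30] <- 1L
  expect_identical(erode_rois(lab, 0), lab)
  er <- erode_rois(lab, 3)
  expect_lt(sum(er == 1L), sum(lab == 1L))
  expect_equal(sum(er == 1L), 15^2)   # square erosion of a 21x21 square
  ribbon <- matrix(0L, 40, 40)
  ribbon[10:15, 5:35] <- 1L           # 6 voxels wide
  expect_warning(er2 <- erode_rois(ribbon, 3), "vanished")
  expect_equal(sum(er2), 0)
  ## disc erosion keeps more of a convex region than square erosion
  expect_gte(sum(erode_rois(lab, 3, shape = "disc") == 1L),
             sum(er == 1L))
  expect_error(erode_rois(lab, -1), "non-negative")
})
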