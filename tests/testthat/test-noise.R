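test_that("complex noise injection calibrates to the requested SNR", {
  fx <- phantom_full()
  acq <- fx$acq
  mask <- fx$model$mask
  snr_m <- vapply(1:4, function(s) {
    noisy <- add_complex_noise(acq$b1p_clean, 90, mask, seed = s)
    measure_snr(Mod(noisy), acq$magnitude, mask)
  }, numeric(1))
  expect_rel_error(mean(snr_m), 90, 0.02)
  ## zero-noise limit and determinism
  expect_identical(add_complex_noise(acq$b1p_clean, Inf, mask), acq$b1p_clean)
  n1 <- add_complex_noise(acq$b1p_clean, 50, mask, seed = 11)
  n2 <- add_complex_noise(acq$b1p_clean, 50, mask, seed = 11)
  expect_identical(n1, n2)
  expect_error(add_complex_noise(acq$b1p_clean, 0, mask), "positive")
  expect_error(add_complex_noise(acq$b1p_clean, 90,
                                 matrix(FALSE, 128, 128)),
               "empty mask")
})

test_that("phase noise of a complex-noised field follows 1/SNR", {
  ## small-angle regime: Arg(B + n) - Arg(B) has SD ~ 1/SNR
  fx <- phantom_full()
  mask <- fx$model$mask
  noisy <- add_complex_noise(fx$acq$b1p_clean, 90, mask, seed = 2)
  dphi <- Arg(noisy / fx$acq$b1p_clean)[mask]
  expect_rel_error(stats::sd(dphi), 1 / 90, 0.1)
})

test_that("acquisition corruption hits both calibration targets", {
  fx <- phantom_full()
  spec <- noise_spec(90, 9e-3, seed = 21)
  nacq <- corrupt_acquisition(fx$acq, spec)
  expect_rel_error(measure_snr(nacq$magnitude, fx$acq$magnitude,
                               fx$model$mask), 90, 0.03)
  expect_rel_error(stats::sd((nacq$phase - fx$acq$phase)[fx$model$mask]),
                   9e-3, 0.05)
  ## aux channel stays noiseless; identity in the noiseless limit
  expect_identical(nacq$aux, fx$acq$aux)
  clean <- corrupt_acquisition(fx$acq, noise_spec(Inf, 0))
  expect_equal(clean$magnitude, fx$acq$magnitude)
  expect_equal(clean$phase, fx$acq$phase)
  ## determinism under the spec seed
  nacq2 <- corrupt_acquisition(fx$acq, spec)
  expect_identical(nacq$magnitude, nacq2$magnitude)
})

test_that("noise draws with different seeds are independent", {
  fx <- phantom_full()
  mask <- fx$model$mask
  a <- add_complex_noise(fx$acq$b1p_clean, 90, mask, seed = 1) -
    fx$acq$b1p_clean
  b <- add_complex_noise(fx$acq$b1p_clean, 90, mask, seed = 2) -
    fx$acq$b1p_clean
  expect_lt(abs(stats::cor(Re(a[mask]), Re(b[mask]))), 0.05)
  expect_lt(abs(stats::cor(Im(a[mask]), Im(b[mask]))), 0.05)
})

test_that("measure_snr validates its inputs", {
  m <- matrix(1, 10, 10)
  expect_error(measure_snr(m, m, m > 0), "identical")
  expect_error(measure_snr(m, matrix(1, 5, 5), m > 0), "grid")
  expect_error(noise_spec(-1), "positive")
  expect_error(noise_spec(90, -1), "non-negative")
})
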