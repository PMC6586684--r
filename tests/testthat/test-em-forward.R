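omega0 <- 2 * pi * larmor_frequency()

test_that("complex Bessel series matches base besselJ on the real axis", {
  x <- seq(0.1, 8, length.out = 40)
  for (n in 0:2) {
    expect_equal(Re(besselJ_complex(x, n)), besselJ(x, n), tolerance = 1e-10)
    expect_equal(Im(besselJ_complex(x, n)), rep(0, length(x)),
                 tolerance = 1e-12)
  }
})

test_that("analytic cylinder field has the expected mode structure", {
  ## vacuum: uniform transmit field, vanishing counter-rotating component
  vac <- analytic_cylinder_field(0.06, sigma = 0, epsr = 1)
  co <- dlept:::grid_coords(c(128, 128), 0.002)
  inb <- sqrt(co$x^2 + co$y^2) < 0.05
  mag <- Mod(vac$B1p[inb])
  ## at 128 MHz the vacuum mode retains a residual J0(k0 rho) curvature of
  ## order (k0 rho)^2/4 ~ 0.5% over the interior; beyond that it is uniform
  ## and the counter-rotating component is of the same tiny order
  expect_lt((max(mag) - min(mag)) / mean(mag), 5e-3)
  expect_lt(max(Mod(vac$B1m_counter[inb])) / mean(mag), 5e-3)
  ## dielectric resonance: center brighter than the rim for high epsr
  die <- analytic_cylinder_field(0.06, sigma = 0.88, epsr = 80)
  c0 <- Mod(die$B1p[64, 64])
  edge <- Mod(die$B1p[64, 34])
  expect_gt(c0, edge)
})

test_that("numerical solver reproduces the analytic cylinder solution", {
  fx <- phantom_full()
  ora <- analytic_cylinder_field(0.06, 0.88, 80)
  co <- dlept:::grid_coords(dim(fx$model$label_grid), fx$model$spacing)
  interior <- sqrt(co$x^2 + co$y^2) <= 0.05
  nrm <- function(B) B / mean(Mod(B)[fx$model$mask])
  a <- nrm(fx$sol$B1p); b <- nrm(ora$B1p)
  expect_lt(max(abs(Mod(a[interior]) - Mod(b[interior])) / Mod(b[interior])),
            0.02)
  ## counter-rotating component magnitude profile agrees too
  ra <- mean(Mod(fx$sol$B1m_counter)[interior]) /
    mean(Mod(fx$sol$B1p)[interior])
  rb <- mean(Mod(ora$B1m_counter)[interior]) / mean(Mod(ora$B1p)[interior])
  expect_rel_error(ra, rb, 0.02)
})

test_that("solver is linear and deterministic", {
  fx <- phantom_small()
  sol2 <- solve_fields(fx$model, coil_config(amplitude = 2))
  expect_equal(sol2$B1p, 2 * fx$sol$B1p, tolerance = 1e-10)
  sol3 <- solve_fields(fx$model)
  expect_identical(sol3$B1p, fx$sol$B1p)
})

test_that("solver guards margins and coil placement", {
  big <- build_phantom_model(0.24, 1, 50, grid_shape = c(128, 128),
                             spacing = 0.002)
  expect_error(solve_fields(big), "margin")
  ph <- phantom_small()$model
  expect_error(solve_fields(ph, coil_config(source_radius = 0.05)),
               "outside")
  expect_error(coil_config(n_sources = 4), "at least 8")
})

test_that("air-only model yields vacuum properties under Helmholtz mapping", {
  empty <- dlept:::new_tissue_model(matrix(0L, 64, 64),
                            data.frame(label = integer(), tissue = character(),
                                       sigma = numeric(), epsr = numeric()),
                            0.004)
  sol <- solve_fields(empty)
  kern <- build_noise_robust_kernel(c(7, 7), 0.004)
  ratio <- dlept:::conv2_same(sol$B1p, kern$weights) / sol$B1p
  interior <- matrix(FALSE, 64, 64); interior[20:45, 20:45] <- TRUE
  epsr <- -Re(ratio[interior]) / (4e-7 * pi * 8.8541878128e-12 * omega0^2)
  sigma <- Im(ratio[interior]) / (4e-7 * pi * omega0)
  expect_lt(max(abs(epsr - 1)), 0.5)
  expect_lt(max(abs(sigma)), 0.005)
})

test_that("transceive phase behaves like twice the transmit phase", {
  fx <- phantom_full()
  tp <- transceive_phase(fx$sol, fx$model$mask)
  expect_equal(tp$phi_plus, tp$phi_pm / 2)
  ## on the symmetric phantom the transceive assumption is near-exact:
  ## phi_pm/2 equals the transmit phase up to a constant
  ref <- Arg(fx$sol$B1p)
  d <- (tp$phi_plus - ref)[fx$model$mask]
  d <- d - mean(d)
  expect_lt(stats::sd(d), 0.01)
  ## conductive phantom: transceive phase varies across the object
  expect_gt(diff(range(tp$phi_pm[fx$model$mask])), 0.1)
})

test_that("acquisitions bundle normalized channels", {
  fx <- phantom_small()
  acq <- fx$acq
  expect_equal(mean(acq$magnitude[acq$mask]), 1)
  expect_setequal(unique(as.vector(acq$aux)), c(0, 1))
  acq_t <- make_acquisition(fx$sol, fx$model, "tissue_contrast")
  expect_equal(max(acq_t$aux), 1)
  expect_error(make_acquisition(fx$sol, build_phantom_model(0.12, 1, 50)),
               "grids differ")
})
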