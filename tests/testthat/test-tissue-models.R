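test_that("literature tissue properties at 128 MHz are returned", {
  wm <- lookup_tissue_properties("WM")
  expect_equal(wm$sigma, 0.34)
  expect_equal(wm$epsr, 52.6)
  gm <- lookup_tissue_properties("GM")
  expect_equal(gm$sigma, 0.59)
  expect_equal(gm$epsr, 73.4)
  csf <- lookup_tissue_properties("CSF")
  expect_equal(csf$sigma, 2.14)
  expect_equal(csf$epsr, 84)
  air <- lookup_tissue_properties("air")
  expect_equal(air$sigma, 0)
  expect_equal(air$epsr, 1)
  expect_error(lookup_tissue_properties("bone"), "unknown tissue")
  expect_error(lookup_tissue_properties("WM", frequency = 298e6),
               "128 MHz")
})

test_that("phantom models are centered homogeneous disks", {
  ph <- build_phantom_model(0.12, sigma = 0.88, epsr = 80)
  expect_s3_class(ph, "tissue_model")
  ## disk area matches the analytic area to discretization accuracy
  expect_rel_error(sum(ph$mask), pi * 0.06^2 / 0.002^2, 0.02)
  ## piecewise constant: zero within-region spread, air exactly (0, 1)
  expect_equal(stats::sd(ph$sigma_map[ph$mask]), 0)
  expect_equal(stats::sd(ph$epsr_map[ph$mask]), 0)
  expect_true(all(ph$sigma_map[!ph$mask] == 0))
  expect_true(all(ph$epsr_map[!ph$mask] == 1))
  expect_identical(ph$mask, ph$label_grid != 0L)
  expect_error(build_phantom_model(0, 1, 50), "positive")
  expect_error(build_phantom_model(0.3, 1, 50), "exceeds")
  expect_error(build_phantom_model(0.12, -1, 50), "non-negative")
})

test_that("phantom library is seeded, distinct and range-checked", {
  lib1 <- build_phantom_library(n = 12, seed = 9, grid_shape = c(64, 64),
                                spacing = 0.004)
  lib2 <- build_phantom_library(n = 12, seed = 9, grid_shape = c(64, 64),
                                spacing = 0.004)
  expect_identical(lib1, lib2)
  eps <- vapply(lib1, function(m) m$properties$epsr, numeric(1))
  sig <- vapply(lib1, function(m) m$properties$sigma, numeric(1))
  expect_equal(anyDuplicated(cbind(sig, eps)), 0L)
  expect_true(all(sig >= 0.2 & sig <= 2.2))
  expect_true(all(eps >= 40 & eps <= 90))
  expect_error(build_phantom_library(n = 2, sigma_range = c(0.5, 0.5),
                                     seed = 1),
               "degenerate")
})

test_that("head models have nested tissues and perturbed properties", {
  h1 <- build_head_model(seed = 4, eps_variation = 0.1)
  h2 <- build_head_model(seed = 4, eps_variation = 0.1)
  expect_identical(h1, h2)
  expect_setequal(unique(as.vector(h1$label_grid)), c(0L, 1L, 2L, 3L))
  ## exact reference values at zero variation
  h0 <- build_head_model(seed = 4, eps_variation = 0)
  p0 <- h0$properties
  expect_equal(p0$sigma[p0$tissue == "WM"], 0.34)
  expect_equal(p0$epsr[p0$tissue == "GM"], 73.4)
  expect_equal(p0$sigma[p0$tissue == "CSF"], 2.14)
  ## perturbations stay within the configured band
  ref <- c(WM = 0.34, GM = 0.59, CSF = 2.14)
  rel <- abs(h1$properties$sigma / ref[h1$properties$tissue] - 1)
  expect_true(all(rel <= 0.1))
  ## a library of heads carries distinct property assignments
  heads <- lapply(1:10, function(s) build_head_model(seed = s))
  sig_wm <- vapply(heads, function(h)
    h$properties$sigma[h$properties$tissue == "WM"], numeric(1))
  expect_equal(anyDuplicated(sig_wm), 0L)
})

test_that("tumor inclusions overwrite host tissue and respect geometry", {
  head <- build_head_model(seed = 2)
  tm <- add_tumor(head, radius = 0.015)
  tumor_vox <- sum(tm$label_grid == 5L)
  expect_rel_error(tumor_vox, pi * 0.015^2 / 0.002^2, 0.08)
  p <- tm$properties
  expect_equal(p$sigma[p$tissue == "tumor"], 1.4)
  expect_equal(p$epsr[p$tissue == "tumor"], 73)
  expect_identical(add_tumor(head, radius = 0), head)
  ## placing the inclusion into air must fail
  expect_error(add_tumor(head, center = c(5, 5), radius = 0.01),
               "inside tissue")
})

test_that("tissue contrast images rank CSF > GM > WM > air", {
  head <- build_head_model(seed = 2)
  img <- make_tissue_contrast(head)
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(unique(img[head$label_grid == 0L]), 0)
  m <- vapply(1:3, function(l) mean(img[head$label_grid == l]), numeric(1))
  expect_true(m[3] > m[2] && m[2] > m[1] && m[1] > 0)
  ## homogeneous phantom gives a constant in-mask image
  ph <- build_phantom_model(0.12, 0.88, 80)
  imgp <- make_tissue_contrast(ph)
  expect_equal(stats::sd(imgp[ph$mask]), 0)
})
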