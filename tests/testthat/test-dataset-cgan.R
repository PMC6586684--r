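test_that("dataset slice bookkeeping matches the full-scale database", {
  expect_equal(count_dataset_slices(42, 25, 20, 56), 2170)
  expect_equal(count_dataset_slices(38, 25, 19, 56), 2014)
  expect_equal(count_dataset_slices(0, 25, 19, 56), 1064)
  expect_equal(count_dataset_slices(0, 0, 0, 0), 0)
})

test_that("dataset splits must be disjoint", {
  expect_error(dataset_split(train = 1:5, validation = 5), "disjoint")
  sp <- dataset_split(train = 1:3, validation = 4, test = 5)
  expect_s3_class(sp, "dataset_split")
})

test_that("dataset assembly is deterministic and targets are exact", {
  lib <- build_phantom_library(n = 3, seed = 12, grid_shape = c(64, 64),
                               spacing = 0.004)
  sp <- dataset_split(train = 1:3)
  ds1 <- assemble_dataset(lib, sp, noise_spec(90, 9e-3, seed = 8),
                          slices_per_model = 2)
  ds2 <- assemble_dataset(lib, sp, noise_spec(90, 9e-3, seed = 8),
                          slices_per_model = 2)
  expect_identical(ds1$train, ds2$train)
  ## without jitter the target equals the generating model's map exactly
  ds0 <- assemble_dataset(lib, sp, noise_spec(90, 9e-3, seed = 8),
                          slices_per_model = 1, jitter = 0)
  expect_identical(ds0$train[[2]]$truth, lib[[2]]$sigma_map)
  expect_error(assemble_dataset(lib, dataset_split(train = 1:4),
                                noise_spec(90, 9e-3, 1)),
               "outside the library")
})

test_that("the cGAN objective reduces to hand arithmetic", {
  cfg <- network_config(target = "sigma", lambda_gan = 0,
                        lambda_l1 = 100, lambda_l2 = 200)
  G <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2)
  Tg <- matrix(c(0.0, 0.5, 0.5, 1.0), 2, 2)
  ## L1 = mean(0.2, 0.1, 0.1, 0.2) = 0.15 ; L2 = mean of squares = 0.025
  obj <- cgan_objective(G, Tg, NULL, cfg)
  expect_equal(obj$generator, 100 * 0.15 + 200 * 0.025)
  expect_true(is.na(obj$discriminator))
  ## perfect output: both distances vanish
  obj0 <- cgan_objective(Tg, Tg, NULL, cfg)
  expect_equal(obj0$generator, 0)
  ## adversarial part requires patch scores
  cfg2 <- network_config(target = "sigma")
  expect_error(cgan_objective(G, Tg, NULL, cfg2), "patch scores")
  scores <- list(real = c(0.9, 0.8), fake = c(0.3, 0.4))
  obj2 <- cgan_objective(G, Tg, scores, cfg2)
  expect_equal(obj2$generator,
               2 * -mean(log(c(0.3, 0.4))) + 100 * 0.15 + 200 * 0.025)
  expect_equal(obj2$discriminator,
               -mean(log(c(0.9, 0.8))) - mean(log(1 - c(0.3, 0.4))))
})

test_that("a small network can overfit a handful of examples", {
  ds <- tiny_dataset()
  ds$train <- ds$train[1:10]
  ds$validation <- list()
  cfg <- network_config(target = "sigma", lambda_gan = 0, epochs = 60,
                        learning_rate = 4e-4, base_channels = 6, seed = 5)
  fit <- dlept(ds, cfg)
  ## training L1 below 5% of the (unit) normalized target range
  expect_lt(utils::tail(fit$history$loss_l1, 1), 0.05)
  ## loss decreased over training
  expect_lt(utils::tail(fit$history$loss_g, 1), fit$history$loss_g[1])
})

test_that("prediction is deterministic, masked, and channel-checked", {
  fit <- tiny_fit()
  fx <- phantom_small()
  nacq <- corrupt_acquisition(fx$acq, noise_spec(90, 9e-3, 77))
  p1 <- predict(fit, nacq)
  p2 <- predict(fit, nacq)
  expect_identical(p1$sigma_map, p2$sigma_map)
  expect_s3_class(p1, "ept_maps")
  expect_equal(p1$method, "cGAN_mask")
  ## air voxels are clamped to vacuum values
  expect_true(all(p1$sigma_map[!fx$model$mask] == 0))
  ## mismatched auxiliary channel is rejected
  acq_t <- make_acquisition(fx$sol, fx$model, "tissue_contrast")
  expect_error(predict(fit, acq_t), "auxiliary channel")
})

test_that("the U-Net ablation (lambda_gan = 0) runs the same pipeline", {
  ds <- tiny_dataset()
  cfg <- network_config(target = "sigma", lambda_gan = 0, epochs = 3,
                        base_channels = 4, seed = 9)
  fit <- dlept(ds, cfg)
  expect_true(all(is.na(fit$history$loss_d)))
  fx <- phantom_small()
  p <- predict(fit, corrupt_acquisition(fx$acq, noise_spec(90, 9e-3, 3)))
  expect_equal(p$method, "U-Net_mask")
  expect_true(all(is.finite(p$sigma_map)))
})

test_that("model selection minimizes mean validation NRMSE", {
  ds <- tiny_dataset()
  good <- tiny_fit()
  poor <- dlept(ds, network_config(target = "sigma", epochs = 1,
                                   base_channels = 4, seed = 3))
  sel <- select_model(list(poor, good), ds$validation)
  expect_equal(sel$index, 2)
  expect_lt(sel$scores[2], sel$scores[1])
  ## single candidate returns itself; ties break to the first index
  expect_equal(select_model(list(good), ds$validation)$index, 1)
  tie <- select_model(list(good, good), ds$validation)
  expect_equal(tie$index, 1)
  expect_error(select_model(list(), ds$validation), "no candidate")
})
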