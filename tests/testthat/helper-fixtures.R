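## Shared fixtures, built once per test session. The heavier ones back the
## acceptance checks and are reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## Agar-phantom analogue at full resolution with its solved fields.
phantom_full <- function() fixture("phantom_full", function() {
  model <- build_phantom_model(0.12, sigma = 0.88, epsr = 80)
  sol <- solve_fields(model)
  list(model = model, sol = sol, acq = make_acquisition(sol, model, "mask"))
})

## Same phantom on the desk-scale 64^2 grid.
phantom_small <- function() fixture("phantom_small", function() {
  model <- build_phantom_model(0.12, sigma = 0.88, epsr = 80,
                               grid_shape = c(64, 64), spacing = 0.004)
  sol <- solve_fields(model)
  list(model = model, sol = sol, acq = make_acquisition(sol, model, "mask"))
})

## Small training dataset (desk scale) for structural network tests.
tiny_dataset <- function() fixture("tiny_dataset", function() {
  lib <- build_phantom_library(n = 8, seed = 31, grid_shape = c(64, 64),
                               spacing = 0.004)
  assemble_dataset(lib, dataset_split(train = 1:6, validation = 7, test = 8),
                   noise_spec(90, 9e-3, seed = 5), target = "sigma",
                   slices_per_model = 2)
})

## A quick low-capacity fit used by prediction/selection tests.
tiny_fit <- function() fixture("tiny_fit", function() {
  dlept(tiny_dataset(),
        network_config(target = "sigma", epochs = 6, base_channels = 4,
                       seed = 3))
})

## Acceptance-scale experiments (shared across acceptance test blocks).
acceptance_phantom <- function() fixture("acceptance_phantom", function() {
  experiment_phantom_dlept(seed = 7)
})

acceptance_head <- function() fixture("acceptance_head", function() {
  experiment_head_hept(seed = 7)
})

acceptance_tumor <- function() fixture("acceptance_tumor", function() {
  experiment_tumor(seed = 7)
})

expect_rel_error <- function(value, target, tol) {
  expect_lt(abs(value - target) / abs(target), tol)
}
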