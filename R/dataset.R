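## Training-set assembly: simulated acquisitions become (input, target)
## image pairs for the network.

#' Count 2D field distributions in a simulation database
#'
#' Bookkeeping of the slice-wise dataset: each phantom model contributes
#' `slices_per_phantom` 2D field maps and each head model
#' `slices_per_head`.
#'
#' @param n_phantoms,slices_per_phantom,n_heads,slices_per_head counts
#' @return total number of 2D field distributions
#' @examples
#' count_dataset_slices(42, 25, 20, 56)  # full database: 2170
#' @export
count_dataset_slices <- function(n_phantoms, slices_per_phantom,
                                 n_heads, slices_per_head) {
  stopifnot(n_phantoms >= 0, slices_per_phantom >= 0,
            n_heads >= 0, slices_per_head >= 0)
  n_phantoms * slices_per_phantom + n_heads * slices_per_head
}

#' Dataset split by model identity
#'
#' Models used for testing or validation never contribute training examples.
#'
#' @param train,validation,test integer vectors of model indices
#' @return a `dataset_split`
#' @export
dataset_split <- function(train, validation = integer(), test = integer()) {
  ids <- c(train, validation, test)
  if (anyDuplicated(ids))
    stop("train/validation/test splits must be pairwise disjoint")
  structure(list(train = train, validation = validation, test = test),
            class = "dataset_split")
}

## Integer translation with zero fill, shared by all channels of a slice.
.shift2 <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
  cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## Normalized network input stack from an acquisition (possibly noisy).
## Magnitude is re-normalized by its in-mask mean (the only normalization
## available at measurement time); phase is scaled by pi.
acq_to_input <- function(acq) {
  magn <- acq$magnitude / mean(acq$magnitude[acq$mask])
  cbind(as.vector(magn), as.vector(acq$phase) / pi, as.vector(acq$aux))
}

.normalize_target <- function(map, range) {
  (as.vector(map) - range[1]) / (range[2] - range[1])
}

.denormalize_target <- function(v, range) {
  v * (range[2] - range[1]) + range[1]
}

#' Assemble a training dataset from tissue models
#'
#' Solves the forward electromagnetic problem once per model, then emulates
#' multiple acquired slices per model by independent noise injections and
#' small integer-voxel translations. Each example pairs the normalized
#' 3-channel input (transmit magnitude, phase, auxiliary channel) with the
#' model's ground-truth property map scaled to the network's `[0, 1]` range.
#'
#' @param models list of `tissue_model` objects on a common grid
#' @param split a [dataset_split()] over model indices
#' @param noise a [noise_spec()]; its seed drives all slice noise
#' @param aux `"mask"` or `"tissue_contrast"`
#' @param target `"sigma"` or `"epsr"`
#' @param slices_per_model emulated slices per model
#' @param jitter maximum translation (voxels) applied per slice
#' @param coil a [coil_config()]
#' @param sigma_range,epsr_range target normalization ranges
#' @param acqs optional list of precomputed clean acquisitions (parallel to
#'   `models`), avoiding repeated field solves when assembling several
#'   datasets over the same library
#' @param verbose print progress
#' @return an `ept_dataset` with `train`, `validation`, `test` example lists
#' @export
assemble_dataset <- function(models, split, noise = noise_spec(),
                             aux = c("mask", "tissue_contrast"),
                             target = c("sigma", "epsr"),
                             slices_per_model = 5, jitter = 2,
                             coil = coil_config(),
                             sigma_range = c(0, 2.5), epsr_range = c(1, 100),
                             acqs = NULL, verbose = FALSE) {
  aux <- match.arg(aux)
  target <- match.arg(target)
  ids <- c(split$train, split$validation, split$test)
  if (max(ids) > length(models) || min(ids) < 1)
    stop("split references models outside the library")
  range <- if (target == "sigma") sigma_range else epsr_range
  seeds <- derive_seeds(noise$seed, length(models) * slices_per_model + 1)
  jit_seed <- seeds[length(seeds)]
  jits <- with_seed(jit_seed, matrix(
    sample(seq(-jitter, jitter), 2 * length(models) * slices_per_model,
           replace = TRUE), ncol = 2))
  out <- list(train = list(), validation = list(), test = list())
  k <- 0
  for (mi in sort(ids)) {
    model <- models[[mi]]
    acq <- if (!is.null(acqs)) acqs[[mi]]
           else make_acquisition(solve_fields(model, coil), model, aux)
    truth <- if (target == "sigma") model$sigma_map else model$epsr_map
    fill <- if (target == "sigma") 0 else 1
    bucket <- if (mi %in% split$train) "train"
              else if (mi %in% split$validation) "validation" else "test"
    for (s in seq_len(slices_per_model)) {
      k <- k + 1
      nacq <- corrupt_acquisition(acq, noise_spec(noise$snr_mag,
                                                  noise$phase_sd,
                                                  seed = seeds[k]))
      dr <- jits[k, 1]; dc <- jits[k, 2]
      magn <- .shift2(nacq$magnitude, dr, dc)
      phase <- .shift2(nacq$phase, dr, dc)
      auxc <- .shift2(nacq$aux, dr, dc)
      mask <- .shift2(model$mask * 1, dr, dc) > 0.5
      tr <- .shift2(truth, dr, dc, fill = fill)
      x <- cbind(as.vector(magn) / mean(magn[mask]),
                 as.vector(phase) / pi,
                 as.vector(auxc))
      ex <- list(x = x, y = matrix(.normalize_target(tr, range), ncol = 1),
                 truth = tr, mask = mask, model_id = mi, slice = s)
      out[[bucket]][[length(out[[bucket]]) + 1]] <- ex
    }
    if (verbose) message("model ", mi, " (", bucket, ") done")
  }
  structure(list(train = out$train, validation = out$validation,
                 test = out$test, aux = aux, target = target,
                 image_size = nrow(models[[1]]$label_grid),
                 spacing = models[[1]]$spacing,
                 omega = 2 * pi * larmor_frequency(),
                 sigma_range = sigma_range, epsr_range = epsr_range,
                 noise = noise),
            class = "ept_dataset")
}

#' @export
print.ept_dataset <- function(x, ...) {
  cat("EPs dataset (target ", x$target, ", aux ", x$aux, "): ",
      length(x$train), " train / ", length(x$validation), " validation / ",
      length(x$test), " test examples @ ", x$image_size, "^2\n", sep = "")
  invisible(x)
}
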