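## The fitted reconstruction model: training interface and S3 methods.

#' Fit a deep-learning EPs reconstructor
#'
#' Trains the conditional GAN (or, with `lambda_gan = 0`, a plain U-Net) to
#' translate simulated acquisition stacks into a conductivity or permittivity
#' map. The fit is deterministic given the configuration seed.
#'
#' @param dataset an [assemble_dataset()] result; its `train` examples drive
#'   the optimization
#' @param config a [network_config()]; target and image size default to the
#'   dataset's
#' @param init optional fitted `dlept` object whose generator weights
#'   initialize this fit (warm start; e.g. a conductivity fit seeding the
#'   permittivity network of the same training repetition)
#' @param verbose print per-epoch losses
#' @return a fitted `dlept` object with methods [predict.dlept()],
#'   `print`, `summary` and `plot`
#' @export
dlept <- function(dataset, config = NULL, init = NULL, verbose = FALSE) {
  if (!inherits(dataset, "ept_dataset")) stop("dataset must be an ept_dataset")
  if (is.null(config))
    config <- network_config(target = dataset$target,
                             image_size = dataset$image_size)
  if (config$target != dataset$target)
    stop("config target (", config$target, ") does not match dataset (",
         dataset$target, ")")
  if (config$image_size != dataset$image_size)
    stop("config image size does not match dataset")
  config$sigma_range <- dataset$sigma_range
  config$epsr_range <- dataset$epsr_range
  fit <- train_cgan(dataset$train, config, validation = dataset$validation,
                    init_G = if (!is.null(init)) init$G,
                    verbose = verbose)
  obj <- structure(list(
    G = fit$G, D = fit$D, config = config, history = fit$history,
    aux_type = dataset$aux, target = config$target,
    spacing = dataset$spacing, omega = dataset$omega,
    n_train = length(dataset$train)
  ), class = "dlept")
  if (length(dataset$validation) > 0)
    obj$validation_nrmse <- validation_nrmse(obj, dataset$validation)
  obj
}

#' Mean NRMSE of a fitted model over a set of examples
#'
#' @param object a `dlept` fit
#' @param examples list of dataset examples (with `truth` and `mask`)
#' @return mean masked NRMSE against the ground truth
#' @export
validation_nrmse <- function(object, examples) {
  vals <- vapply(examples, function(ex) {
    pred <- .predict_example(object, ex$x, ex$mask)
    nrmse(pred, ex$truth, ex$mask)
  }, numeric(1))
  mean(vals)
}

## Forward pass + denormalization + air clamping on a raw input stack.
.predict_example <- function(object, x, mask) {
  yhat <- unet_forward(object$G, x)$y
  range <- .target_range(object$config)
  map <- matrix(.denormalize_target(yhat, range),
                object$config$image_size, object$config$image_size)
  bg <- if (object$target == "sigma") 0 else 1
  map[!mask] <- bg
  map
}

#' Reconstruct electrical properties with a fitted network
#'
#' @param object a `dlept` fit
#' @param acq an `acquisition` whose auxiliary channel matches the one the
#'   network was trained with
#' @param ... unused
#' @return an `ept_maps` object (the non-target map is left `NA`)
#' @export
predict.dlept <- function(object, acq, ...) {
  if (!inherits(acq, "acquisition")) stop("acq must be an acquisition")
  if (acq$aux_type != object$aux_type)
    stop("acquisition auxiliary channel (", acq$aux_type,
         ") does not match the network's training input (",
         object$aux_type, ")")
  if (nrow(acq$magnitude) != object$config$image_size)
    stop("acquisition grid does not match the network's image size")
  map <- .predict_example(object, acq_to_input(acq), acq$mask)
  method <- paste0(if (object$config$lambda_gan > 0) "cGAN_" else "U-Net_",
                   object$aux_type)
  na <- matrix(NA_real_, nrow(map), ncol(map))
  if (object$target == "sigma")
    new_ept_maps(map, na, method, acq$mask, acq$spacing)
  else
    new_ept_maps(na, map, method, acq$mask, acq$spacing)
}

#' Select the best candidate model on a validation set
#'
#' Returns the candidate with the lowest average NRMSE over the validation
#' examples. A candidate may be a single `dlept` fit or a list of fits (e.g.
#' a conductivity/permittivity pair, validated on the mean of the two);
#' validation sets are supplied per target in the same order.
#'
#' @param candidates non-empty list of candidates
#' @param validation list of example lists: one per fit within a candidate
#' @return list with `model` (the winner), `index`, and `scores`
#' @export
select_model <- function(candidates, validation) {
  if (length(candidates) == 0) stop("no candidate models")
  if (!is.list(validation[[1]]) || !is.null(validation[[1]]$x))
    validation <- list(validation)
  scores <- vapply(candidates, function(cand) {
    fits <- if (inherits(cand, "dlept")) list(cand) else cand
    mean(vapply(seq_along(fits), function(i)
      validation_nrmse(fits[[i]], validation[[min(i, length(validation))]]),
      numeric(1)))
  }, numeric(1))
  index <- which.min(scores)    # which.min takes the first: deterministic ties
  list(model = candidates[[index]], index = index, scores = scores)
}

#' @export
print.dlept <- function(x, ...) {
  cat("DL-EPT reconstructor (", x$target, ", aux = ", x$aux_type, ")\n",
      sep = "")
  cat(sprintf("  %s, %d levels, base width %d, %d^2 voxels\n",
              if (x$config$lambda_gan > 0) "cGAN (U-Net + PatchGAN)"
              else "U-Net (lambda_gan = 0)",
              x$config$depth, x$config$base_channels, x$config$image_size))
  cat(sprintf("  lambda: gan %g, L1 %g, L2 %g | %d epochs on %d examples\n",
              x$config$lambda_gan, x$config$lambda_l1, x$config$lambda_l2,
              x$config$epochs, x$n_train))
  cat(sprintf("  final training loss %.4f (L1 %.4f)\n",
              utils::tail(x$history$loss_g, 1),
              utils::tail(x$history$loss_l1, 1)))
  if (!is.null(x$validation_nrmse))
    cat(sprintf("  validation NRMSE %.4f\n", x$validation_nrmse))
  invisible(x)
}

#' @export
summary.dlept <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.dlept <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$loss_g, type = "l", xlab = "epoch", ylab = "loss",
       main = paste("Training loss:", x$target), ...)
  lines(h$epoch, x$config$lambda_l1 * h$loss_l1, lty = 2)
  legend("topright", c("generator objective", "weighted L1 term"),
         lty = c(1, 2), bty = "n")
  invisible(x)
}
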