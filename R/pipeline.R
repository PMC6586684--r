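## Experiment configuration and the staged pipeline binding the modules
## together: simulate -> corrupt -> reconstruct -> evaluate.

#' Experiment configuration
#'
#' A fully serializable description of a run; its hash identifies the run
#' and every stochastic stage draws from the master seed.
#'
#' @param model_type `"phantom"` or `"head"`
#' @param grid_shape,spacing simulation grid
#' @param sigma,epsr phantom properties (phantom model only)
#' @param noise list with `snr` and `phase_sd`
#' @param kernel_support Laplacian kernel support
#' @param aux auxiliary acquisition channel
#' @param seed master seed
#' @return an `ept_config`
#' @export
ept_config <- function(model_type = c("phantom", "head"),
                       grid_shape = c(128, 128), spacing = 0.002,
                       sigma = 0.88, epsr = 80,
                       noise = list(snr = 90, phase_sd = 9e-3),
                       kernel_support = c(7, 7),
                       aux = "mask", seed = 1) {
  structure(list(model_type = match.arg(model_type),
                 grid_shape = grid_shape, spacing = spacing,
                 sigma = sigma, epsr = epsr, noise = noise,
                 kernel_support = kernel_support, aux = aux, seed = seed),
            class = "ept_config")
}

#' Read an experiment configuration from a JSON or YAML file
#'
#' @param path file path (`.json`, `.yaml` or `.yml`)
#' @return an `ept_config`
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ept_config, vals)
}

#' Run pipeline stages for a configured experiment
#'
#' Executes the requested stages in dependency order, writes all artifacts
#' under `out_dir` and returns a manifest (config hash, seeds, artifact
#' checksums). Later stages require the in-memory products of earlier ones,
#' so requesting e.g. `"hept"` implies `"simulate"` and `"corrupt"`.
#'
#' @param config an [ept_config()]
#' @param stages subset of `c("simulate", "corrupt", "hept", "evaluate")`
#' @param out_dir output directory (created if missing)
#' @return the manifest, invisibly written to `manifest.json`
#' @export
run_pipeline <- function(config, stages = c("simulate", "corrupt", "hept",
                                            "evaluate"),
                         out_dir = tempfile("ept_run_")) {
  stages <- match.arg(stages, several.ok = TRUE)
  order <- c("simulate", "corrupt", "hept", "evaluate")
  needed <- order[seq_len(max(match(stages, order)))]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  model <- if (config$model_type == "phantom")
    build_phantom_model(0.12, config$sigma, config$epsr,
                        config$grid_shape, config$spacing)
  else build_head_model(seed = config$seed, grid_shape = config$grid_shape,
                        spacing = config$spacing)
  acq <- NULL; nacq <- NULL; maps <- NULL
  if ("simulate" %in% needed) {
    sol <- solve_fields(model)
    acq <- make_acquisition(sol, model, config$aux)
    artifacts <- c(artifacts,
                   write_tissue_model(model, file.path(out_dir, "model")),
                   write_acquisition(acq, file.path(out_dir, "acq.nii.gz")))
  }
  if ("corrupt" %in% needed) {
    nacq <- corrupt_acquisition(acq, noise_spec(config$noise$snr,
                                                config$noise$phase_sd,
                                                seed = config$seed))
    artifacts <- c(artifacts,
                   write_acquisition(nacq,
                                     file.path(out_dir, "acq_noisy.nii.gz")))
  }
  if ("hept" %in% needed) {
    kern <- build_noise_robust_kernel(config$kernel_support, config$spacing)
    maps <- hept_reconstruct(nacq, kern)
    artifacts <- c(artifacts,
                   write_ept_maps(maps, file.path(out_dir, "sigma.nii.gz"),
                                  file.path(out_dir, "epsr.nii.gz")))
  }
  if ("evaluate" %in% needed) {
    st <- roi_statistics(maps, model$label_grid)
    rp <- file.path(out_dir, "report.csv")
    utils::write.csv(st, rp, row.names = FALSE)
    jsonlite::write_json(st, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    artifacts <- c(artifacts, rp, file.path(out_dir, "report.json"))
  }
  manifest <- list(
    config = unclass(config),
    config_hash = object_hash(unclass(config)),
    stages = needed,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) unname(tools::md5sum(p))),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
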