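## NIfTI serialization of maps, models and acquisitions, plus JSON reports.
## Complex arrays are stored as magnitude/phase or real/imaginary volume
## pairs; voxel spacing travels in the NIfTI header (mm).

.as_nifti <- function(arr, spacing) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- rep(spacing * 1000, length(dim(arr)))
  im
}

#' Write reconstructed property maps to NIfTI
#'
#' @param maps an `ept_maps` object
#' @param sigma_path,epsr_path output file paths (`.nii` / `.nii.gz`)
#' @return invisibly, the paths
#' @export
write_ept_maps <- function(maps, sigma_path, epsr_path) {
  s <- .as_nifti(maps$sigma_map, maps$spacing)
  e <- .as_nifti(maps$epsr_map, maps$spacing)
  attr(s, "description") <- maps$method
  RNifti::writeNifti(s, sigma_path)
  RNifti::writeNifti(e, epsr_path)
  invisible(c(sigma_path, epsr_path))
}

#' Write a tissue model to NIfTI (one volume per map)
#'
#' @param model a `tissue_model`
#' @param prefix path prefix; writes `<prefix>_labels.nii.gz`,
#'   `<prefix>_sigma.nii.gz`, `<prefix>_epsr.nii.gz`
#' @return invisibly, the written paths
#' @export
write_tissue_model <- function(model, prefix) {
  paths <- paste0(prefix, c("_labels", "_sigma", "_epsr"), ".nii.gz")
  RNifti::writeNifti(.as_nifti(model$label_grid + 0, model$spacing), paths[1])
  RNifti::writeNifti(.as_nifti(model$sigma_map, model$spacing), paths[2])
  RNifti::writeNifti(.as_nifti(model$epsr_map, model$spacing), paths[3])
  invisible(paths)
}

#' Read a tissue model written by [write_tissue_model()]
#'
#' @param prefix the path prefix used when writing
#' @return a `tissue_model`
#' @export
read_tissue_model <- function(prefix) {
  paths <- paste0(prefix, c("_labels", "_sigma", "_epsr"), ".nii.gz")
  lab <- RNifti::readNifti(paths[1])
  spacing <- RNifti::pixdim(lab)[1] / 1000
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  sig <- as.matrix(RNifti::readNifti(paths[2]))
  eps <- as.matrix(RNifti::readNifti(paths[3]))
  labs <- setdiff(sort(unique(as.vector(lab))), 0L)
  props <- do.call(rbind, lapply(labs, function(l) data.frame(
    label = l,
    tissue = .tissue_table_128$tissue[match(l, .tissue_table_128$label)],
    sigma = sig[lab == l][1], epsr = eps[lab == l][1])))
  new_tissue_model(lab, props, spacing)
}

#' Write an acquisition to NIfTI
#'
#' All channels (magnitude, phase, auxiliary) in one 3-volume file; the
#' clean complex field is stored alongside as real/imaginary volumes so the
#' round-trip is lossless.
#'
#' @param acq an `acquisition`
#' @param path output path for the channel stack
#' @return invisibly, the written paths
#' @export
write_acquisition <- function(acq, path) {
  arr <- array(0, c(nrow(acq$magnitude), ncol(acq$magnitude), 3))
  arr[, , 1] <- acq$magnitude
  arr[, , 2] <- acq$phase
  arr[, , 3] <- acq$aux
  RNifti::writeNifti(.as_nifti(arr, acq$spacing), path)
  side <- sub("\\.nii(\\.gz)?$", "_field.nii.gz", path)
  fld <- array(0, c(dim(acq$magnitude), 3))
  fld[, , 1] <- Re(acq$b1p_clean)
  fld[, , 2] <- Im(acq$b1p_clean)
  fld[, , 3] <- acq$mask
  RNifti::writeNifti(.as_nifti(fld, acq$spacing), side)
  meta <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(aux_type = acq$aux_type, snr = acq$snr,
                            phase_sd = acq$phase_sd,
                            omega = acq$omega, spacing = acq$spacing),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side, meta))
}

#' Read an acquisition written by [write_acquisition()]
#'
#' @param path the channel-stack path used when writing
#' @return an `acquisition`
#' @export
read_acquisition <- function(path) {
  arr <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", "_field.nii.gz", path)
  fld <- RNifti::readNifti(side)
  meta <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  structure(list(
    magnitude = arr[, , 1], phase = arr[, , 2], aux = arr[, , 3],
    aux_type = meta$aux_type,
    b1p_clean = matrix(complex(real = fld[, , 1], imaginary = fld[, , 2]),
                       dim(arr)[1], dim(arr)[2]),
    mask = fld[, , 3] > 0.5,
    spacing = meta$spacing, omega = meta$omega,
    snr = if (is.null(meta$snr) || meta$snr == "Inf") Inf
          else as.numeric(meta$snr),
    phase_sd = meta$phase_sd
  ), class = "acquisition")
}

## Stable hash of an R object (serialized to a temp file, md5).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
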