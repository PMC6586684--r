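## Quantitative evaluation: per-tissue statistics, error metrics, noise
## sweeps and the tumor-contrast harness.

#' Per-tissue statistics of reconstructed property maps
#'
#' Mean and population standard deviation of conductivity and permittivity
#' over each eroded tissue region, intersected with the map's valid mask.
#'
#' @param maps an `ept_maps` object
#' @param labels integer tissue label matrix
#' @param erosion erosion radius in voxels applied to each region (default 3)
#' @param tissue_names optional named translation of labels
#' @return a data.frame with one row per surviving tissue region
#' @export
roi_statistics <- function(maps, labels, erosion = 3, tissue_names = NULL) {
  er <- erode_rois(labels, erosion)
  labs <- setdiff(sort(unique(as.vector(er))), 0L)
  rows <- lapply(labs, function(l) {
    roi <- er == l & maps$valid_mask
    if (!any(roi)) {
      warning("eroded region for label ", l,
              " has no valid voxels; omitted")
      return(NULL)
    }
    psd <- function(x) sqrt(mean((x - mean(x))^2))
    nm <- if (!is.null(tissue_names)) tissue_names[[as.character(l)]]
          else .tissue_table_128$tissue[match(l, .tissue_table_128$label)]
    data.frame(label = l, tissue = if (is.null(nm) || is.na(nm))
                 as.character(l) else nm,
               n_voxels = sum(roi),
               sigma_mean = mean(maps$sigma_map[roi]),
               sigma_sd = psd(maps$sigma_map[roi]),
               epsr_mean = mean(maps$epsr_map[roi]),
               epsr_sd = psd(maps$epsr_map[roi]))
  })
  do.call(rbind, rows)
}

#' Normalized root-mean-square error
#'
#' RMSE over the mask divided by the mean of the ground truth over the mask.
#'
#' @param recon,truth matrices on a common grid
#' @param mask boolean evaluation region
#' @return scalar NRMSE
#' @export
nrmse <- function(recon, truth, mask) {
  if (!any(mask)) stop("empty evaluation mask")
  mt <- mean(truth[mask])
  if (mt == 0) stop("ground truth has zero mean over the mask")
  sqrt(mean((recon[mask] - truth[mask])^2)) / mt
}

#' Relative error of a reconstructed mean value, in percent
#'
#' @param recon_mean reconstructed ROI mean
#' @param truth ground-truth value (nonzero)
#' @return `100 * |recon_mean - truth| / truth`
#' @export
relative_error <- function(recon_mean, truth) {
  if (any(truth == 0)) stop("relative error undefined for zero truth")
  100 * abs(recon_mean - truth) / truth
}

#' Reconstruction statistics across noise levels
#'
#' Repeats noise injection and reconstruction at each SNR level with
#' independent seeds and tabulates per-tissue means and standard deviations.
#'
#' @param reconstruct function mapping an `acquisition` to `ept_maps`
#'   (e.g. [hept_reconstruct()] or `function(a) predict(fit, a)`)
#' @param acq a clean `acquisition`
#' @param labels tissue label matrix of the generating model
#' @param snr_levels numeric vector of magnitude SNRs (may include `Inf`)
#' @param phase_sd phase-noise SD in rad; scaled as `90 / snr * 9e-3` when
#'   `NULL` so both noise sources track the SNR level
#' @param seeds one integer seed per repetition at each level
#' @param erosion ROI erosion in voxels
#' @return a data.frame of per-tissue statistics by SNR and seed
#' @export
snr_sweep <- function(reconstruct, acq, labels, snr_levels = c(20, 45, 90),
                      phase_sd = NULL, seeds = 1:3, erosion = 3) {
  rows <- list()
  for (snr in snr_levels) {
    psd <- if (!is.null(phase_sd)) phase_sd
           else if (is.infinite(snr)) 0 else 9e-3 * 90 / snr
    for (s in seeds) {
      nacq <- corrupt_acquisition(acq, noise_spec(snr, psd, seed = s))
      maps <- reconstruct(nacq)
      st <- roi_statistics(maps, labels, erosion)
      if (is.null(st)) next
      st$snr <- snr; st$seed <- s; st$method <- maps$method
      rows[[length(rows) + 1]] <- st
    }
  }
  do.call(rbind, rows)
}

#' Tumor detection experiment
#'
#' Reconstructs a head model carrying a tumor inclusion with networks that
#' never saw tumor tissue during training, and compares tumor conspicuity
#' against the Helmholtz baseline. Contrast-to-noise ratio is defined as
#' `|mean(tumor) - mean(surround)| / SD(surround)` with the surround taken
#' from the eroded host tissue.
#'
#' @param tumor_model a `tissue_model` containing the tumor label
#' @param fits list with elements `sigma` and `epsr`: fitted `dlept` models
#' @param noise a [noise_spec()]
#' @param coil a [coil_config()]
#' @param erosion ROI erosion in voxels (applied on each model's own grid)
#' @param hept_model optional `tissue_model`: the same physical scene on the
#'   acquisition-native grid for the Helmholtz arm (the analytic baseline
#'   needs no training and runs at measurement resolution); defaults to
#'   `tumor_model`
#' @param hept_erosion ROI erosion for the Helmholtz arm
#' @return list with per-method ROI tables, tumor relative errors and CNR
#' @export
tumor_experiment <- function(tumor_model, fits, noise = noise_spec(),
                             coil = coil_config(), erosion = 3,
                             hept_model = NULL, hept_erosion = 3) {
  tl <- .tissue_label("tumor")
  if (!any(tumor_model$label_grid == tl))
    stop("model carries no tumor label")
  sol <- solve_fields(tumor_model, coil)
  acq_m <- make_acquisition(sol, tumor_model, "mask")
  nacq <- corrupt_acquisition(acq_m, noise)
  dl_sigma <- predict(fits$sigma, nacq)
  dl_epsr <- predict(fits$epsr, nacq)
  dl_maps <- new_ept_maps(dl_sigma$sigma_map, dl_epsr$epsr_map,
                          dl_sigma$method, dl_sigma$valid_mask,
                          dl_sigma$spacing)
  if (is.null(hept_model)) {
    hept_model <- tumor_model
    hept_erosion <- erosion
  }
  hept_nacq <- if (identical(hept_model, tumor_model)) nacq else
    corrupt_acquisition(make_acquisition(solve_fields(hept_model, coil),
                                         hept_model, "mask"), noise)
  hept_maps <- hept_reconstruct(hept_nacq)
  truth <- tumor_model$properties
  tumor_truth <- truth[truth$label == tl, ]
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  eval_one <- function(maps, labels, ero) {
    er <- erode_rois(labels, ero)
    roi_t <- er == tl & maps$valid_mask
    roi_s <- er == .tissue_label("WM") & maps$valid_mask  # host tissue
    if (!any(roi_t) || !any(roi_s)) return(NULL)
    cnr <- function(m) abs(mean(m[roi_t]) - mean(m[roi_s])) / psd(m[roi_s])
    list(
      tumor_sigma = mean(maps$sigma_map[roi_t]),
      tumor_epsr = mean(maps$epsr_map[roi_t]),
      tumor_sigma_sd = psd(maps$sigma_map[roi_t]),
      tumor_epsr_sd = psd(maps$epsr_map[roi_t]),
      rel_error_sigma = relative_error(mean(maps$sigma_map[roi_t]),
                                       tumor_truth$sigma),
      rel_error_epsr = relative_error(mean(maps$epsr_map[roi_t]),
                                      tumor_truth$epsr),
      cnr_sigma = cnr(maps$sigma_map),
      cnr_epsr = cnr(maps$epsr_map)
    )
  }
  list(hept = eval_one(hept_maps, hept_model$label_grid, hept_erosion),
       dlept = eval_one(dl_maps, tumor_model$label_grid, erosion),
       truth = tumor_truth, maps = list(hept = hept_maps, dlept = dl_maps),
       acquisition = nacq)
}
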