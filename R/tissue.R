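## Tissue models: label maps plus piecewise-constant electrical properties.

## Literature dielectric properties at 128 MHz (3 T). Conductivity in S/m,
## relative permittivity dimensionless. "phantom" is the agar-phantom analogue.
.tissue_table_128 <- data.frame(
  tissue = c("air", "WM", "GM", "CSF", "phantom", "tumor"),
  label  = c(0L, 1L, 2L, 3L, 4L, 5L),
  sigma  = c(0, 0.34, 0.59, 2.14, 0.88, 1.4),
  epsr   = c(1, 52.6, 73.4, 84, 80, 73),
  stringsAsFactors = FALSE
)

.tissue_label <- function(tissue) {
  .tissue_table_128$label[match(tissue, .tissue_table_128$tissue)]
}

#' Look up literature tissue electrical properties
#'
#' Ground-truth conductivity and relative permittivity of brain tissues and
#' phantom material at the 3 T Larmor frequency (128 MHz).
#'
#' @param tissue one of `"air"`, `"WM"`, `"GM"`, `"CSF"`, `"phantom"`, `"tumor"`
#' @param frequency operating frequency in Hz; only 128 MHz is tabulated
#' @return a list with `tissue`, `sigma` (S/m), `epsr`, `frequency`
#' @examples
#' lookup_tissue_properties("WM")
#' @export
lookup_tissue_properties <- function(tissue, frequency = larmor_frequency()) {
  if (!isTRUE(all.equal(frequency, 128e6)))
    stop("only the 128 MHz (3 T) property table is available")
  i <- match(tissue, .tissue_table_128$tissue)
  if (is.na(i)) stop("unknown tissue: ", tissue)
  list(tissue = tissue, sigma = .tissue_table_128$sigma[i],
       epsr = .tissue_table_128$epsr[i], frequency = frequency)
}

## Construct and validate a tissue_model from a label grid and per-label EPs.
## props: data.frame with columns label, sigma, epsr (must cover all labels != 0)
new_tissue_model <- function(label_grid, props, spacing,
                             tissue_names = NULL) {
  storage.mode(label_grid) <- "integer"
  sigma_map <- matrix(0, nrow(label_grid), ncol(label_grid))
  epsr_map <- matrix(1, nrow(label_grid), ncol(label_grid))
  labs <- sort(unique(as.vector(label_grid)))
  labs <- labs[labs != 0L]
  for (l in labs) {
    i <- match(l, props$label)
    if (is.na(i)) stop("no properties supplied for label ", l)
    if (props$sigma[i] < 0) stop("conductivity must be non-negative")
    if (props$epsr[i] < 1) stop("relative permittivity must be >= 1 in tissue")
    sel <- label_grid == l
    sigma_map[sel] <- props$sigma[i]
    epsr_map[sel] <- props$epsr[i]
  }
  structure(list(
    label_grid = label_grid,
    sigma_map = sigma_map,
    epsr_map = epsr_map,
    spacing = spacing,
    mask = label_grid != 0L,
    properties = props[props$label %in% labs, , drop = FALSE],
    tissue_names = tissue_names
  ), class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("Tissue model:", nrow(x$label_grid), "x", ncol(x$label_grid),
      "voxels @", x$spacing * 1e3, "mm\n")
  cat("  object voxels:", sum(x$mask), "\n")
  p <- x$properties
  for (i in seq_len(nrow(p))) {
    nm <- if (!is.null(p$tissue)) p$tissue[i] else paste("label", p$label[i])
    cat(sprintf("  %-8s sigma = %.3g S/m, eps_r = %.4g\n", nm,
                p$sigma[i], p$epsr[i]))
  }
  invisible(x)
}

#' Build a homogeneous cylindrical phantom model (2D cross-section)
#'
#' A centered disk of the given diameter with uniform electrical properties,
#' surrounded by air, emulating the homogeneous cylinder phantoms used to
#' train and test the reconstruction networks.
#'
#' @param diameter disk diameter in m (default 0.12, a 12 cm phantom)
#' @param sigma conductivity in S/m
#' @param epsr relative permittivity (>= 1)
#' @param grid_shape integer vector (rows, cols)
#' @param spacing voxel size in m
#' @return a `tissue_model`
#' @examples
#' ph <- build_phantom_model(0.12, sigma = 0.88, epsr = 80)
#' @export
build_phantom_model <- function(diameter = 0.12, sigma, epsr,
                                grid_shape = c(128, 128), spacing = 0.002) {
  if (diameter <= 0) stop("phantom diameter must be positive")
  if (diameter >= min(grid_shape) * spacing)
    stop("phantom diameter exceeds the grid extent")
  if (sigma < 0) stop("conductivity must be non-negative")
  if (epsr < 1) stop("relative permittivity must be >= 1")
  co <- grid_coords(grid_shape, spacing)
  lab <- matrix(0L, grid_shape[1], grid_shape[2])
  lab[co$x^2 + co$y^2 <= (diameter / 2)^2] <- .tissue_label("phantom")
  new_tissue_model(lab,
                   data.frame(label = .tissue_label("phantom"),
                              tissue = "phantom", sigma = sigma, epsr = epsr),
                   spacing)
}

#' Build a library of homogeneous phantom models
#'
#' Samples `n` distinct (conductivity, permittivity) pairs uniformly from the
#' given ranges and builds one phantom model for each. The default ranges
#' bracket the brain-tissue and agar-phantom values at 128 MHz.
#'
#' @param n number of phantoms (default 42)
#' @param sigma_range conductivity range in S/m
#' @param epsr_range relative permittivity range
#' @param seed integer seed; the library is reproducible under it
#' @inheritParams build_phantom_model
#' @return a list of `tissue_model` objects; each carries its sampled values
#' @export
build_phantom_library <- function(n = 42, sigma_range = c(0.2, 2.2),
                                  epsr_range = c(40, 90), seed = 1,
                                  diameter = 0.12, grid_shape = c(128, 128),
                                  spacing = 0.002) {
  if (n < 1) stop("need at least one phantom")
  if (any(sigma_range <= 0) || any(epsr_range < 1))
    stop("property ranges must be positive (eps_r >= 1)")
  if (n > 1 && (diff(sigma_range) <= 0 || diff(epsr_range) <= 0))
    stop("degenerate property range cannot yield distinct phantoms")
  vals <- with_seed(seed, {
    ## stratified sampling: spread conductivities across the range so small
    ## libraries still cover it, with a random permutation for permittivity
    s <- sigma_range[1] + diff(sigma_range) *
      (sample(n) - runif(n)) / n
    e <- epsr_range[1] + diff(epsr_range) *
      (sample(n) - runif(n)) / n
    cbind(s, e)
  })
  lapply(seq_len(n), function(i)
    build_phantom_model(diameter, vals[i, 1], vals[i, 2], grid_shape, spacing))
}

## Perturbed-ellipse radius profile: base radius modulated by low-order
## sinusoids to create non-convex, "convoluted" boundaries. Terms even in phi
## preserve bilateral (left-right) symmetry; odd terms, scaled by `asym`,
## introduce the mild asymmetry of real anatomy.
.wobbly_radius <- function(phi, r0, amp, harmonics, phases, asym) {
  r <- rep(r0, length(phi))
  for (j in seq_along(harmonics))
    r <- r + amp[j] * (cos(harmonics[j] * phi) * cos(phases[j] * asym) +
                         asym * sin(harmonics[j] * phi + phases[j]))
  r
}

#' Build a procedural head-like tissue model
#'
#' A 2D stand-in for an anatomical head slice: nested, sinusoidally perturbed
#' shells of CSF (outer rim), gray matter (ribbon) and white matter (core),
#' plus two CSF ventricle-like inclusions in the core. Per-tissue properties
#' are the 128 MHz literature values perturbed by up to `eps_variation`
#' (relative), constant within each tissue.
#'
#' @param seed integer seed controlling geometry and property perturbation
#' @param eps_variation maximum relative perturbation of the per-tissue
#'   properties (0 gives exactly the literature values)
#' @param grid_shape integer vector (rows, cols)
#' @param spacing voxel size in m
#' @param head_radius mean outer radius in m
#' @param asymmetry fraction of boundary perturbation that breaks the
#'   bilateral (left-right) symmetry of the head; real heads are close to
#'   mirror-symmetric with respect to the quadrature coil, which is also the
#'   regime in which the transceive phase assumption is accurate at 3 T
#' @return a `tissue_model` with labels air(0)/WM(1)/GM(2)/CSF(3)
#' @export
build_head_model <- function(seed = 1, eps_variation = 0.1,
                             grid_shape = c(128, 128), spacing = 0.002,
                             head_radius = 0.088, asymmetry = 0.2) {
  if (eps_variation < 0) stop("eps_variation must be non-negative")
  geo <- with_seed(seed, list(
    harm = sample(2:5, 3),
    ph_out = runif(3, 0, 2 * pi),
    ph_gm = runif(3, 0, 2 * pi),
    ph_wm = runif(3, 0, 2 * pi),
    ecc = runif(1, 0.85, 1.1),
    vent_dx = runif(1, -0.05, 0.05),
    vent_dy = runif(1, 0.16, 0.24),
    pert = runif(3, -eps_variation, eps_variation)
  ))
  co <- grid_coords(grid_shape, spacing)
  x <- co$x; y <- co$y * geo$ecc
  rho <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)
  r0 <- head_radius
  amp <- r0 * c(0.035, 0.025, 0.015)
  r_out <- .wobbly_radius(phi, r0, amp, geo$harm, geo$ph_out, asymmetry)
  r_gm <- .wobbly_radius(phi, r0 * 0.90, amp * 1.3, geo$harm, geo$ph_gm,
                         asymmetry)
  r_wm <- .wobbly_radius(phi, r0 * 0.58, amp * 1.6, geo$harm, geo$ph_wm,
                         asymmetry)
  lab <- matrix(0L, grid_shape[1], grid_shape[2])
  lab[rho <= r_out] <- .tissue_label("CSF")
  lab[rho <= r_gm] <- .tissue_label("GM")
  lab[rho <= r_wm] <- .tissue_label("WM")
  ## two ventricle-like CSF inclusions deep in the white matter core,
  ## mirrored across the symmetry axis with a small seed-dependent offset
  vr <- r0 * 0.10
  for (sgn in c(-1, 1)) {
    cx <- (geo$vent_dx * asymmetry + sgn * 0.02) * r0
    cy <- sgn * geo$vent_dy * r0
    vent <- ((x - cx) / (1.6 * vr))^2 + ((y - cy) / (0.7 * vr))^2 <= 1
    lab[vent & lab == .tissue_label("WM")] <- .tissue_label("CSF")
  }
  base <- .tissue_table_128[.tissue_table_128$tissue %in% c("WM", "GM", "CSF"), ]
  props <- data.frame(label = base$label, tissue = base$tissue,
                      sigma = base$sigma * (1 + geo$pert),
                      epsr = pmax(1, base$epsr * (1 + geo$pert)))
  new_tissue_model(lab, props, spacing)
}

#' Insert a tumor-like disk inclusion into a tissue model
#'
#' Overwrites host tissue with a new label region carrying the given
#' electrical properties (defaults match a high-conductivity tumor analogue:
#' 1.5 cm radius, 1.4 S/m, eps_r 73).
#'
#' @param model a `tissue_model`
#' @param center inclusion center as (row, col) voxel indices; default places
#'   it at the grid center
#' @param radius inclusion radius in m; 0 returns the model unchanged
#' @param sigma,epsr inclusion properties
#' @return a new `tissue_model` with the tumor label added
#' @export
add_tumor <- function(model, center = NULL, radius = 0.015,
                      sigma = 1.4, epsr = 73) {
  if (radius == 0) return(model)
  if (radius < 0) stop("tumor radius must be non-negative")
  shape <- dim(model$label_grid)
  if (is.null(center)) center <- (shape + 1) / 2
  rr <- row(model$label_grid) - center[1]
  cc <- col(model$label_grid) - center[2]
  disk <- (rr^2 + cc^2) * model$spacing^2 <= radius^2
  if (any(model$label_grid[disk] == 0L))
    stop("tumor inclusion must lie fully inside tissue")
  lab <- model$label_grid
  lab[disk] <- .tissue_label("tumor")
  props <- rbind(model$properties,
                 data.frame(label = .tissue_label("tumor"), tissue = "tumor",
                            sigma = sigma, epsr = epsr))
  new_tissue_model(lab, props, model$spacing)
}

## Default pseudo spin-echo intensities per tissue (arbitrary units before
## normalization): CSF brightest, then GM, WM; air is zero.
.default_se_intensity <- c(air = 0, WM = 0.45, GM = 0.7, CSF = 1,
                           phantom = 0.8, tumor = 0.85)

#' Pseudo spin-echo tissue-contrast image
#'
#' Assigns each tissue label a configured spin-echo-like intensity and
#' normalizes the image to `[0, 1]`. Used as the third network input channel
#' of the tissue-contrast network variant.
#'
#' @param model a `tissue_model`
#' @param intensities named vector of per-tissue intensities
#' @return a matrix in `[0, 1]`, 0 in air
#' @export
make_tissue_contrast <- function(model, intensities = .default_se_intensity) {
  labs <- sort(unique(as.vector(model$label_grid)))
  img <- matrix(0, nrow(model$label_grid), ncol(model$label_grid))
  for (l in labs[labs != 0L]) {
    nm <- .tissue_table_128$tissue[match(l, .tissue_table_128$label)]
    if (is.na(nm) || !nm %in% names(intensities))
      stop("no spin-echo intensity configured for label ", l)
    img[model$label_grid == l] <- intensities[[nm]]
  }
  if (max(img) > 0) img <- img / max(img)
  img
}
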