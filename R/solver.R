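## Frequency-domain electromagnetic solver (2D, TM polarization).
##
## The longitudinal electric field Ez of a tissue model under quadrature
## birdcage-like excitation solves
##     (Laplacian + omega^2 mu0 eps~(r)) Ez = -i omega mu0 Jz,
## with complex permittivity eps~ = eps0 epsr - i sigma / omega under the
## e^{+i omega t} time convention. The line-source coil sits outside the
## computational domain, so the solve uses the scattered-field formulation:
## the incident field of the sources in vacuum is evaluated analytically
## (outgoing Hankel functions) and only the object-scattered part is solved
## for on the grid, with a thin conductive damping annulus at the domain edge
## absorbing outgoing scattered waves.

#' Quadrature coil configuration
#'
#' Point line-sources evenly spaced on a circle outside the imaging domain,
#' driven with phases `-phi_n` (co-rotating quadrature, mimicking the
#' dominant birdcage mode) or `+phi_n` for the polarity-reversed (receive)
#' drive.
#'
#' @param n_sources number of line sources (>= 8)
#' @param source_radius circle radius in m; must exceed the grid half-extent
#' @param phase_scheme `"co"` (transmit polarity) or `"counter"`
#' @param amplitude complex drive amplitude
#' @return a `coil_config`
#' @export
coil_config <- function(n_sources = 16, source_radius = 0.35,
                        phase_scheme = c("co", "counter"), amplitude = 1) {
  phase_scheme <- match.arg(phase_scheme)
  if (n_sources < 8) stop("need at least 8 sources for a clean quadrature mode")
  structure(list(n_sources = n_sources, source_radius = source_radius,
                 phase_scheme = phase_scheme, amplitude = amplitude),
            class = "coil_config")
}

new_field_solution <- function(Ez, B1p, B1m, B1m_counter, omega, spacing) {
  structure(list(Ez = Ez, B1p = B1p, B1m = B1m, B1m_counter = B1m_counter,
                 omega = omega, spacing = spacing),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat("Field solution:", nrow(x$B1p), "x", ncol(x$B1p), "voxels @",
      x$spacing * 1e3, "mm,", x$omega / (2 * pi) / 1e6, "MHz\n")
  invisible(x)
}

## Incident Ez of the line sources in vacuum, evaluated on the grid.
## polarity +1 excites the m = -1 Ez mode (transmit), -1 the reversed drive.
.incident_field <- function(coil, shape, spacing, k0, polarity = 1) {
  co <- grid_coords(shape, spacing)
  th <- 2 * pi * (seq_len(coil$n_sources) - 1) / coil$n_sources
  Ez <- matrix(0i, shape[1], shape[2])
  for (n in seq_along(th)) {
    R <- sqrt((co$x - coil$source_radius * cos(th[n]))^2 +
              (co$y - coil$source_radius * sin(th[n]))^2)
    Ez <- Ez + coil$amplitude * exp(-1i * polarity * th[n]) *
      (besselJ(k0 * R, 0) - 1i * besselY(k0 * R, 0))
  }
  Ez
}

## Conductivity profile of the absorbing annulus: quadratic ramp over the
## outermost `width` voxels.
.absorber_sigma <- function(shape, width = 6, sigma_max = 15) {
  d <- pmin(pmin(row(matrix(0, shape[1], shape[2])) - 1,
                 shape[1] - row(matrix(0, shape[1], shape[2]))),
            pmin(col(matrix(0, shape[1], shape[2])) - 1,
                 shape[2] - col(matrix(0, shape[1], shape[2]))))
  ramp <- pmax(0, (width - d) / width)
  sigma_max * ramp^2
}

## Central-difference transverse B-field components from Ez
## (Faraday's law, e^{+i omega t}): Bx = (i/omega) dEz/dy, By = -(i/omega) dEz/dx.
.b_from_ez <- function(Ez, spacing, omega) {
  nr <- nrow(Ez); nc <- ncol(Ez)
  dEdy <- matrix(0i, nr, nc)
  dEdx <- matrix(0i, nr, nc)
  dEdy[2:(nr - 1), ] <- (Ez[3:nr, ] - Ez[1:(nr - 2), ]) / (2 * spacing)
  dEdx[, 2:(nc - 1)] <- (Ez[, 3:nc] - Ez[, 1:(nc - 2)]) / (2 * spacing)
  Bx <- (1i / omega) * dEdy
  By <- -(1i / omega) * dEdx
  list(Bx = Bx, By = By)
}

#' Solve transmit and receive field maps for a tissue model
#'
#' Computes the complex longitudinal electric field and the derived
#' circularly polarized field components on the model grid at the coil's
#' operating frequency. Two drives are solved against one factorized system:
#' the transmit-polarity drive yields `B1p = (Bx + i By)/2` (and its
#' counter-rotating component `B1m_counter = Conj(Bx - i By)/2`); the
#' polarity-reversed drive yields the receive sensitivity `B1m`.
#'
#' @param model a `tissue_model`
#' @param coil a [coil_config()]
#' @param frequency operating frequency in Hz
#' @param absorber_width width in voxels of the edge damping annulus
#' @param min_margin minimum vacuum margin (voxels) required between the
#'   object mask and the domain edge
#' @return a `field_solution`
#' @export
solve_fields <- function(model, coil = coil_config(),
                         frequency = larmor_frequency(),
                         absorber_width = 6, min_margin = 10) {
  shape <- dim(model$label_grid)
  h <- model$spacing
  omega <- 2 * pi * frequency
  k0 <- omega / .c0
  if (coil$source_radius <= max(shape) * h / sqrt(2))
    stop("coil sources must lie outside the computational domain")
  idx <- which(model$mask, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    margin <- min(idx[, 1] - 1, shape[1] - idx[, 1],
                  idx[, 2] - 1, shape[2] - idx[, 2])
    if (margin < min_margin)
      stop("object mask needs a vacuum margin of at least ", min_margin,
           " voxels to the domain edge")
  }
  ## complex k^2 with object contrast and edge absorber
  contrast <- omega^2 * .mu0 *
    (.eps0 * (model$epsr_map - 1) - 1i * model$sigma_map / omega)
  sig_abs <- .absorber_sigma(shape, absorber_width)
  k2 <- k0^2 + contrast - 1i * omega * .mu0 * sig_abs
  N <- prod(shape)
  ## 5-point Laplacian with homogeneous Dirichlet edge (scattered field)
  i_all <- rep(seq_len(shape[1]), times = shape[2])
  j_all <- rep(seq_len(shape[2]), each = shape[1])
  p <- seq_len(N)
  trip_i <- p; trip_j <- p; trip_x <- rep(-4 / h^2, N)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    ok <- i_all + d[1] >= 1L & i_all + d[1] <= shape[1] &
          j_all + d[2] >= 1L & j_all + d[2] <= shape[2]
    q <- (j_all[ok] + d[2] - 1L) * shape[1] + i_all[ok] + d[1]
    trip_i <- c(trip_i, p[ok]); trip_j <- c(trip_j, q)
    trip_x <- c(trip_x, rep(1 / h^2, sum(ok)))
  }
  L <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x, dims = c(N, N))
  Ar <- L + Matrix::Diagonal(N, Re(as.vector(k2)))
  Ai <- Matrix::Diagonal(N, Im(as.vector(k2)))
  A <- rbind(cbind(Ar, -Ai), cbind(Ai, Ar))
  Einc_t <- .incident_field(coil, shape, h, k0, polarity = +1)
  Einc_r <- .incident_field(coil, shape, h, k0, polarity = -1)
  rhs <- function(Einc) {
    b <- -as.vector(contrast) * as.vector(Einc)
    c(Re(b), Im(b))
  }
  sol <- tryCatch(
    Matrix::solve(A, cbind(rhs(Einc_t), rhs(Einc_r))),
    error = function(e) stop("field solve failed (singular system?): ",
                             conditionMessage(e)))
  sol <- as.matrix(sol)
  esc <- function(colv) matrix(complex(real = colv[1:N],
                                       imaginary = colv[(N + 1):(2 * N)]),
                               shape[1], shape[2])
  Ez_t <- Einc_t + esc(sol[, 1])
  Ez_r <- Einc_r + esc(sol[, 2])
  Bt <- .b_from_ez(Ez_t, h, omega)
  Br <- .b_from_ez(Ez_r, h, omega)
  B1p <- (Bt$Bx + 1i * Bt$By) / 2
  B1m_counter <- Conj(Bt$Bx - 1i * Bt$By) / 2
  B1m <- Conj(Br$Bx - 1i * Br$By) / 2
  if (!all(is.finite(Re(B1p)) & is.finite(Im(B1p))))
    stop("field solve produced non-finite values")
  new_field_solution(Ez = Ez_t, B1p = B1p, B1m = B1m,
                     B1m_counter = B1m_counter, omega = omega, spacing = h)
}

## Flood-fill phase unwrapping over a mask, starting from the in-mask voxel
## with the largest weight (breadth-first; neighbors adjusted by 2 pi).
.unwrap_phase <- function(phase, mask, weight = NULL) {
  nr <- nrow(phase); nc <- ncol(phase)
  out <- phase
  done <- !mask
  if (!any(mask)) return(out)
  if (is.null(weight)) weight <- matrix(1, nr, nc)
  w <- weight; w[!mask] <- -Inf
  start <- which.max(w)
  queue <- integer(sum(mask)); queue[1] <- start; qh <- 1L; qt <- 1L
  done[start] <- TRUE
  offs <- c(-1L, 1L, -nr, nr)
  while (qh <= qt) {
    cur <- queue[qh]; qh <- qh + 1L
    r <- (cur - 1L) %% nr + 1L
    for (k in 1:4) {
      if ((k == 1 && r == 1L) || (k == 2 && r == nr)) next
      nb <- cur + offs[k]
      if (nb < 1L || nb > nr * nc || done[nb]) next
      done[nb] <- TRUE
      out[nb] <- out[nb] + 2 * pi * round((out[cur] - out[nb]) / (2 * pi))
      qt <- qt + 1L; queue[qt] <- nb
    }
  }
  out
}

#' Transceive phase of a field solution
#'
#' The phase measurable in a transmit/receive MR experiment: the transmit
#' phase plus the receive phase. By reciprocity the receive sensitivity
#' enters the signal conjugated, so `phi_pm = arg(B1p * Conj(B1m))`,
#' unwrapped inside the mask. The transceive phase assumption used by the
#' reconstructions halves it: `phi_plus = phi_pm / 2`.
#'
#' @param sol a `field_solution`
#' @param mask boolean object support; phase is unwrapped within it
#' @return list with `phi_pm`, `phi_plus` (radians) and `valid` (voxels with
#'   non-vanishing transmit field)
#' @export
transceive_phase <- function(sol, mask) {
  s <- sol$B1p * Conj(sol$B1m)
  valid <- Mod(sol$B1p) > 0 & Mod(sol$B1m) > 0
  phi <- Arg(s)
  phi <- .unwrap_phase(phi, mask & valid, weight = Mod(sol$B1p))
  ## reference the phase to the in-mask maximum-signal voxel
  if (any(mask & valid)) {
    w <- Mod(sol$B1p); w[!(mask & valid)] <- -Inf
    phi <- phi - phi[which.max(w)]
  }
  list(phi_pm = phi, phi_plus = phi / 2, valid = valid)
}

#' Bundle a field solution into an MR-like acquisition
#'
#' What an MR scan of the simulated object would yield: the transmit-field
#' magnitude (normalized so its in-mask mean is 1), the transceive-phase
#' based transmit phase estimate, and an auxiliary channel (binary object
#' mask or pseudo spin-echo tissue contrast). The clean complex field is
#' retained so calibrated noise can be injected later.
#'
#' @param sol a `field_solution`
#' @param model the generating `tissue_model`
#' @param aux `"mask"` or `"tissue_contrast"`
#' @return an `acquisition`
#' @export
make_acquisition <- function(sol, model, aux = c("mask", "tissue_contrast")) {
  aux <- match.arg(aux)
  if (!all(dim(sol$B1p) == dim(model$label_grid)))
    stop("field solution and tissue model grids differ")
  mask <- model$mask
  scale <- mean(Mod(sol$B1p)[mask])
  if (!is.finite(scale) || scale == 0) stop("vanishing transmit field in mask")
  b1p <- sol$B1p / scale
  tp <- transceive_phase(sol, mask)
  aux_img <- if (aux == "mask") mask * 1 else make_tissue_contrast(model)
  structure(list(
    magnitude = Mod(b1p),
    phase = tp$phi_plus,
    aux = aux_img,
    aux_type = aux,
    b1p_clean = b1p,
    mask = mask,
    spacing = sol$spacing,
    omega = sol$omega,
    snr = Inf,
    phase_sd = 0
  ), class = "acquisition")
}

#' @export
print.acquisition <- function(x, ...) {
  cat("Acquisition:", nrow(x$magnitude), "x", ncol(x$magnitude),
      "voxels, aux =", x$aux_type,
      if (is.finite(x$snr)) paste0(", SNR ", signif(x$snr, 3)) else ", noiseless",
      "\n")
  invisible(x)
}
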