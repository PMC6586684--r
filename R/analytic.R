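## Analytic field of a homogeneous dielectric cylinder under circularly
## polarized excitation: the verification oracle for the numerical solver.

#' Bessel function of the first kind for complex argument
#'
#' Power-series evaluation of J_n(z), adequate for the moderate arguments
#' (|z| up to ~30) arising at radiofrequency in tissue-sized objects.
#'
#' @param z complex vector
#' @param n non-negative integer order
#' @param nterms series length
#' @return complex vector
#' @export
besselJ_complex <- function(z, n, nterms = 40) {
  z <- as.complex(z)
  half <- z / 2
  term <- half^n / factorial(n)
  out <- term
  for (m in seq_len(nterms - 1)) {
    term <- -term * half^2 / (m * (m + n))
    out <- out + term
  }
  out
}

## d/dz J_n(z) via the recurrence J_n' = (J_{n-1} - J_{n+1})/2; J_0' = -J_1
.besselJp_complex <- function(z, n) {
  if (n == 0) return(-besselJ_complex(z, 1))
  (besselJ_complex(z, n - 1) - besselJ_complex(z, n + 1)) / 2
}

## Hankel function of the second kind (outgoing for the e^{+i omega t}
## convention) and its derivative, real argument.
.hankel2 <- function(x, n) besselJ(x, n) - 1i * besselY(x, n)
.hankel2p <- function(x, n) {
  if (n == 0) return(-.hankel2(x, 1))
  (.hankel2(x, n - 1) - .hankel2(x, n + 1)) / 2
}

#' Analytic transmit/receive field of a homogeneous cylinder
#'
#' Closed-form interior and exterior fields for a homogeneous dielectric
#' cylinder of the given radius and electrical properties, excited by a unit
#' circularly polarized incident field co-rotating with the transmit
#' polarization (azimuthal mode m = -1 of the longitudinal electric field).
#' Inside the cylinder the transmit field follows `J0(k rho)` while the
#' counter-rotating component follows `J2(k rho) e^{2 i phi}`, with
#' `k^2 = omega^2 mu0 (eps0 epsr - i sigma / omega)`.
#'
#' The returned object mirrors [solve_fields()]: `B1p` is the transmit field,
#' `B1m` the receive sensitivity of the polarity-reversed drive (for a
#' rotationally symmetric object this is `-Conj(B1p)` up to the mirror
#' symmetry), and `B1m_counter` the counter-rotating component of the forward
#' drive.
#'
#' @param radius cylinder radius in m
#' @param sigma conductivity in S/m
#' @param epsr relative permittivity
#' @param grid_shape integer vector (rows, cols)
#' @param spacing voxel size in m
#' @param frequency operating frequency in Hz
#' @return a `field_solution`
#' @export
analytic_cylinder_field <- function(radius, sigma, epsr,
                                    grid_shape = c(128, 128), spacing = 0.002,
                                    frequency = larmor_frequency()) {
  omega <- 2 * pi * frequency
  k0 <- omega / .c0
  k1 <- sqrt(omega^2 * .mu0 * (.eps0 * epsr - 1i * sigma / omega))
  co <- grid_coords(grid_shape, spacing)
  rho <- sqrt(co$x^2 + co$y^2)
  phi <- atan2(co$y, co$x)
  x0 <- k0 * radius
  x1 <- k1 * radius
  ## Ez mode matching at rho = a for Ez = J1(k0 rho) e^{-i phi} incident:
  ##   A J1(k1 a)      = J1(k0 a) + b H1(k0 a)
  ##   A k1 J1'(k1 a)  = k0 J1'(k0 a) + b k0 H1'(k0 a)
  J1a0 <- besselJ(x0, 1); J1pa0 <- (besselJ(x0, 0) - besselJ(x0, 2)) / 2
  H1a0 <- .hankel2(x0, 1); H1pa0 <- .hankel2p(x0, 1)
  J1a1 <- besselJ_complex(x1, 1); J1pa1 <- .besselJp_complex(x1, 1)
  M <- matrix(c(J1a1, k1 * J1pa1, -H1a0, -k0 * H1pa0), 2, 2)
  rhs <- c(J1a0, k0 * J1pa0)
  coefs <- base::solve(M, as.complex(rhs))
  A <- coefs[1]; b <- coefs[2]
  inside <- rho <= radius
  ## B1p = (1/(2 omega)) d+ Ez ; for g(rho) e^{-i phi}: d+ -> k J0, d- -> -k J2 e^{-2i phi}
  B1p <- matrix(0i, grid_shape[1], grid_shape[2])
  B1c <- matrix(0i, grid_shape[1], grid_shape[2])
  Ez <- matrix(0i, grid_shape[1], grid_shape[2])
  kr_in <- k1 * rho[inside]
  Ez[inside] <- A * besselJ_complex(kr_in, 1) * exp(-1i * phi[inside])
  B1p[inside] <- (A * k1 / (2 * omega)) * besselJ_complex(kr_in, 0)
  B1c[inside] <- Conj((A * k1 / (2 * omega)) * besselJ_complex(kr_in, 2) *
                        exp(-2i * phi[inside]))
  kr_out <- k0 * rho[!inside]
  Ez[!inside] <- (besselJ(kr_out, 1) + b * .hankel2(kr_out, 1)) *
    exp(-1i * phi[!inside])
  B1p[!inside] <- (k0 / (2 * omega)) *
    (besselJ(kr_out, 0) + b * .hankel2(kr_out, 0))
  B1c[!inside] <- Conj((k0 / (2 * omega)) *
                         (besselJ(kr_out, 2) + b * .hankel2(kr_out, 2)) *
                         exp(-2i * phi[!inside]))
  new_field_solution(Ez = Ez, B1p = B1p, B1m = -Conj(B1p),
                     B1m_counter = B1c, omega = omega, spacing = spacing)
}
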