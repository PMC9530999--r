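## exciton_coupling: excitonic hopping parameter J in the extended dipole
## approximation, with the point-dipole (Kasha) closed form as a far-field
## oracle.  Internal arithmetic is SI, converted once to meV.

#' Coupling configuration
#'
#' Physical constants and medium screening for coupling calculations.
#' The default refractive index is that of water at optical frequencies;
#' the medium screens the end-charge Coulomb interaction by \eqn{n^2}.
#'
#' @param refractive_index medium refractive index, >= 1 (default 1.33).
#' @return An object of class `coupling_config` carrying the refractive
#'   index, the vacuum permittivity (F/m), the Debye-to-C.m conversion and
#'   the meV output conversion.
#' @export
coupling_config <- function(refractive_index = 1.33) {
  if (!is.numeric(refractive_index) || refractive_index < 1)
    stop("configuration error: refractive_index must be >= 1")
  out <- list(refractive_index = refractive_index,
              eps0 = .const$eps0, debye_Cm = .const$debye_Cm,
              meV_J = .const$meV_J)
  class(out) <- "coupling_config"
  out
}

#' Extended-dipole prefactor J0
#'
#' \deqn{J_0 = \frac{\mu_m \mu_n}{4\pi\epsilon_0 n^2 l_m l_n}}
#' reported in meV nm, so that the extended-dipole coupling is
#' `J0 * (1/|r_m-r_n| + 1/|s_m-s_n| - 1/|r_m-s_n| - 1/|s_m-r_n|)` with the
#' four end-pair distances in nm.  Equivalently, `J0` is the screened
#' Coulomb constant of the end charges \eqn{q_i = \mu_i/l_i}.
#'
#' @param mu_m,mu_n transition dipole magnitudes, Debye.
#' @param l_m,l_n dye lengths (end-to-end), nm; must be positive.
#' @param cfg a [coupling_config()].
#' @return J0 in meV nm; positive when both magnitudes are, symmetric in
#'   (m, n).
#' @export
prefactor_J0 <- function(mu_m, mu_n, l_m, l_n, cfg = coupling_config()) {
  if (l_m <= 0 || l_n <= 0)
    stop("degenerate-geometry error: dye length must be positive")
  n2 <- cfg$refractive_index^2
  J0_SI <- (mu_m * cfg$debye_Cm) * (mu_n * cfg$debye_Cm) /
    (4 * pi * cfg$eps0 * n2 * (l_m * .const$nm_m) * (l_n * .const$nm_m))
  # J m -> meV nm
  J0_SI / cfg$meV_J / .const$nm_m
}

#' Excitonic coupling in the extended dipole approximation
#'
#' Each transition dipole is replaced by two opposite point charges
#' \eqn{\pm q_i} with \eqn{q_i = \mu_i / l_i}: `+q` at the head `r`, `-q`
#' at the tail `s`.  J is the Coulomb energy of the four charge pairs
#' screened by \eqn{n^2}:
#' \deqn{J_{m,n} = J_0\left(\frac{1}{|r_m-r_n|}+\frac{1}{|s_m-s_n|}
#'   -\frac{1}{|r_m-s_n|}-\frac{1}{|s_m-r_n|}\right).}
#' Parallel stacked dyes give J > 0; collinear head-to-tail dyes give
#' J < 0.  Symmetric in (m, n); flips sign if one dye's (r, s) labels are
#' swapped.
#'
#' @param m,n `dipole_geometry` objects (positions in nm).
#' @param mu_m,mu_n transition dipole magnitudes, Debye.
#' @param cfg a [coupling_config()].
#' @return Signed coupling, meV.
#' @export
extended_dipole_J <- function(m, n, mu_m, mu_n, cfg = coupling_config()) {
  d_rr <- vnorm(m$r - n$r); d_ss <- vnorm(m$s - n$s)
  d_rs <- vnorm(m$r - n$s); d_sr <- vnorm(m$s - n$r)
  if (min(d_rr, d_ss, d_rs, d_sr) < 1e-9)
    stop("degenerate-geometry error: coincident dye end points")
  J0 <- prefactor_J0(mu_m, mu_n, m$length, n$length, cfg)
  J0 * (1 / d_rr + 1 / d_ss - 1 / d_rs - 1 / d_sr)
}

#' Point-dipole (Kasha) coupling
#'
#' Far-field closed form
#' \deqn{J_{m,n} = \frac{\kappa_{m,n}\,\mu_m \mu_n}{4\pi\epsilon_0 n^2
#'   R_{m,n}^3},}
#' the limit of the extended-dipole expression for centre separations much
#' larger than the dye lengths.  Used as an independent validation oracle.
#'
#' @inheritParams extended_dipole_J
#' @return Signed coupling, meV.
#' @export
point_dipole_J <- function(m, n, mu_m, mu_n, cfg = coupling_config()) {
  R <- center_distance(m, n)
  if (R < 1e-9) stop("degenerate-geometry error: coincident dipole centers")
  kappa <- orientation_factor(m, n)
  n2 <- cfg$refractive_index^2
  J_SI <- kappa * (mu_m * cfg$debye_Cm) * (mu_n * cfg$debye_Cm) /
    (4 * pi * cfg$eps0 * n2 * (R * .const$nm_m)^3)
  J_SI / cfg$meV_J
}
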