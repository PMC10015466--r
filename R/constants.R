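#' Physical constants used throughout the package
#'
#' Single source of truth for the fundamental constants entering the
#' relaxation models. All values are CODATA SI values; the electron/proton
#' Larmor frequency ratio (658.21) folds the electron g-factor once so that
#' \eqn{\omega_S = 658.21\,\omega_I} everywhere.
#'
#' @return A named list with elements
#'   \describe{
#'     \item{g}{electron g-factor (2.0023, dimensionless)}
#'     \item{S}{total electron spin of high-spin Fe(III) (5/2)}
#'     \item{muB}{Bohr magneton, J/T}
#'     \item{gammaH}{proton gyromagnetic ratio, rad s^-1 T^-1}
#'     \item{hbar}{reduced Planck constant, J s}
#'     \item{kB}{Boltzmann constant, J/K}
#'     \item{NA}{Avogadro constant, mol^-1}
#'     \item{mu0_4pi}{magnetic constant over 4 pi, T m / A}
#'     \item{water_molarity}{molar concentration of pure water, mol/L}
#'     \item{omega_ratio}{electron-to-proton Larmor frequency ratio}
#'     \item{R_kJ}{gas constant, kJ mol^-1 K^-1}
#'     \item{T_ref}{reference temperature for all "298 K" parameters, K}
#'   }
#' @export
#' @examples
#' physical_constants()$S
physical_constants <- function() {
  list(
    g = 2.0023,
    S = 2.5,
    muB = 9.2740100783e-24,
    gammaH = 2.67522128e8,
    hbar = 1.054571817e-34,
    kB = 1.380649e-23,
    N_A = 6.02214076e23,
    mu0_4pi = 1e-7,
    water_molarity = 55.6,
    omega_ratio = 658.21,
    R_kJ = 8.31446261815324e-3,
    T_ref = 298.15
  )
}

# internal copy, avoids rebuilding the list in hot loops
.pc <- physical_constants()

#' Magnetic field point expressed as proton Larmor frequency
#'
#' @param nu_MHz proton Larmor frequency in MHz (vectorized, must be > 0)
#' @return list with `nu_MHz`, `omegaI` (proton angular frequency, rad/s) and
#'   `omegaS` (electron angular frequency, rad/s; `658.21 * omegaI`).
#' @export
#' @examples
#' field_point(60)$omegaS / field_point(60)$omegaI
field_point <- function(nu_MHz) {
  if (any(!is.finite(nu_MHz)) || any(nu_MHz <= 0))
    stop("proton Larmor frequency must be finite and positive (MHz)")
  omegaI <- 2 * pi * nu_MHz * 1e6
  list(nu_MHz = nu_MHz, omegaI = omegaI, omegaS = .pc$omega_ratio * omegaI)
}

#' Temperature scaling laws for model parameters
#'
#' Scales a 298.15 K reference value to temperature `T` using one of the
#' conventional laws of variable-temperature relaxometric analysis:
#' \describe{
#'   \item{`arrhenius-time`}{correlation times (and the mean-square transient
#'     ZFS energy), \eqn{x(T) = x_{298}\exp[E/R\,(1/T - 1/298.15)]}; with
#'     `E > 0` the quantity grows on cooling.}
#'   \item{`arrhenius-rate`}{rate-like quantities such as diffusion
#'     coefficients, \eqn{x(T) = x_{298}\exp[-E/R\,(1/T - 1/298.15)]}.}
#'   \item{`eyring-exchange`}{water residence time \eqn{\tau_M = 1/k_{ex}}
#'     with \eqn{k_{ex}(T) = k_{ex}^{298}\,(T/298.15)\exp[\Delta H_M/R\,
#'     (1/298.15 - 1/T)]}; `E` is the exchange activation enthalpy.}
#' }
#' At `T = 298.15` every law returns `x298` exactly.
#'
#' @param x298 value at 298.15 K
#' @param E activation energy (or enthalpy), kJ/mol
#' @param T absolute temperature, K (vectorized)
#' @param law one of `"arrhenius-time"`, `"arrhenius-rate"`, `"eyring-exchange"`
#' @return the value at `T`, same units as `x298`
#' @export
#' @examples
#' temperature_scale(272, 56.2, 310, "eyring-exchange") # residence time in ns
temperature_scale <- function(x298, E, T,
                              law = c("arrhenius-time", "arrhenius-rate",
                                      "eyring-exchange")) {
  law <- match.arg(law)
  if (any(!is.finite(T)) || any(T <= 0)) stop("temperature must be positive (K)")
  T0 <- .pc$T_ref
  u <- (E / .pc$R_kJ) * (1 / T - 1 / T0)
  switch(law,
    "arrhenius-time" = x298 * exp(u),
    "arrhenius-rate" = x298 * exp(-u),
    "eyring-exchange" = {
      kex298 <- 1 / x298
      kex <- kex298 * (T / T0) * exp((E / .pc$R_kJ) * (1 / T0 - 1 / T))
      1 / kex
    }
  )
}
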