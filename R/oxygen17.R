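#' Parameters governing the 17O observables of a complex
#'
#' Water-exchange and hyperfine parameters entering the Swift-Connick
#' analysis of reduced 17O transverse relaxation rates and chemical shifts
#' of bulk water.
#'
#' @param A_O scalar hyperfine (Fermi-contact) coupling constant between
#'   the electron spin and the bound-water 17O nucleus, in units of
#'   10^6 rad s^-1 (e.g. `-50.1`)
#' @param tauM water residence time at 298.15 K, ns
#' @param dH_M activation enthalpy of the exchange, kJ/mol
#' @param C_os empirical outer-sphere shift coefficient (dimensionless);
#'   adds `C_os * Delta_omega_m` to the reduced shift
#' @param q number of bound water molecules (>= 1 for any complex with
#'   17O data)
#' @param B0 magnetic field, T
#' @param Delta2,E_Delta,tauv,E_v electron-relaxation parameters shared
#'   with the relaxometry model (s^-2, kJ/mol, ps, kJ/mol)
#' @return object of class `o17_params`
#' @export
#' @examples
#' swift_connick(tiron_o17_params("FeL2"), 298.15)
o17_params <- function(A_O, tauM, dH_M, C_os = 0, q,
                       B0 = 11.74, Delta2, E_Delta = 0, tauv, E_v = 1.0) {
  if (q < 1) stop("q must be >= 1 for a complex with 17O data")
  if (B0 <= 0) stop("B0 must be > 0")
  if (tauM <= 0) stop("tauM must be > 0")
  structure(list(A_O = A_O, tauM = tauM, dH_M = dH_M, C_os = C_os, q = q,
                 B0 = B0, Delta2 = Delta2, E_Delta = E_Delta,
                 tauv = tauv, E_v = E_v),
            class = "o17_params")
}

# electron Larmor angular frequency at field B0 (rad/s)
.omegaS_at_B0 <- function(B0) .pc$g * .pc$muB * B0 / .pc$hbar

#' Chemical shift of bound-water 17O
#'
#' Scalar-coupling (Fermi-contact) shift of the 17O nucleus of a bound
#' water molecule:
#' \deqn{\Delta\omega_m = \frac{g\,\mu_B\,S(S+1)\,B_0}{3 k_B T}\,
#'   \frac{A_O}{\hbar}}
#' The sign follows the sign of \eqn{A_O/\hbar} and the shift is linear
#' in the applied field.
#'
#' @param params an [o17_params()]
#' @param T temperature, K (vectorized)
#' @return shift in rad/s
#' @export
bound_shift <- function(params, T = 298.15) {
  (.pc$g * .pc$muB * .pc$S * (.pc$S + 1) * params$B0 / (3 * .pc$kB * T)) *
    params$A_O * 1e6
}

# scalar-mechanism transverse relaxation rate of the bound 17O (s^-1)
.scalar_rate <- function(params, T, tauM_s) {
  omS <- .omegaS_at_B0(params$B0)
  Te <- electron_relaxation(list(omegaS = omS), T,
                            params$Delta2, params$tauv,
                            params$E_Delta, params$E_v)
  taus <- 1 / (1 / tauM_s + 1 / Te$T1e)
  (.pc$S * (.pc$S + 1) / 3) * (params$A_O * 1e6)^2 * taus
}

#' Swift-Connick reduced 17O relaxation rate and shift
#'
#' Reduced (per mole fraction of bound water) transverse relaxation rate
#' and chemical shift of bulk water in exchange with the bound site:
#' \deqn{R_{2r} = \frac{1}{\tau_M}\,
#'   \frac{T_{2m}^{-2} + T_{2m}^{-1}\tau_M^{-1} + \Delta\omega_m^2}
#'        {(T_{2m}^{-1}+\tau_M^{-1})^2 + \Delta\omega_m^2}}
#' \deqn{\Delta\omega_r = \frac{\Delta\omega_m}
#'   {(1+\tau_M/T_{2m})^2 + \tau_M^2\Delta\omega_m^2} + C_{os}\Delta\omega_m}
#' with \eqn{1/T_{2m}} from the scalar mechanism
#' (\eqn{(S(S+1)/3)(A_O/\hbar)^2 \tau_{s1}},
#' \eqn{1/\tau_{s1} = 1/\tau_M + 1/T_{1e}}) and \eqn{\tau_M(T)} from the
#' Eyring law. In the slow-exchange limit \eqn{R_{2r}\to 1/\tau_M}; in the
#' fast-exchange limit \eqn{R_{2r}\to 1/T_{2m}} (plus the small shift term).
#'
#' @param params an [o17_params()]
#' @param T temperature, K (vectorized)
#' @return data.frame with columns `temperature_K`, `R2r` (s^-1),
#'   `dOmega_r` (rad/s), `tauM_s`, `T2m_s`
#' @export
swift_connick <- function(params, T = 298.15) {
  out <- t(vapply(T, function(Ti) {
    tauM_s <- temperature_scale(params$tauM, params$dH_M, Ti,
                                "eyring-exchange") * 1e-9
    invT2m <- .scalar_rate(params, Ti, tauM_s)
    dwm <- bound_shift(params, Ti)
    invtau <- 1 / tauM_s
    R2r <- invtau * (invT2m^2 + invT2m * invtau + dwm^2) /
      ((invT2m + invtau)^2 + dwm^2)
    dwr <- dwm / ((1 + tauM_s * invT2m)^2 + tauM_s^2 * dwm^2) +
      params$C_os * dwm
    c(Ti, R2r, dwr, tauM_s, 1 / invT2m)
  }, numeric(5)))
  out <- as.data.frame(out)
  names(out) <- c("temperature_K", "R2r", "dOmega_r", "tauM_s", "T2m_s")
  out
}

#' Classify the water-exchange regime at each temperature
#'
#' Compares the residence time with the bound-site transverse relaxation
#' time: `tauM/T2m > 10` is slow exchange, `< 0.1` fast exchange, anything
#' between is intermediate.
#'
#' @param params an [o17_params()]
#' @param T temperatures, K
#' @return data.frame with `temperature_K`, `ratio` (tauM/T2m), `regime`
#' @export
#' @examples
#' classify_regime(tiron_o17_params("FeL1"), c(278, 298, 350))
classify_regime <- function(params, T) {
  sc <- swift_connick(params, T)
  ratio <- sc$tauM_s / sc$T2m_s
  regime <- ifelse(ratio > 10, "slow", ifelse(ratio < 0.1, "fast",
                                              "intermediate"))
  data.frame(temperature_K = T, ratio = ratio, regime = regime)
}
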