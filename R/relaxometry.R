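#' Relaxation parameters of a paramagnetic Fe(III) complex
#'
#' Container for the per-complex physical parameters of the three-term
#' relaxivity model (inner sphere + second sphere + outer sphere), in the
#' units conventionally tabulated in variable-temperature NMRD analyses:
#'
#' @param q number of inner-sphere water molecules (integer >= 0)
#' @param r Fe-H(water) distance, Angstrom (`NA` allowed when `q = 0`)
#' @param tauR rotational correlation time at 298.15 K, ps
#' @param E_R activation energy of tauR, kJ/mol
#' @param tauM inner-sphere water residence time at 298.15 K, ns
#'   (`NA` allowed when `q = 0`)
#' @param dH_M activation enthalpy of the water exchange, kJ/mol
#' @param Delta2 mean-square transient zero-field-splitting energy at
#'   298.15 K, s^-2 (e.g. `12.2e20`)
#' @param E_Delta Arrhenius activation energy of Delta^2, kJ/mol
#' @param tauv correlation time of the transient ZFS at 298.15 K, ps
#' @param E_v activation energy of tauv, kJ/mol
#' @param q_ss number of second-sphere water molecules (integer >= 0)
#' @param r_ss Fe-H distance of second-sphere waters, Angstrom
#' @param tauR_ss second-sphere rotational correlation time at 298.15 K, ps
#' @param E_R_ss activation energy of tauR_ss, kJ/mol
#' @param tauM_ss second-sphere water residence time, ns (default 1 ns)
#' @param D relative diffusion coefficient of water and complex at
#'   298.15 K, cm^2 s^-1
#' @param E_D activation energy of D, kJ/mol
#' @param a distance of closest approach of outer-sphere water protons,
#'   Angstrom
#' @return object of class `relax_params`
#' @export
#' @examples
#' p <- tiron_relax_params("FeL2")
#' total_r1(p, 60)
relax_params <- function(q, r = NA, tauR = NA, E_R = 0,
                         tauM = NA, dH_M = 0,
                         Delta2, E_Delta = 0, tauv, E_v = 1.0,
                         q_ss = 0, r_ss = NA, tauR_ss = NA, E_R_ss = 0,
                         tauM_ss = 1.0,
                         D = 2.24e-5, E_D = 20.0, a = 3.5) {
  if (q < 0 || q != round(q)) stop("q must be a non-negative integer")
  if (q_ss < 0 || q_ss != round(q_ss)) stop("q_ss must be a non-negative integer")
  if (q > 0) {
    if (!is.finite(r) || r <= 0) stop("r (Angstrom) must be > 0 when q > 0")
    if (!is.finite(tauM) || tauM <= 0) stop("tauM (ns) must be > 0 when q > 0")
    if (!is.finite(tauR) || tauR <= 0) stop("tauR (ps) must be > 0 when q > 0")
  }
  if (q_ss > 0) {
    if (!is.finite(r_ss) || r_ss <= 0) stop("r_ss must be > 0 when q_ss > 0")
    if (!is.finite(tauR_ss) || tauR_ss <= 0) stop("tauR_ss must be > 0 when q_ss > 0")
    if (!is.finite(tauM_ss) || tauM_ss <= 0) stop("tauM_ss must be > 0")
  }
  if (Delta2 < 0) stop("Delta2 must be >= 0")
  if (!is.finite(tauv) || tauv <= 0) stop("tauv must be > 0")
  if (!is.finite(D) || D <= 0 || !is.finite(a) || a <= 0)
    stop("D and a must be > 0")
  structure(list(q = q, r = r, tauR = tauR, E_R = E_R,
                 tauM = tauM, dH_M = dH_M,
                 Delta2 = Delta2, E_Delta = E_Delta, tauv = tauv, E_v = E_v,
                 q_ss = q_ss, r_ss = r_ss, tauR_ss = tauR_ss,
                 E_R_ss = E_R_ss, tauM_ss = tauM_ss,
                 D = D, E_D = E_D, a = a),
            class = "relax_params")
}

#' @export
print.relax_params <- function(x, ...) {
  cat("Relaxivity model parameters (298.15 K reference values)\n")
  cat(sprintf("  inner sphere : q = %d, r = %s A, tauR = %s ps, tauM = %s ns\n",
              x$q, format(x$r), format(x$tauR), format(x$tauM)))
  cat(sprintf("  electron     : Delta2 = %.3g s^-2, tauv = %.3g ps\n",
              x$Delta2, x$tauv))
  cat(sprintf("  second sphere: q_ss = %d, r_ss = %s A, tauR_ss = %s ps, tauM_ss = %s ns\n",
              x$q_ss, format(x$r_ss), format(x$tauR_ss), format(x$tauM_ss)))
  cat(sprintf("  outer sphere : D = %.3g cm2/s, a = %.2f A\n", x$D, x$a))
  invisible(x)
}

# scale the temperature-dependent parameters to T (internal, SI units out)
.relax_at_T <- function(p, T) {
  list(
    tauR = temperature_scale(p$tauR, p$E_R, T, "arrhenius-time") * 1e-12,
    tauM = if (is.finite(p$tauM))
      temperature_scale(p$tauM, p$dH_M, T, "eyring-exchange") * 1e-9 else Inf,
    Delta2 = temperature_scale(p$Delta2, p$E_Delta, T, "arrhenius-time"),
    tauv = temperature_scale(p$tauv, p$E_v, T, "arrhenius-time") * 1e-12,
    tauR_ss = if (is.finite(p$tauR_ss))
      temperature_scale(p$tauR_ss, p$E_R_ss, T, "arrhenius-time") * 1e-12 else Inf,
    tauM_ss = p$tauM_ss * 1e-9,
    D = temperature_scale(p$D, p$E_D, T, "arrhenius-rate") * 1e-4,
    a = p$a * 1e-10
  )
}

#' Electron-spin relaxation times from the transient ZFS mechanism
#'
#' Longitudinal and transverse relaxation times of the S = 5/2 electron
#' spin from the Bloembergen-Morgan/McLachlan expressions for modulation of
#' a transient zero-field splitting:
#' \deqn{1/T_{1e} = \frac{\Delta^2\tau_v}{25}\,[4S(S+1)-3]\left[
#'   \frac{1}{1+\omega_S^2\tau_v^2} + \frac{4}{1+4\omega_S^2\tau_v^2}\right]}
#' \deqn{1/T_{2e} = \frac{\Delta^2\tau_v}{50}\,[4S(S+1)-3]\left[3 +
#'   \frac{5}{1+\omega_S^2\tau_v^2} + \frac{2}{1+4\omega_S^2\tau_v^2}\right]}
#' At zero field the two rates coincide. `Delta2 = 0` disables electron
#' relaxation (`T1e = T2e = Inf`).
#'
#' @param field a [field_point()] (uses `omegaS`; vectorized)
#' @param T temperature, K
#' @param Delta2 mean-square transient ZFS at 298.15 K, s^-2
#' @param tauv ZFS correlation time at 298.15 K, ps
#' @param E_Delta,E_v Arrhenius activation energies, kJ/mol
#' @return list with `T1e` and `T2e` in seconds
#' @export
#' @examples
#' electron_relaxation(field_point(60), 298.15, 12.2e20, 5.6)
electron_relaxation <- function(field, T = 298.15, Delta2, tauv,
                                E_Delta = 0, E_v = 0) {
  if (Delta2 < 0 || tauv <= 0) stop("Delta2 must be >= 0 and tauv > 0")
  D2 <- temperature_scale(Delta2, E_Delta, T, "arrhenius-time")
  tv <- temperature_scale(tauv, E_v, T, "arrhenius-time") * 1e-12
  if (D2 == 0) {
    n <- length(field$omegaS)
    return(list(T1e = rep(Inf, n), T2e = rep(Inf, n)))
  }
  S <- .pc$S
  x2 <- (field$omegaS * tv)^2
  pre <- D2 * tv * (4 * S * (S + 1) - 3)
  r1e <- (pre / 25) * (1 / (1 + x2) + 4 / (1 + 4 * x2))
  r2e <- (pre / 50) * (3 + 5 / (1 + x2) + 2 / (1 + 4 * x2))
  list(T1e = 1 / r1e, T2e = 1 / r2e)
}

# Solomon-Bloembergen dipolar 1/T1M for a proton at distance r_m (m) with
# effective correlation times td1, td2 (s); all SI.
.dipolar_rate <- function(omegaI, omegaS, r_m, td1, td2) {
  K <- (2 / 15) * .pc$mu0_4pi^2 * .pc$gammaH^2 * .pc$g^2 * .pc$muB^2 *
    .pc$S * (.pc$S + 1) / r_m^6
  K * (3 * td1 / (1 + omegaI^2 * td1^2) + 7 * td2 / (1 + omegaS^2 * td2^2))
}

# generic sphere contribution (inner or second): per-mM relaxivity of q_w
# protons-bearing waters at distance r_A with rotational time tauR_s and
# residence time tauM_s
.sphere_r1 <- function(field, q_w, r_A, tauR_s, tauM_s, Te) {
  if (q_w == 0) return(rep(0, length(field$omegaI)))
  td1 <- 1 / (1 / tauR_s + 1 / tauM_s + 1 / Te$T1e)
  td2 <- 1 / (1 / tauR_s + 1 / tauM_s + 1 / Te$T2e)
  invT1M <- .dipolar_rate(field$omegaI, field$omegaS, r_A * 1e-10, td1, td2)
  Pm <- q_w * 1e-3 / .pc$water_molarity
  Pm / (1 / invT1M + tauM_s)
}

#' Inner-sphere relaxivity
#'
#' Per-mM inner-sphere contribution \eqn{r_1^{IS} = P_m/(T_{1M}+\tau_M)}
#' with \eqn{P_m = q\,[\mathrm{1 mM}]/55.6\,\mathrm{M}}, the dipolar
#' \eqn{1/T_{1M}} evaluated with effective correlation times
#' \eqn{1/\tau_{di} = 1/\tau_R + 1/\tau_M + 1/T_{ie}}.
#'
#' @param p a [relax_params()]
#' @param field a [field_point()] or frequency in MHz (vectorized)
#' @param T temperature, K
#' @return relaxivity, mM^-1 s^-1
#' @export
inner_sphere_r1 <- function(p, field, T = 298.15) {
  field <- .as_field(field)
  if (p$q == 0) return(rep(0, length(field$omegaI)))
  s <- .relax_at_T(p, T)
  Te <- electron_relaxation(field, T, p$Delta2, p$tauv, p$E_Delta, p$E_v)
  .sphere_r1(field, p$q, p$r, s$tauR, s$tauM, Te)
}

#' Second-sphere relaxivity
#'
#' Same functional form as [inner_sphere_r1()] with the second-sphere
#' parameter set (`q_ss`, `r_ss`, `tauR_ss`, `tauM_ss`); the residence time
#' of the hydrogen-bonded second-sphere waters defaults to 1 ns.
#'
#' @inheritParams inner_sphere_r1
#' @return relaxivity, mM^-1 s^-1
#' @export
second_sphere_r1 <- function(p, field, T = 298.15) {
  field <- .as_field(field)
  if (p$q_ss == 0) return(rep(0, length(field$omegaI)))
  s <- .relax_at_T(p, T)
  Te <- electron_relaxation(field, T, p$Delta2, p$tauv, p$E_Delta, p$E_v)
  .sphere_r1(field, p$q_ss, p$r_ss, s$tauR_ss, s$tauM_ss, Te)
}

#' Outer-sphere relaxivity (Freed model)
#'
#' Hard-sphere translational-diffusion contribution of bulk water, with the
#' Freed spectral density including finite electron relaxation:
#' \deqn{J(\omega, T_{je}) = \mathrm{Re}\,\frac{1 + z/4}
#'   {1 + z + 4z^2/9 + z^3/9},\qquad
#'   z = \sqrt{i\omega\tau_D + \tau_D/T_{je}},\quad \tau_D = a^2/D}
#' \deqn{r_1^{OS} = \frac{32\pi}{405}\left(\frac{\mu_0}{4\pi}\right)^2
#'   \gamma_I^2\gamma_S^2\hbar^2 S(S+1)\,\frac{N_A [C]}{aD}
#'   \,[3J(\omega_I,T_{1e}) + 7J(\omega_S,T_{2e})]}
#' evaluated per 1 mM of complex.
#'
#' @inheritParams inner_sphere_r1
#' @return relaxivity, mM^-1 s^-1
#' @export
outer_sphere_r1 <- function(p, field, T = 298.15) {
  field <- .as_field(field)
  s <- .relax_at_T(p, T)
  Te <- electron_relaxation(field, T, p$Delta2, p$tauv, p$E_Delta, p$E_v)
  tauD <- s$a^2 / s$D
  gammaS <- .pc$g * .pc$muB / .pc$hbar
  conc <- .pc$N_A * 1 # number density of a 1 mM = 1 mol m^-3 solution
  pre <- (32 * pi / 405) * .pc$mu0_4pi^2 * .pc$gammaH^2 * gammaS^2 *
    .pc$hbar^2 * .pc$S * (.pc$S + 1) * conc / (s$a * s$D)
  pre * (3 * .freed_J(field$omegaI, tauD, Te$T1e) +
           7 * .freed_J(field$omegaS, tauD, Te$T2e))
}

.freed_J <- function(omega, tauD, Tje) {
  z <- sqrt(1i * omega * tauD + tauD / Tje)
  Re((1 + z / 4) / (1 + z + 4 * z^2 / 9 + z^3 / 9))
}

.as_field <- function(field) {
  if (is.numeric(field)) field_point(field) else field
}

#' Total water-proton relaxivity and its component breakdown
#'
#' Sum of the inner-, second- and outer-sphere contributions at the given
#' field(s) and temperature.
#'
#' @inheritParams inner_sphere_r1
#' @return data.frame with columns `nu_MHz`, `temperature_K`, `IS`, `SS`,
#'   `OS`, `r1` (all relaxivities in mM^-1 s^-1) and the percentage shares
#'   `IS_pct`, `SS_pct`, `OS_pct` (summing to 100)
#' @export
#' @examples
#' total_r1(tiron_relax_params("FeL2"), c(60, 120))
total_r1 <- function(p, field, T = 298.15) {
  field <- .as_field(field)
  is_ <- inner_sphere_r1(p, field, T)
  ss <- second_sphere_r1(p, field, T)
  os <- outer_sphere_r1(p, field, T)
  tot <- is_ + ss + os
  share <- function(x) ifelse(tot > 0, 100 * x / tot, 0)
  data.frame(nu_MHz = field$nu_MHz, temperature_K = T,
             IS = is_, SS = ss, OS = os, r1 = tot,
             IS_pct = share(is_), SS_pct = share(ss), OS_pct = share(os))
}

#' Speciation-weighted relaxivity versus pH
#'
#' Forward prediction of the observed relaxivity of an Fe(III)-Tiron
#' solution as the mole-fraction-weighted sum of the per-species
#' relaxivities, combining the speciation solver with the per-complex
#' relaxivity models. The hydroxo species FeL2H-1 is modeled with the
#' FeL2 parameter set and one inner-sphere water (one bound water replaced
#' by hydroxide).
#'
#' @param model a [species_model()]
#' @param params named list of [relax_params()] with entries `Fe`, `FeL`,
#'   `FeL2`, `FeL3` (defaults: the tabulated parameter sets,
#'   [tiron_relax_params()])
#' @param total_Fe,total_L totals, mol/L
#' @param pH numeric vector
#' @param nu_MHz proton Larmor frequency, MHz (scalar)
#' @param T temperature, K
#' @return data.frame with `pH`, per-species weighted contributions, and
#'   the total `r1` (mM^-1 s^-1)
#' @export
#' @examples
#' r1_ph_profile(species_model(), total_Fe = 1.88e-3, total_L = 94e-3,
#'               pH = c(4.0, 7.4), nu_MHz = 32)
r1_ph_profile <- function(model, params = NULL, total_Fe, total_L, pH,
                          nu_MHz = 32, T = 298.15) {
  if (is.null(params)) {
    params <- list(Fe = tiron_relax_params("FeAqua"),
                   FeL = tiron_relax_params("FeL1"),
                   FeL2 = tiron_relax_params("FeL2"),
                   FeL3 = tiron_relax_params("FeL3"))
  }
  stopifnot(all(c("Fe", "FeL", "FeL2", "FeL3") %in% names(params)))
  pHm1 <- params$FeL2
  pHm1$q <- max(pHm1$q - 1, 0)
  species_r1 <- vapply(c(params, list(FeL2Hm1 = pHm1)),
                       function(p) total_r1(p, nu_MHz, T)$r1, numeric(1))
  rows <- lapply(pH, function(ph) {
    st <- solve_speciation(model, solution_conditions(total_Fe, total_L, ph))
    w <- st$fe_fractions[c("Fe", "FeL", "FeL2", "FeL3", "FeL2Hm1")]
    contrib <- w * species_r1[c("Fe", "FeL", "FeL2", "FeL3", "FeL2Hm1")]
    c(pH = ph, contrib, r1 = sum(contrib))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("pH", "Fe", "FeL", "FeL2", "FeL3", "FeL2Hm1", "r1")
  out
}
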