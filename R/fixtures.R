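#' Tabulated equilibrium constants of the Fe(III)-Tiron system
#'
#' The protonation and stability constants determined at 0.15 M NaNO3 and
#' 25 C (concentration constants): logK1H = 12.40, logK2H = 7.46,
#' logK_FeL = 20.32, logK_FeL2 = 14.49, logK_FeL3 = 9.83,
#' logK_FeL2Hm1 = 7.86, with pKw = 13.77 and electrode offset pA = 0.02.
#'
#' @return a [species_model()]
#' @export
#' @examples
#' tiron_constants()
tiron_constants <- function() species_model()

#' Tabulated relaxivity parameter sets of the Fe(III)-Tiron complexes
#'
#' Best-fit and fixed parameters of the three-term relaxivity model for the
#' three Tiron complexes, plus the hexaaqua ion as a reference set:
#' `"FeL3"` = \[Fe(Tiron)3\]9- (q = 0, five second-sphere waters),
#' `"FeL2"` = \[Fe(Tiron)2(H2O)2\]5-, `"FeL1"` = \[Fe(Tiron)(H2O)4\]-,
#' `"FeAqua"` = \[Fe(H2O)6\]3+. Fixed values common to all sets:
#' D = 2.24e-5 cm2/s, E_D = 20 kJ/mol, a = 3.5 A, E_v = 1 kJ/mol,
#' tauM_ss = 1 ns.
#'
#' @param complex one of `"FeL3"`, `"FeL2"`, `"FeL1"`, `"FeAqua"`
#' @return a [relax_params()]
#' @export
#' @examples
#' tiron_relax_params("FeL3")
tiron_relax_params <- function(complex = c("FeL3", "FeL2", "FeL1", "FeAqua")) {
  complex <- match.arg(complex)
  switch(complex,
    FeL3 = relax_params(q = 0, Delta2 = 9.7e20, E_Delta = 4.6,
                        tauv = 6.9, E_v = 1.0,
                        q_ss = 5, r_ss = 3.50, tauR_ss = 52.7, E_R_ss = 15.3,
                        tauM_ss = 1.0, D = 2.24e-5, E_D = 20.0, a = 3.5),
    FeL2 = relax_params(q = 2, r = 2.70, tauR = 70.0, E_R = 16.0,
                        tauM = 272, dH_M = 56.2,
                        Delta2 = 12.2e20, E_Delta = 2.7, tauv = 5.6, E_v = 1.0,
                        q_ss = 2, r_ss = 3.25, tauR_ss = 31.2, E_R_ss = 11.0,
                        tauM_ss = 1.0, D = 2.24e-5, E_D = 20.0, a = 3.5),
    FeL1 = relax_params(q = 4, r = 2.70, tauR = 34.7, E_R = 15.0,
                        tauM = 18000, dH_M = 57.5,
                        Delta2 = 5.5e20, E_Delta = 3.3, tauv = 9.2, E_v = 1.0,
                        q_ss = 0, D = 2.24e-5, E_D = 20.0, a = 3.5),
    FeAqua = relax_params(q = 6, r = 2.69, tauR = 60.7, E_R = 17.9,
                          tauM = 25000, dH_M = 31.4,
                          Delta2 = 4.2e20, E_Delta = 0, tauv = 5.3, E_v = 1.0,
                          q_ss = 0, D = 2.24e-5, E_D = 20.0, a = 3.5)
  )
}

#' Tabulated 17O parameter sets
#'
#' Hyperfine and exchange parameters of the complexes with bound water and
#' 17O data (`"FeL2"`, `"FeL1"`) and of the hexaaqua reference
#' (`"FeAqua"`), at 11.74 T, with the electron-relaxation parameters
#' shared with [tiron_relax_params()].
#'
#' @param complex one of `"FeL2"`, `"FeL1"`, `"FeAqua"`
#' @return an [o17_params()]
#' @export
tiron_o17_params <- function(complex = c("FeL2", "FeL1", "FeAqua")) {
  complex <- match.arg(complex)
  switch(complex,
    FeL2 = o17_params(A_O = -50.1, tauM = 272, dH_M = 56.2, C_os = 0.04,
                      q = 2, B0 = 11.74, Delta2 = 12.2e20, E_Delta = 2.7,
                      tauv = 5.6, E_v = 1.0),
    FeL1 = o17_params(A_O = -71.6, tauM = 18000, dH_M = 57.5, C_os = 0.05,
                      q = 4, B0 = 11.74, Delta2 = 5.5e20, E_Delta = 3.3,
                      tauv = 9.2, E_v = 1.0),
    FeAqua = o17_params(A_O = -99.3, tauM = 25000, dH_M = 31.4, C_os = 0.038,
                        q = 6, B0 = 11.74, Delta2 = 4.2e20, E_Delta = 0,
                        tauv = 5.3, E_v = 1.0)
  )
}

#' Tabulated transchelation rate constants
#'
#' Rate and equilibrium constants of the CDTA-mediated dissociation of the
#' Fe(III)-Tiron complexes (0.15 M NaNO3, 25 C): spontaneous dissociation
#' of FeL3 (`k0`), proton-assisted (`k1`) and proton+CDTA-assisted (`k4`)
#' dissociation of FeL2, and the kinetically determined stability constant
#' of FeL3.
#'
#' @return a [kinetic_rate_model()]
#' @export
#' @examples
#' tiron_rate_constants()
tiron_rate_constants <- function() {
  kinetic_rate_model(k0 = 8e-5, k1 = 3.9e3, k4 = 7e5, logK_FeL3_kin = 9.20)
}

#' Reference dissociation parameters of Fe(EDTA)- and Fe(CDTA)-
#'
#' Hydroxide-assisted dissociation constants used only for the comparative
#' half-life table: `k0` (s^-1), `kOH` (M^-1 s^-1), `kOH2` (M^-2 s^-1),
#' the protonation constant `logK_FeLHm1` of the hydroxo complex, and the
#' dissociation rate constant near physiological pH, `kd_pH74` (s^-1).
#'
#' @param complex `"FeEDTA"` or `"FeCDTA"`
#' @return named list
#' @export
reference_rate_constants <- function(complex = c("FeEDTA", "FeCDTA")) {
  complex <- match.arg(complex)
  switch(complex,
    FeEDTA = list(k0 = 5e-6, kOH = 1.0, kOH2 = 1.4e3,
                  logK_FeLHm1 = 7.41, kd_pH74 = 2.9e-6),
    FeCDTA = list(k0 = 3.2e-7, kOH = 3.6e-3, kOH2 = 1.2,
                  logK_FeLHm1 = 9.58, kd_pH74 = 2.1e-9)
  )
}
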