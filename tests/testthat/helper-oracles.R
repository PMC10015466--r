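# Independent reference implementations ("oracles") used to cross-check the
# package: a brute-force grid+bisection equilibrium solver and flat, single-
# function transcriptions of the relaxation models. Deliberately written as
# monolithic closed-form evaluations, sharing no code with the package.

# --- speciation: 1-D logarithmic grid search + bisection -------------------
oracle_speciation <- function(logK1H, logK2H, logK_FeL, logK_FeL2, logK_FeL3,
                              logK_FeL2Hm1 = NA, FeT, LT, pH,
                              n_grid = 2e5, lo = -25, hi = 0) {
  h <- 10^(-pH)
  K1 <- 10^logK1H; K2 <- 10^logK2H
  b1 <- 10^logK_FeL
  b2 <- 10^(logK_FeL + logK_FeL2)
  b3 <- 10^(logK_FeL + logK_FeL2 + logK_FeL3)
  bOH <- if (is.finite(logK_FeL2Hm1)) b2 / (10^logK_FeL2Hm1 * h) else 0
  alpha <- 1 + K1 * h + K1 * K2 * h^2
  res <- function(lx) {
    x <- 10^lx
    y <- FeT / (1 + b1 * x + (b2 + bOH) * x^2 + b3 * x^3)
    x * alpha + y * (b1 * x + 2 * (b2 + bOH) * x^2 + 3 * b3 * x^3) - LT
  }
  lx <- seq(lo, hi, length.out = n_grid)
  r <- vapply(lx, res, numeric(1))
  i <- which(r[-1] > 0 & r[-n_grid] <= 0)[1]
  stopifnot(is.finite(i))
  a <- lx[i]; b <- lx[i + 1]
  for (k in 1:200) {
    m <- (a + b) / 2
    if (res(m) <= 0) a <- m else b <- m
    if (b - a < 1e-14) break
  }
  x <- 10^((a + b) / 2)
  y <- FeT / (1 + b1 * x + (b2 + bOH) * x^2 + b3 * x^3)
  list(L = x, Fe = y,
       conc = c(L = x, HL = K1 * h * x, H2L = K1 * K2 * h^2 * x,
                Fe = y, FeL = b1 * x * y, FeL2 = b2 * x^2 * y,
                FeL3 = b3 * x^3 * y, FeL2Hm1 = bOH * x^2 * y))
}

# --- relaxometry: flat transcription of the three-term r1 model ------------
oracle_r1 <- function(nu_MHz, T = 298.15,
                      q, r_A, tauR_ps, E_R, tauM_ns, dH_M,
                      Delta2, E_Delta, tauv_ps, E_v,
                      q_ss = 0, r_ss_A = NA, tauR_ss_ps = NA, E_R_ss = 0,
                      tauM_ss_ns = 1, D_cm2s = 2.24e-5, E_D = 20, a_A = 3.5) {
  g <- 2.0023; S <- 2.5
  muB <- 9.2740100783e-24; gamH <- 2.67522128e8
  hbar <- 1.054571817e-34; NAv <- 6.02214076e23
  Rk <- 8.31446261815324e-3; T0 <- 298.15
  arr <- function(x, E) x * exp((E / Rk) * (1 / T - 1 / T0))
  omI <- 2 * pi * nu_MHz * 1e6
  omS <- 658.21 * omI
  D2 <- arr(Delta2, E_Delta)
  tv <- arr(tauv_ps, E_v) * 1e-12
  x2 <- (omS * tv)^2
  pre <- D2 * tv * (4 * S * (S + 1) - 3)
  T1e <- 1 / ((pre / 25) * (1 / (1 + x2) + 4 / (1 + 4 * x2)))
  T2e <- 1 / ((pre / 50) * (3 + 5 / (1 + x2) + 2 / (1 + 4 * x2)))
  Kdd <- function(r_m) (2 / 15) * 1e-14 * gamH^2 * g^2 * muB^2 * S * (S + 1) / r_m^6
  sphere <- function(qw, r_m, tR, tM) {
    if (qw == 0) return(0)
    td1 <- 1 / (1 / tR + 1 / tM + 1 / T1e)
    td2 <- 1 / (1 / tR + 1 / tM + 1 / T2e)
    iT1M <- Kdd(r_m) * (3 * td1 / (1 + omI^2 * td1^2) +
                          7 * td2 / (1 + omS^2 * td2^2))
    (qw * 1e-3 / 55.6) / (1 / iT1M + tM)
  }
  is_ <- if (q > 0) {
    kex <- (1 / (tauM_ns * 1e-9)) * (T / T0) * exp((dH_M / Rk) * (1 / T0 - 1 / T))
    sphere(q, r_A * 1e-10, arr(tauR_ps, E_R) * 1e-12, 1 / kex)
  } else 0
  ss <- if (q_ss > 0)
    sphere(q_ss, r_ss_A * 1e-10, arr(tauR_ss_ps, E_R_ss) * 1e-12,
           tauM_ss_ns * 1e-9) else 0
  D <- arr(D_cm2s, -E_D) * 1e-4
  a <- a_A * 1e-10
  tauD <- a^2 / D
  J <- function(om, Tje) {
    z <- sqrt(1i * om * tauD + tauD / Tje)
    Re((1 + z / 4) / (1 + z + 4 * z^2 / 9 + z^3 / 9))
  }
  os <- (32 * pi / 405) * 1e-14 * gamH^2 * (g * muB / hbar)^2 * hbar^2 *
    S * (S + 1) * NAv / (a * D) * (3 * J(omI, T1e) + 7 * J(omS, T2e))
  c(IS = is_, SS = ss, OS = os, r1 = is_ + ss + os)
}

# --- 17O: flat transcription of the Swift-Connick observables --------------
oracle_o17 <- function(T = 298.15, A_O_1e6, tauM_ns, dH_M, C_os, q,
                       B0 = 11.74, Delta2, E_Delta, tauv_ps, E_v) {
  g <- 2.0023; S <- 2.5
  muB <- 9.2740100783e-24; hbar <- 1.054571817e-34; kB <- 1.380649e-23
  Rk <- 8.31446261815324e-3; T0 <- 298.15
  arr <- function(x, E) x * exp((E / Rk) * (1 / T - 1 / T0))
  kex <- (1 / (tauM_ns * 1e-9)) * (T / T0) * exp((dH_M / Rk) * (1 / T0 - 1 / T))
  tauM <- 1 / kex
  omS <- g * muB * B0 / hbar
  D2 <- arr(Delta2, E_Delta)
  tv <- arr(tauv_ps, E_v) * 1e-12
  x2 <- (omS * tv)^2
  T1e <- 1 / ((D2 * tv * (4 * S * (S + 1) - 3) / 25) *
                (1 / (1 + x2) + 4 / (1 + 4 * x2)))
  A <- A_O_1e6 * 1e6
  dwm <- (g * muB * S * (S + 1) * B0 / (3 * kB * T)) * A
  taus <- 1 / (1 / tauM + 1 / T1e)
  iT2m <- (S * (S + 1) / 3) * A^2 * taus
  R2r <- (1 / tauM) * (iT2m^2 + iT2m / tauM + dwm^2) /
    ((iT2m + 1 / tauM)^2 + dwm^2)
  dwr <- dwm / ((1 + tauM * iT2m)^2 + (tauM * dwm)^2) + C_os * dwm
  c(R2r = R2r, dOmega_r = dwr, tauM = tauM, T2m = 1 / iT2m)
}

# --- kinetics: flat transcription of the pathway-weighted rate law ---------
oracle_kd <- function(k0, k1, k4, logK3kin, logK1H, logK2H,
                      logK_FeL, logK_FeL2, pH, FeT, LT, CDTA) {
  sp <- oracle_speciation(logK1H, logK2H, logK_FeL, logK_FeL2, logK3kin,
                          NA, FeT, LT, pH)
  c2 <- sp$conc[["FeL2"]]; c3 <- sp$conc[["FeL3"]]
  x3 <- c3 / (c2 + c3)
  h <- 10^(-pH)
  x3 * k0 + (1 - x3) * (k1 * h + k4 * h * CDTA)
}

# random parameter draws for the equivalence sweeps
rand_relax_draw <- function() {
  list(q = sample(0:6, 1), r_A = runif(1, 2.4, 3.2),
       tauR_ps = 10^runif(1, 1, 2.5), E_R = runif(1, 5, 30),
       tauM_ns = 10^runif(1, 0.5, 4.5), dH_M = runif(1, 20, 70),
       Delta2 = 10^runif(1, 19.5, 21.5), E_Delta = runif(1, 0.5, 8),
       tauv_ps = runif(1, 2, 20), E_v = 1,
       q_ss = sample(0:5, 1), r_ss_A = runif(1, 3, 4),
       tauR_ss_ps = 10^runif(1, 1, 2), E_R_ss = runif(1, 5, 20),
       tauM_ss_ns = 1, D_cm2s = 10^runif(1, -5, -4.3), E_D = 20,
       a_A = runif(1, 3.2, 4))
}

relax_params_from_draw <- function(d) {
  relax_params(q = d$q, r = if (d$q > 0) d$r_A else NA,
               tauR = if (d$q > 0) d$tauR_ps else NA, E_R = d$E_R,
               tauM = if (d$q > 0) d$tauM_ns else NA, dH_M = d$dH_M,
               Delta2 = d$Delta2, E_Delta = d$E_Delta,
               tauv = d$tauv_ps, E_v = d$E_v,
               q_ss = d$q_ss, r_ss = if (d$q_ss > 0) d$r_ss_A else NA,
               tauR_ss = if (d$q_ss > 0) d$tauR_ss_ps else NA,
               E_R_ss = d$E_R_ss, tauM_ss = d$tauM_ss_ns,
               D = d$D_cm2s, E_D = d$E_D, a = d$a_A)
}
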