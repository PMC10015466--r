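#' Single-wavelength kinetic trace of a transchelation reaction
#'
#' @param times seconds, strictly increasing
#' @param absorbance absorbance at each time
#' @param pH,CDTA_t,Fe_t,Tiron_t reaction conditions (mol/L for totals)
#' @return object of class `kinetic_trace`; a flag `pseudo_first_order`
#'   records whether the CDTA excess reaches the conventional 20-fold
#'   threshold for pseudo-first-order validity
#' @export
kinetic_trace <- function(times, absorbance, pH = NA,
                          CDTA_t = NA, Fe_t = NA, Tiron_t = NA) {
  if (length(times) != length(absorbance))
    stop("times and absorbance must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  pfo <- if (is.finite(CDTA_t) && is.finite(Fe_t) && Fe_t > 0)
    CDTA_t >= 20 * Fe_t else NA
  structure(list(times = times, absorbance = absorbance,
                 conditions = list(pH = pH, CDTA_t = CDTA_t,
                                   Fe_t = Fe_t, Tiron_t = Tiron_t),
                 pseudo_first_order = pfo),
            class = "kinetic_trace")
}

#' Fit a pseudo-first-order absorbance decay
#'
#' Least-squares fit of the mono-exponential model
#' \eqn{A_t = A_p + (A_0 - A_p)\exp(-k_d t)} to a kinetic trace, with the
#' endpoints \eqn{A_0} and \eqn{A_p} free by default (`fix_endpoints`
#' freezes them at the first/last observed values). A trace with no signal
#' change is a degenerate-trace error. Traces with fewer than 5 points or
#' spanning less than two half-lives are flagged, not rejected.
#'
#' @param trace a [kinetic_trace()]
#' @param fix_endpoints logical; fix `A0`/`Ap` instead of fitting them
#' @return list with `kd` (s^-1), `sigma_kd`, `A0`, `Ap`, `converged`,
#'   `flags` (character), `residuals`
#' @export
#' @examples
#' tr <- make_traces(kd = 1e-4, times = seq(0, 3e4, length.out = 30))[[1]]
#' fit_trace(tr)$kd
fit_trace <- function(trace, fix_endpoints = FALSE) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$times; A <- trace$absorbance
  dA <- diff(range(A))
  if (dA <= 1e-12 * max(abs(A), 1))
    stop("degenerate trace: no absorbance change (A0 = Ap)")
  A0g <- A[1]; Apg <- A[length(A)]
  # initial rate from the log-linearized early decay
  u <- (A - Apg) / (A0g - Apg)
  ok <- u > 0.05
  kdg <- if (sum(ok) >= 2) {
    max(-stats::coef(stats::lm(log(u[ok]) ~ t[ok]))[2], 1e-12)
  } else 1 / max(t)

  if (fix_endpoints) {
    fn <- function(par) Apg + (A0g - Apg) * exp(-exp(par[1]) * t) - A
    fit <- minpack.lm::nls.lm(par = c(lkd = log(kdg)), fn = fn)
    kd <- exp(stats::coef(fit)[["lkd"]])
    J <- .num_jacobian(fn, stats::coef(fit))
    sig <- .sigma_from_jacobian(J, fit$fvec) * kd # delta method on log scale
    A0 <- A0g; Ap <- Apg
  } else {
    fn <- function(par) par[["Ap"]] + (par[["A0"]] - par[["Ap"]]) *
      exp(-exp(par[["lkd"]]) * t) - A
    fit <- minpack.lm::nls.lm(par = c(A0 = A0g, Ap = Apg, lkd = log(kdg)),
                              fn = fn)
    cf <- stats::coef(fit)
    kd <- exp(cf[["lkd"]])
    J <- .num_jacobian(fn, cf)
    sig_all <- .sigma_from_jacobian(J, fit$fvec)
    sig <- sig_all[which(names(cf) == "lkd")] * kd
    A0 <- cf[["A0"]]; Ap <- cf[["Ap"]]
  }
  flags <- character(0)
  if (length(t) < 5) flags <- c(flags, "fewer than 5 points")
  if (max(t) < 2 * log(2) / kd) flags <- c(flags, "span < 2 half-lives")
  if (isFALSE(trace$pseudo_first_order))
    flags <- c(flags, "CDTA excess below 20-fold")
  list(kd = kd, sigma_kd = unname(sig), A0 = A0, Ap = Ap,
       converged = fit$info %in% 1:4, flags = flags, residuals = fit$fvec)
}

#' Multi-pathway rate model of the transchelation reaction
#'
#' Rate constants of the proposed dissociation mechanism: spontaneous
#' dissociation of FeL3 (`k0`, s^-1), proton-assisted (`k1`, M^-1 s^-1)
#' and proton+CDTA-assisted (`k4`, M^-2 s^-1) dissociation of FeL2, plus
#' the kinetically determined stability constant `logK_FeL3_kin` that sets
#' the FeL3/FeL2 partition.
#'
#' @param k0,k1,k4 rate constants (>= 0)
#' @param logK_FeL3_kin stability constant of FeL3 (log10) as determined
#'   kinetically
#' @return object of class `kinetic_rate_model`
#' @export
kinetic_rate_model <- function(k0, k1, k4 = 0, logK_FeL3_kin) {
  if (any(c(k0, k1, k4) < 0)) stop("rate constants must be >= 0")
  structure(list(k0 = k0, k1 = k1, k4 = k4,
                 logK_FeL3_kin = logK_FeL3_kin),
            class = "kinetic_rate_model")
}

#' Observed pseudo-first-order dissociation rate constant
#'
#' Pathway-weighted rate law of the transchelation mechanism:
#' \deqn{k_d = x_{FeL_3} k_0 + x_{FeL_2}\,(k_1 [H^+] + k_4 [H^+] [CDTA])}
#' where \eqn{x_{FeL_3}} and \eqn{x_{FeL_2}} are the mole fractions of the
#' two dominant complexes, computed from the kinetic stability constant
#' and the free ligand concentration delivered by the speciation solver
#' (the minor hydroxo species FeL2H-1 is neglected in the kinetic model).
#'
#' @param model a [kinetic_rate_model()]
#' @param species a [species_model()] supplying the ligand protonation and
#'   FeL/FeL2 stability constants
#' @param pH -log[H+]
#' @param total_Fe,total_L totals, mol/L
#' @param CDTA total CDTA concentration, mol/L
#' @return kd in s^-1
#' @export
#' @examples
#' observed_kd(tiron_rate_constants(), tiron_constants(),
#'             pH = 7.4, total_Fe = 1e-4, total_L = 5e-4, CDTA = 0)
observed_kd <- function(model, species, pH, total_Fe, total_L, CDTA = 0) {
  stopifnot(inherits(model, "kinetic_rate_model"),
            inherits(species, "species_model"))
  kin_species <- species_model(
    logK1H = species$logK1H, logK2H = species$logK2H,
    logK_FeL = species$logK_FeL, logK_FeL2 = species$logK_FeL2,
    logK_FeL3 = model$logK_FeL3_kin, logK_FeL2Hm1 = NA,
    pKw = species$pKw, pA = species$pA)
  st <- solve_speciation(kin_species,
                         solution_conditions(total_Fe, total_L, pH))
  c2 <- st$concentrations[["FeL2"]]
  c3 <- st$concentrations[["FeL3"]]
  if (c2 + c3 <= 0)
    stop("neither FeL2 nor FeL3 is present under these conditions")
  x3 <- c3 / (c2 + c3); x2 <- 1 - x3
  h <- 10^(-pH)
  unname(x3 * model$k0 + x2 * (model$k1 * h + model$k4 * h * CDTA))
}

#' Hydroxide-assisted dissociation rate law
#'
#' Dissociation rate constant of the polyaminocarboxylate reference
#' complexes, \eqn{k_d = k_0 + k_{OH}[OH^-] + k_{OH2}[OH^-]^2}, with
#' `[OH-]` from the stoichiometric water ionic product. Used only for the
#' comparative inertness table.
#'
#' @param k0,kOH,kOH2 rate constants (s^-1, M^-1 s^-1, M^-2 s^-1)
#' @param pH -log[H+]
#' @param pKw stoichiometric water ionic product
#' @return kd in s^-1
#' @export
hydroxide_kd <- function(k0, kOH, kOH2, pH, pKw = 13.77) {
  oh <- 10^(pH - pKw)
  k0 + kOH * oh + kOH2 * oh^2
}

#' Dissociation half-life
#'
#' \eqn{t_{1/2} = \ln 2 / k_d}, converted to hours.
#'
#' @param kd pseudo-first-order rate constant, s^-1 (> 0)
#' @return half-life in hours
#' @export
#' @examples
#' half_life(1.1e-4) # about 1.8 h
half_life <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("kd must be > 0")
  log(2) / kd / 3600
}

#' Refine transchelation rate constants from a kd surface
#'
#' Weighted least-squares fit of the multi-pathway rate law to a table of
#' observed rate constants across pH and CDTA levels. Residuals are
#' relative (model/observed - 1) so that conditions spanning decades of kd
#' contribute comparably. Rate constants are refined on a log scale
#' (positivity); the kinetic stability constant directly.
#'
#' @param kd_table data.frame with columns `pH`, `CDTA` (mol/L), `kd`
#'   (s^-1) and optionally `total_Fe`, `total_L` (defaults 1e-4 / 5e-4 M)
#' @param model0 starting [kinetic_rate_model()]
#' @param species a [species_model()] for the ligand/complex constants
#' @param free character subset of `c("k0","k1","k4","logK_FeL3_kin")`
#' @return a `fit_result` (see [refine_constants()]) whose `model` element
#'   is the refined [kinetic_rate_model()]
#' @export
refine_rate_constants <- function(kd_table, model0, species,
                                  free = c("k0", "k1", "k4",
                                           "logK_FeL3_kin")) {
  stopifnot(is.data.frame(kd_table),
            all(c("pH", "CDTA", "kd") %in% names(kd_table)))
  if (!all(free %in% c("k0", "k1", "k4", "logK_FeL3_kin")))
    stop("free must be a subset of k0, k1, k4, logK_FeL3_kin")
  if (nrow(kd_table) < length(free))
    stop("fewer conditions than free constants")
  Fe_t <- kd_table$total_Fe %||% rep(1e-4, nrow(kd_table))
  L_t <- kd_table$total_L %||% rep(5e-4, nrow(kd_table))

  to_theta <- function(m) {
    th <- c(k0 = log(m$k0), k1 = log(m$k1),
            k4 = if (m$k4 > 0) log(m$k4) else log(1e-12),
            logK_FeL3_kin = m$logK_FeL3_kin)
    th[free]
  }
  to_model <- function(theta) {
    m <- model0
    for (nm in free) {
      m[[nm]] <- if (nm == "logK_FeL3_kin") theta[[nm]] else exp(theta[[nm]])
    }
    class(m) <- "kinetic_rate_model"
    m
  }
  resid_fun <- function(theta) {
    m <- to_model(theta)
    pred <- vapply(seq_len(nrow(kd_table)), function(i)
      observed_kd(m, species, kd_table$pH[i], Fe_t[i], L_t[i],
                  kd_table$CDTA[i]), numeric(1))
    pred / kd_table$kd - 1
  }

  theta0 <- to_theta(model0)
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  theta <- stats::coef(fit)
  r <- resid_fun(theta)
  J <- .num_jacobian(resid_fun, theta)
  rank_def <- qr(J)$rank < length(theta)
  if (rank_def)
    warning("kinetic refinement is rank-deficient (e.g. no CDTA variation for k4)")
  sig_theta <- .sigma_from_jacobian(J, r)
  m <- to_model(theta)
  est <- vapply(free, function(nm) m[[nm]], numeric(1))
  # delta method back to the natural scale for the log-parameterized rates
  sig <- ifelse(free == "logK_FeL3_kin", sig_theta, sig_theta * est)

  structure(list(model = m,
                 coefficients = data.frame(estimate = est, sigma = sig,
                                           row.names = free),
                 fixed = unlist(model0[setdiff(c("k0", "k1", "k4",
                                                 "logK_FeL3_kin"), free)]),
                 objective = sum(r^2),
                 converged = fit$info %in% 1:4,
                 rank_deficient = rank_def,
                 residuals = r),
            class = "fit_result")
}
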