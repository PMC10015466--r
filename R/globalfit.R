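# Shared parameter vector for simultaneous 1H NMRD + 17O fitting.
# Names follow the relax_params()/o17_params() fields, with A_O in
# 1e6 rad s^-1 and B0 in tesla.
.theta_names <- c("q", "r", "tauR", "E_R", "tauM", "dH_M",
                  "Delta2", "E_Delta", "tauv", "E_v",
                  "q_ss", "r_ss", "tauR_ss", "E_R_ss", "tauM_ss",
                  "D", "E_D", "a", "A_O", "C_os", "B0")

#' Flatten parameter objects into the shared global-fit vector
#'
#' @param relax a [relax_params()]
#' @param o17 an [o17_params()] sharing `tauM`, `dH_M`, `Delta2`, `tauv`
#'   with the relaxometry set, or `NULL` for a complex without 17O data
#' @return named numeric vector over the full shared parameter set
#' @export
#' @examples
#' th <- global_theta(tiron_relax_params("FeL2"), tiron_o17_params("FeL2"))
global_theta <- function(relax, o17 = NULL) {
  th <- unlist(relax[c("q", "r", "tauR", "E_R", "tauM", "dH_M",
                       "Delta2", "E_Delta", "tauv", "E_v",
                       "q_ss", "r_ss", "tauR_ss", "E_R_ss", "tauM_ss",
                       "D", "E_D", "a")])
  th <- c(th, A_O = if (is.null(o17)) 0 else o17$A_O,
          C_os = if (is.null(o17)) 0 else o17$C_os,
          B0 = if (is.null(o17)) 11.74 else o17$B0)
  th[.theta_names]
}

.relax_from_theta <- function(th) {
  structure(as.list(th[c("q", "r", "tauR", "E_R", "tauM", "dH_M",
                         "Delta2", "E_Delta", "tauv", "E_v",
                         "q_ss", "r_ss", "tauR_ss", "E_R_ss", "tauM_ss",
                         "D", "E_D", "a")]),
            class = "relax_params")
}

.o17_from_theta <- function(th) {
  structure(list(A_O = th[["A_O"]], tauM = th[["tauM"]],
                 dH_M = th[["dH_M"]], C_os = th[["C_os"]],
                 q = th[["q"]], B0 = th[["B0"]],
                 Delta2 = th[["Delta2"]], E_Delta = th[["E_Delta"]],
                 tauv = th[["tauv"]], E_v = th[["E_v"]]),
            class = "o17_params")
}

#' Define a simultaneous NMRD + 17O fitting problem
#'
#' @param datasets list of datasets: `nmrd_dataset` objects (columns
#'   `freq_MHz`, `temperature_K`, `r1_mM_s`) and/or `o17_dataset` objects
#'   (columns `temperature_K`, `R2r_s`, `dOmega_r_rad_s`)
#' @param params full shared parameter vector (see [global_theta()]);
#'   starting values for free parameters, fixed values for the rest
#' @param free names of the free parameters
#' @param lower,upper named bounds for the free parameters (defaults:
#'   a broad physically sensible box, see Details)
#' @param weights optional per-dataset weights; by default each residual
#'   series is normalized by its mean observed magnitude so that NMRD and
#'   17O data contribute comparably
#'
#' @details Default bounds (units as in [relax_params()]): `tauR`, `tauR_ss`
#'   10-500 ps, `tauM` 1-1e5 ns, `tauv` 1-50 ps, `Delta2` 1e19-1e22 s^-2,
#'   `A_O` -150 to -10, `C_os` 0-0.2, activation energies 0.1-80 kJ/mol,
#'   `r`/`r_ss` 2-5 A, `D` 1e-6-1e-4 cm2/s, `a` 3-4.5 A.
#' @return object of class `fit_problem`
#' @export
fit_problem <- function(datasets, params, free,
                        lower = NULL, upper = NULL, weights = NULL) {
  if (!length(datasets)) stop("at least one dataset is required")
  kinds <- vapply(datasets, function(d)
    if (inherits(d, "nmrd_dataset")) "nmrd"
    else if (inherits(d, "o17_dataset")) "o17"
    else stop("datasets must be nmrd_dataset or o17_dataset objects"),
    character(1))
  if (!all(.theta_names %in% names(params)))
    stop("params must cover the full shared parameter set (see global_theta)")
  if (!all(free %in% .theta_names)) stop("unknown free parameter name")
  def <- .default_bounds()
  lo <- def$lower[free]; hi <- def$upper[free]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(params[free] < lo | params[free] > hi))
    stop("initial values must lie within the bounds")
  if (is.null(weights)) {
    weights <- lapply(datasets, function(d) {
      if (inherits(d, "nmrd_dataset")) 1 / mean(abs(d$r1_mM_s))
      else c(R2r = 1 / mean(abs(d$R2r_s)),
             shift = 1 / mean(abs(d$dOmega_r_rad_s)))
    })
  }
  # identifiability guard: exchange/hyperfine parameters are blind without
  # bound water or 17O data
  rank_warn <- FALSE
  if (params[["q"]] == 0 && !any(kinds == "o17") &&
      any(c("tauM", "dH_M", "A_O", "C_os") %in% free)) {
    rank_warn <- TRUE
    warning("tauM/A_O-type parameters are unidentifiable for a q = 0 ",
            "problem without 17O data; fix them")
  }
  structure(list(datasets = datasets, kinds = kinds, params = params,
                 free = free, lower = lo, upper = hi, weights = weights,
                 rank_warning = rank_warn),
            class = "fit_problem")
}

.default_bounds <- function() {
  lower <- c(q = 0, r = 2, tauR = 10, E_R = 0.1, tauM = 1, dH_M = 0.1,
             Delta2 = 1e19, E_Delta = 0.1, tauv = 1, E_v = 0.1,
             q_ss = 0, r_ss = 2, tauR_ss = 10, E_R_ss = 0.1, tauM_ss = 0.1,
             D = 1e-6, E_D = 0.1, a = 3, A_O = -150, C_os = 0, B0 = 0.1)
  upper <- c(q = 8, r = 5, tauR = 500, E_R = 80, tauM = 1e5, dH_M = 80,
             Delta2 = 1e22, E_Delta = 80, tauv = 50, E_v = 80,
             q_ss = 8, r_ss = 5, tauR_ss = 500, E_R_ss = 80, tauM_ss = 100,
             D = 1e-4, E_D = 80, a = 4.5, A_O = -10, C_os = 0.2, B0 = 30)
  list(lower = lower, upper = upper)
}

# weighted residual vector of the full problem at parameter vector th
.global_residuals <- function(problem, th) {
  unlist(lapply(seq_along(problem$datasets), function(i) {
    d <- problem$datasets[[i]]
    w <- problem$weights[[i]]
    if (problem$kinds[i] == "nmrd") {
      p <- .relax_from_theta(th)
      pred <- numeric(nrow(d))
      for (Tu in unique(d$temperature_K)) {
        idx <- d$temperature_K == Tu
        pred[idx] <- total_r1(p, d$freq_MHz[idx], Tu)$r1
      }
      w * (pred - d$r1_mM_s)
    } else {
      o <- .o17_from_theta(th)
      sc <- swift_connick(o, d$temperature_K)
      c(w[["R2r"]] * (sc$R2r - d$R2r_s),
        w[["shift"]] * (sc$dOmega_r - d$dOmega_r_rad_s))
    }
  }))
}

#' Global-fit objective function
#'
#' Sum over all datasets of the weighted squared residuals of the shared
#' model at parameter vector `theta` (free entries override the problem's
#' stored values).
#'
#' @param problem a [fit_problem()]
#' @param theta named numeric vector; values for (a subset of) the shared
#'   parameters
#' @return scalar objective value
#' @export
objective <- function(problem, theta = NULL) {
  th <- problem$params
  if (!is.null(theta)) th[names(theta)] <- theta
  sum(.global_residuals(problem, th)^2)
}

#' Simultaneous fit of 1H NMRD profiles and 17O data
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with a
#' deterministic multi-start scheme: the stored initial values plus
#' `n_starts - 1` log-uniform draws within the bounds (uniform for
#' parameters whose box crosses or sits below zero), seeded by `seed`.
#' The best local optimum is returned with Jacobian-based 1-sigma
#' uncertainties for the free parameters. Non-convergence is flagged in
#' the result, never raised as an error.
#'
#' @param problem a [fit_problem()]
#' @param n_starts number of starts (default 8)
#' @param seed integer seed making the start sequence reproducible
#' @return a `fit_result` with elements `theta` (full parameter vector at
#'   the optimum), `coefficients` (free parameters with 1-sigma
#'   uncertainties), `fixed`, `objective`, `converged`, `rank_deficient`,
#'   `residuals`, `starts` (objective value reached from each start)
#' @export
fit_global <- function(problem, n_starts = 8, seed = 1) {
  stopifnot(inherits(problem, "fit_problem"))
  free <- problem$free
  lo <- problem$lower; hi <- problem$upper

  if (!length(free)) {
    r <- .global_residuals(problem, problem$params)
    return(structure(list(theta = problem$params,
                          coefficients = data.frame(estimate = numeric(0),
                                                    sigma = numeric(0)),
                          fixed = problem$params,
                          objective = sum(r^2), converged = TRUE,
                          rank_deficient = isTRUE(problem$rank_warning),
                          residuals = r, starts = numeric(0)),
                     class = "fit_result"))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  starts <- list(problem$params[free])
  for (k in seq_len(max(n_starts - 1, 0))) {
    starts[[k + 1]] <- vapply(free, function(nm) {
      if (lo[[nm]] > 0) {
        10^stats::runif(1, log10(lo[[nm]]), log10(hi[[nm]]))
      } else if (hi[[nm]] < 0) {
        -10^stats::runif(1, log10(-hi[[nm]]), log10(-lo[[nm]]))
      } else stats::runif(1, lo[[nm]], hi[[nm]])
    }, numeric(1))
  }

  resid_free <- function(par) {
    th <- problem$params
    th[free] <- par
    .global_residuals(problem, th)
  }

  best <- NULL
  start_obj <- numeric(length(starts))
  for (k in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[k]], fn = resid_free,
                         lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    start_obj[k] <- if (is.null(fit)) Inf else fit$deviance
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("all starts failed to evaluate")

  par <- stats::coef(best)
  th <- problem$params; th[free] <- par
  r <- resid_free(par)
  J <- .num_jacobian(resid_free, par)
  rank_def <- qr(J)$rank < length(par) || isTRUE(problem$rank_warning)
  sig <- .sigma_from_jacobian(J, r)

  structure(list(theta = th,
                 coefficients = data.frame(estimate = par, sigma = sig,
                                           row.names = free),
                 fixed = problem$params[setdiff(.theta_names, free)],
                 objective = best$deviance,
                 converged = best$info %in% 1:4,
                 rank_deficient = rank_def,
                 residuals = r,
                 starts = start_obj),
            class = "fit_result")
}
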