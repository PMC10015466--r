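#' Simulate spectrophotometric or potentiometric titration observables
#'
#' Forward model for the two observable kinds used to determine the
#' equilibrium constants:
#' \describe{
#'   \item{absorbance}{Beer-Lambert: \eqn{A(\lambda) = \ell \sum_s
#'     \varepsilon_s(\lambda)\,[s]} over the declared absorbing species at
#'     each pH of the grid.}
#'   \item{base-volume}{volume of strong base needed to bring the titrated
#'     solution to each pH, from the full proton balance (including `pKw`
#'     and the base-consuming formation of the hydroxo complex FeL2H-1),
#'     with dilution by the titrant accounted for.}
#' }
#' When `emulate_measured = TRUE` the returned pH column is the electrode
#' reading `pH_read = pH_true + pA`.
#'
#' @param model a [species_model()]
#' @param kind `"absorbance"` or `"base-volume"`
#' @param total_Fe,total_L analytical totals, mol/L (initial values for
#'   base-volume titrations, which are diluted by the titrant)
#' @param pH true -log[H+] grid (strictly increasing)
#' @param eps matrix of molar absorptivities (L mol^-1 cm^-1); rows are
#'   species names, columns wavelengths in nm. Required for absorbance.
#' @param absorbing species expected to absorb; a species in `absorbing`
#'   missing from `rownames(eps)` is a validation error
#' @param path_length optical path, cm
#' @param acid0 initial strong-acid concentration, mol/L (base-volume)
#' @param V0_mL initial sample volume, mL (base-volume)
#' @param base_conc titrant concentration, mol/L (base-volume)
#' @param emulate_measured apply the electrode offset `pA` to the reported pH
#' @return object of class `titration_dataset`: list with `points`
#'   (data.frame; `pH` plus either one `A<wavelength>` column per wavelength
#'   or `V_base_mL`), `kind`, and the generating metadata
#' @export
#' @examples
#' eps <- matrix(c(1800, 2600, 2100), 3, 1,
#'               dimnames = list(c("FeL", "FeL2", "FeL3"), "562"))
#' td <- simulate_observable(species_model(), "absorbance",
#'                           total_Fe = 1.9e-4, total_L = 9.1e-3,
#'                           pH = seq(2, 10, 0.5), eps = eps)
#' head(td$points)
simulate_observable <- function(model, kind = c("absorbance", "base-volume"),
                                total_Fe, total_L, pH,
                                eps = NULL,
                                absorbing = c("FeL", "FeL2", "FeL3"),
                                path_length = 1,
                                acid0 = 0, V0_mL = 6, base_conc = 0.1,
                                emulate_measured = FALSE) {
  kind <- match.arg(kind)
  if (any(diff(pH) <= 0)) stop("pH grid must be strictly increasing")
  pts <- if (kind == "absorbance") {
    if (is.null(eps)) stop("absorbance simulation requires an eps matrix")
    if (any(eps < 0)) stop("molar absorptivities must be >= 0")
    missing_sp <- setdiff(absorbing, rownames(eps))
    if (length(missing_sp))
      stop("missing molar absorptivity for present species: ",
           paste(missing_sp, collapse = ", "))
    A <- matrix(t(vapply(pH, function(p) {
      st <- solve_speciation(model, solution_conditions(total_Fe, total_L, p))
      conc <- st$concentrations[rownames(eps)]
      as.numeric(path_length * (conc %*% eps))
    }, numeric(ncol(eps)))), nrow = length(pH), ncol = ncol(eps))
    out <- data.frame(pH = pH)
    out[paste0("A", colnames(eps))] <- as.data.frame(A)
    out
  } else {
    Vb <- vapply(pH, function(p) {
      .base_volume_at_pH(model, p, total_Fe, total_L, acid0, V0_mL, base_conc)
    }, numeric(1))
    data.frame(pH = pH, V_base_mL = Vb)
  }
  if (emulate_measured) pts$pH <- pts$pH + model$pA
  structure(list(points = pts, kind = kind,
                 wavelengths = if (kind == "absorbance")
                   as.numeric(colnames(eps)) else NULL,
                 eps = eps, path_length = path_length,
                 total_Fe = total_Fe, total_L = total_L,
                 acid0 = acid0, V0_mL = V0_mL, base_conc = base_conc,
                 measured_pH = emulate_measured),
            class = "titration_dataset")
}

# Titratable-proton content of the solution at a given true pH (mol/L),
# relative to the reference state (fully deprotonated ligand, aquo iron):
#   TH = [H+] - [OH-] + [HL] + 2[H2L] - [FeL2H-1]
.proton_content <- function(model, pH, total_Fe, total_L) {
  st <- solve_speciation(model, solution_conditions(total_Fe, total_L, pH))
  cc <- st$concentrations
  h <- 10^(-pH)
  h - 10^(-model$pKw) / h + cc[["HL"]] + 2 * cc[["H2L"]] - cc[["FeL2Hm1"]]
}

# Base volume (mL) bringing the diluted solution to the target true pH.
# Conservation: TH(pH; diluted totals) * (V0+Vb) = TH0 * V0 - Cb * Vb,
# where TH0 is the initial proton content (strong acid + 2 protons per
# ligand, Tiron being supplied as the diprotonated H2L^2- salt).
.base_volume_at_pH <- function(model, pH, total_Fe, total_L,
                               acid0, V0_mL, base_conc) {
  TH0 <- acid0 + 2 * total_L
  g <- function(Vb) {
    dil <- V0_mL / (V0_mL + Vb)
    .proton_content(model, pH, total_Fe * dil, total_L * dil) *
      (V0_mL + Vb) - (TH0 * V0_mL - base_conc * Vb)
  }
  Vmax <- max(1e-6, 2 * TH0 * V0_mL / base_conc + 1)
  g0 <- g(0)
  if (g0 >= 0) return(0) # already at or above target pH before any base
  stats::uniroot(g, c(0, Vmax), tol = 1e-12)$root
}

#' Refine equilibrium constants against titration datasets
#'
#' Weighted least-squares refinement of a selected subset of the equilibrium
#' constants (and, optionally, of the molar absorptivities) against one or
#' more simulated or measured titration datasets, in the spirit of classical
#' equilibrium-refinement programs. Uncertainties (1 sigma) are computed
#' from the curvature of the objective (Jacobian-based covariance) at the
#' optimum.
#'
#' @param datasets a list of `titration_dataset` objects (absorbance and/or
#'   base-volume)
#' @param model0 starting [species_model()]; fixed constants retain these
#'   values
#' @param free character vector of constant names to refine, subset of
#'   `c("logK1H","logK2H","logK_FeL","logK_FeL2","logK_FeL3","logK_FeL2Hm1")`
#' @param free_eps also refine all molar absorptivities of the absorbing
#'   species (absorbance datasets only)
#' @param control passed to [minpack.lm::nls.lm.control()]
#' @return object of class `fit_result`: list with `model` (refined
#'   [species_model()]), `coefficients` (data.frame of free parameters,
#'   estimates and 1-sigma uncertainties), `fixed`, `objective` (residual
#'   sum of squares), `converged`, `rank_deficient`, `residuals`
#' @export
refine_constants <- function(datasets, model0, free = "logK_FeL2",
                             free_eps = FALSE,
                             control = minpack.lm::nls.lm.control(maxiter = 200)) {
  if (!length(datasets)) stop("at least one dataset is required")
  if (inherits(datasets, "titration_dataset")) datasets <- list(datasets)
  allowed <- c("logK1H", "logK2H", "logK_FeL", "logK_FeL2", "logK_FeL3",
               "logK_FeL2Hm1")
  if (length(free) && !all(free %in% allowed))
    stop("free constants must be among: ", paste(allowed, collapse = ", "))

  eps_par <- character(0)
  eps_template <- NULL
  if (free_eps) {
    i_abs <- which(vapply(datasets, function(d) d$kind == "absorbance",
                          logical(1)))
    if (!length(i_abs)) stop("free_eps requires an absorbance dataset")
    eps_template <- datasets[[i_abs[1]]]$eps
    eps_par <- as.vector(outer(rownames(eps_template), colnames(eps_template),
                               function(s, w) paste0("eps.", s, ".", w)))
  }

  theta0 <- c(unlist(model0[free]),
              if (free_eps) structure(as.vector(eps_template), names = eps_par))
  names(theta0)[seq_along(free)] <- free

  build_model <- function(theta) {
    m <- model0
    for (nm in free) m[[nm]] <- theta[[nm]]
    class(m) <- "species_model"
    m
  }
  build_eps <- function(theta, d) {
    if (!free_eps || d$kind != "absorbance") return(d$eps)
    e <- d$eps
    e[] <- theta[eps_par]
    e
  }

  resid_fun <- function(theta) {
    m <- build_model(theta)
    unlist(lapply(datasets, function(d) {
      pH_true <- if (isTRUE(d$measured_pH)) d$points$pH - m$pA else d$points$pH
      if (d$kind == "absorbance") {
        e <- build_eps(theta, d)
        pred <- matrix(t(vapply(pH_true, function(p) {
          st <- solve_speciation(m, solution_conditions(d$total_Fe, d$total_L, p))
          as.numeric(d$path_length * (st$concentrations[rownames(e)] %*% e))
        }, numeric(ncol(e)))), nrow = length(pH_true), ncol = ncol(e))
        as.vector(pred - as.matrix(d$points[paste0("A", colnames(e))]))
      } else {
        pred <- vapply(pH_true, function(p)
          .base_volume_at_pH(m, p, d$total_Fe, d$total_L,
                             d$acid0, d$V0_mL, d$base_conc), numeric(1))
        (pred - d$points$V_base_mL) / max(mean(abs(d$points$V_base_mL)), 1e-12)
      }
    }))
  }

  if (!length(theta0)) {
    r <- resid_fun(theta0)
    return(structure(list(model = model0,
                          coefficients = data.frame(estimate = numeric(0),
                                                    sigma = numeric(0)),
                          fixed = unlist(model0[setdiff(allowed, free)]),
                          objective = sum(r^2), converged = TRUE,
                          rank_deficient = FALSE, residuals = r),
                     class = "fit_result"))
  }

  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fun, control = control)
  theta <- stats::coef(fit)
  r <- resid_fun(theta)
  J <- .num_jacobian(resid_fun, theta)
  rank_def <- qr(J)$rank < length(theta)
  if (rank_def)
    warning("refinement is rank-deficient: more free parameters than the data determine")
  sig <- .sigma_from_jacobian(J, r)

  structure(list(model = build_model(theta),
                 coefficients = data.frame(estimate = theta, sigma = sig,
                                           row.names = names(theta)),
                 eps = if (free_eps) {
                   e <- eps_template; e[] <- theta[eps_par]; e
                 } else NULL,
                 fixed = unlist(model0[setdiff(allowed, free)]),
                 objective = sum(r^2),
                 converged = fit$info %in% 1:4,
                 rank_deficient = rank_def,
                 residuals = r),
            class = "fit_result")
}

# forward-difference Jacobian of a residual-vector function
.num_jacobian <- function(fn, theta, rel = 1e-6, abs_min = 1e-10) {
  r0 <- fn(theta)
  J <- matrix(0, length(r0), length(theta),
              dimnames = list(NULL, names(theta)))
  for (j in seq_along(theta)) {
    dh <- max(abs(theta[j]) * rel, abs_min)
    th <- theta; th[j] <- th[j] + dh
    J[, j] <- (fn(th) - r0) / dh
  }
  J
}

# 1-sigma uncertainties from the Jacobian-based covariance at the optimum;
# a pseudo-inverse keeps near-singular (poorly determined) directions finite
.sigma_from_jacobian <- function(J, r) {
  p <- ncol(J); n <- length(r)
  s2 <- sum(r^2) / max(n - p, 1)
  sv <- svd(crossprod(J))
  keep <- sv$d > max(sv$d) * 1e-12
  dinv <- ifelse(keep, 1 / sv$d, 0)
  cov <- sv$v %*% (dinv * t(sv$u)) * s2
  sqrt(pmax(diag(cov), 0))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Least-squares fit result\n")
  cat(sprintf("  objective (RSS): %.6g   converged: %s\n",
              x$objective, x$converged))
  if (isTRUE(x$rank_deficient)) cat("  WARNING: rank-deficient problem\n")
  if (nrow(x$coefficients)) {
    cat("  free parameters (estimate +/- 1 sigma):\n")
    print(signif(x$coefficients, 6))
  } else cat("  no free parameters (echo of the fixed model)\n")
  invisible(x)
}
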