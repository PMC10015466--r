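#' Equilibrium model of the Fe(III)-Tiron system
#'
#' Bundles the equilibrium constants (decadic logarithms, concentration
#' constants at fixed ionic strength) that define the solution chemistry of
#' Fe(III) with Tiron (L = 4,5-dihydroxy-1,3-benzenedisulfonate, fully
#' deprotonated form L^4-):
#' \describe{
#'   \item{`logK1H`, `logK2H`}{stepwise ligand protonation constants,
#'     \eqn{K_i^H = [H_iL]/([H_{i-1}L][H^+])}.}
#'   \item{`logK_FeL`, `logK_FeL2`, `logK_FeL3`}{stepwise stability constants
#'     \eqn{K_{FeL_x} = [FeL_x]/([FeL_{x-1}][L])}.}
#'   \item{`logK_FeL2Hm1`}{protonation constant linking the mixed hydroxo
#'     complex to the bis complex, \eqn{K = [FeL_2]/([FeL_2H_{-1}][H^+])},
#'     i.e. \eqn{[FeL_2H_{-1}]} (one bound water replaced by OH-) grows above
#'     pH = logK. Set to `NA` to exclude the species from the model.}
#'   \item{`pKw`}{stoichiometric water ionic product.}
#'   \item{`pA`}{offset between electrode pH reading and -log[H+];
#'     `pH_true = pH_read - pA`.}
#' }
#'
#' Defaults are the constants determined at 0.15 M NaNO3, 25 C; see
#' [tiron_constants()].
#'
#' @param logK1H,logK2H ligand protonation constants (log10)
#' @param logK_FeL,logK_FeL2,logK_FeL3 stepwise stability constants (log10)
#' @param logK_FeL2Hm1 protonation constant of the hydroxo species, or `NA`
#' @param pKw stoichiometric water ionic product
#' @param pA electrode offset, pH units
#' @return object of class `species_model`
#' @export
#' @examples
#' m <- species_model()
#' m$logK_FeL + m$logK_FeL2   # cumulative log beta2
species_model <- function(logK1H = 12.40, logK2H = 7.46,
                          logK_FeL = 20.32, logK_FeL2 = 14.49,
                          logK_FeL3 = 9.83, logK_FeL2Hm1 = 7.86,
                          pKw = 13.77, pA = 0.02) {
  num <- c(logK1H = logK1H, logK2H = logK2H, logK_FeL = logK_FeL,
           logK_FeL2 = logK_FeL2, logK_FeL3 = logK_FeL3, pKw = pKw, pA = pA)
  if (any(!is.finite(num)))
    stop("all equilibrium constants except logK_FeL2Hm1 must be finite")
  if (logK1H <= logK2H)
    stop("first protonation must be stronger than the second (logK1H > logK2H)")
  structure(list(logK1H = logK1H, logK2H = logK2H,
                 logK_FeL = logK_FeL, logK_FeL2 = logK_FeL2,
                 logK_FeL3 = logK_FeL3, logK_FeL2Hm1 = logK_FeL2Hm1,
                 pKw = pKw, pA = pA),
            class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat("Fe(III)-Tiron equilibrium model (log10 concentration constants)\n")
  cat(sprintf("  ligand:  logK1H = %.2f  logK2H = %.2f\n", x$logK1H, x$logK2H))
  cat(sprintf("  complex: logK_FeL = %.2f  logK_FeL2 = %.2f  logK_FeL3 = %.2f\n",
              x$logK_FeL, x$logK_FeL2, x$logK_FeL3))
  if (is.finite(x$logK_FeL2Hm1 %||% NA))
    cat(sprintf("  hydroxo: logK_FeL2Hm1 = %.2f\n", x$logK_FeL2Hm1))
  cat(sprintf("  pKw = %.2f   pA = %.2f\n", x$pKw, x$pA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solution conditions for a speciation calculation
#'
#' @param total_Fe total iron concentration, mol/L
#' @param total_L total Tiron concentration, mol/L
#' @param pH -log10 of the free hydrogen-ion concentration
#' @param temperature K (metadata only; constants are 25 C values)
#' @param ionic_strength mol/L (metadata only)
#' @return object of class `solution_conditions`
#' @export
solution_conditions <- function(total_Fe, total_L, pH,
                                temperature = 298.15, ionic_strength = 0.15) {
  if (!is.finite(pH)) stop("pH must be finite")
  if (total_Fe < 0 || total_L < 0) stop("total concentrations must be >= 0")
  structure(list(total_Fe = total_Fe, total_L = total_L, pH = pH,
                 temperature = temperature, ionic_strength = ionic_strength),
            class = "solution_conditions")
}

# Side-reaction coefficients at fixed [H+] = h.
# alphaL: free-ligand protonation polynomial 1 + K1H h + K1H K2H h^2
# Complex cumulative constants as powers of free [L]; the hydroxo species
# enters with beta2 / (K_FeL2Hm1 * h).
.spec_coefs <- function(model, h) {
  K1 <- 10^model$logK1H; K2 <- 10^model$logK2H
  b1 <- 10^model$logK_FeL
  b2 <- 10^(model$logK_FeL + model$logK_FeL2)
  b3 <- 10^(model$logK_FeL + model$logK_FeL2 + model$logK_FeL3)
  bOH <- if (is.finite(model$logK_FeL2Hm1 %||% NA))
    b2 / (10^model$logK_FeL2Hm1 * h) else 0
  list(alphaL = 1 + K1 * h + K1 * K2 * h^2, K1 = K1, K2 = K2,
       b1 = b1, b2 = b2, b3 = b3, bOH = bOH)
}

# Free [Fe3+] given free ligand x at fixed h (from the Fe mass balance).
.free_fe <- function(cf, x, total_Fe) {
  total_Fe / (1 + cf$b1 * x + (cf$b2 + cf$bOH) * x^2 + cf$b3 * x^3)
}

# Ligand mass-balance residual as a function of free ligand x; strictly
# increasing in x, which makes the root unique and bracketable.
.lig_residual <- function(cf, x, total_Fe, total_L) {
  y <- .free_fe(cf, x, total_Fe)
  x * cf$alphaL +
    y * (cf$b1 * x + 2 * (cf$b2 + cf$bOH) * x^2 + 3 * cf$b3 * x^3) - total_L
}

.state_from_free <- function(model, cf, x, y, h, cond) {
  conc <- c(
    L = x,
    HL = cf$K1 * h * x,
    H2L = cf$K1 * cf$K2 * h^2 * x,
    Fe = y,
    FeL = cf$b1 * x * y,
    FeL2 = cf$b2 * x^2 * y,
    FeL3 = cf$b3 * x^3 * y,
    FeL2Hm1 = cf$bOH * x^2 * y
  )
  fe_tot <- cond$total_Fe
  fe_species <- conc[c("Fe", "FeL", "FeL2", "FeL3", "FeL2Hm1")]
  fractions <- if (fe_tot > 0) fe_species / fe_tot else fe_species * 0
  structure(list(concentrations = conc, fe_fractions = fractions,
                 conditions = cond, model = model),
            class = "speciation_state")
}

#' Solve the Fe(III)-Tiron multi-equilibrium mass balance at fixed pH
#'
#' Distributes the total iron and total ligand among the species
#' L, HL, H2L, free Fe3+, FeL, FeL2, FeL3 and FeL2H-1 at a stated pH
#' (pH-stat assumption: `[H+] = 10^-pH` is held fixed). The two coupled
#' mass balances are reduced exactly to a single monotone equation in the
#' free ligand concentration (free Fe3+ is eliminated analytically), which
#' is solved by Brent's method in log space - guaranteeing positivity -
#' and polished by Newton steps to a relative mass-balance residual
#' below 1e-12.
#'
#' @param model a [species_model()]
#' @param cond a [solution_conditions()]
#' @return object of class `speciation_state`: a list with
#'   `concentrations` (mol/L, named), `fe_fractions` (mole fractions of the
#'   iron-containing species, summing to 1), and the inputs.
#' @export
#' @examples
#' st <- solve_speciation(species_model(),
#'                        solution_conditions(1.88e-3, 94.0e-3, 4.3))
#' st$fe_fractions["FeL2"]
solve_speciation <- function(model, cond) {
  stopifnot(inherits(model, "species_model"),
            inherits(cond, "solution_conditions"))
  h <- 10^(-cond$pH)
  cf <- .spec_coefs(model, h)

  if (cond$total_L == 0) {
    return(.state_from_free(model, cf, 0, cond$total_Fe, h, cond))
  }
  if (cond$total_Fe == 0) {
    x <- cond$total_L / cf$alphaL
    return(.state_from_free(model, cf, x, 0, h, cond))
  }

  f <- function(lx) .lig_residual(cf, 10^lx, cond$total_Fe, cond$total_L)
  lo <- -45; hi <- log10(cond$total_L) + 1
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0)
    stop(sprintf("speciation solver could not bracket the root at pH %.3f, [Fe]t = %.3g M, [L]t = %.3g M",
                 cond$pH, cond$total_Fe, cond$total_L))
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-14, maxiter = 1000)
  lx <- root$root

  # Newton polish on log10(x) against the (monotone) ligand balance
  for (i in seq_len(6)) {
    x <- 10^lx
    r <- .lig_residual(cf, x, cond$total_Fe, cond$total_L)
    dr <- (.lig_residual(cf, x * (1 + 1e-7), cond$total_Fe, cond$total_L) - r) /
      (x * 1e-7)
    if (!is.finite(dr) || dr == 0) break
    step <- r / dr
    lx <- lx - step / (x * log(10))
    if (abs(step / x) < 1e-15) break
  }
  x <- 10^lx
  y <- .free_fe(cf, x, cond$total_Fe)
  .state_from_free(model, cf, x, y, h, cond)
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf("Speciation at pH %.2f ([Fe]t = %.3g M, [L]t = %.3g M)\n",
              x$conditions$pH, x$conditions$total_Fe, x$conditions$total_L))
  print(signif(x$concentrations, 4))
  if (x$conditions$total_Fe > 0) {
    cat("Fe mole fractions:\n")
    print(round(x$fe_fractions, 4))
  }
  invisible(x)
}

#' Species distribution curve over a pH grid
#'
#' Solves the speciation at each pH of a strictly increasing grid and
#' returns the mole fractions of the iron-containing species (and the free
#' ligand species as fractions of total ligand).
#'
#' @param model a [species_model()]
#' @param total_Fe,total_L totals, mol/L
#' @param pH_grid strictly increasing numeric vector
#' @return data.frame with columns `pH`, `Fe`, `FeL`, `FeL2`, `FeL3`,
#'   `FeL2Hm1` (iron mole fractions) and `L`, `HL`, `H2L` (ligand fractions)
#' @export
#' @examples
#' d <- distribution_curve(species_model(), 2e-4, 9e-3, seq(0, 10, 0.5))
#' rowSums(d[, c("Fe", "FeL", "FeL2", "FeL3", "FeL2Hm1")])
distribution_curve <- function(model, total_Fe, total_L, pH_grid) {
  if (any(diff(pH_grid) <= 0)) stop("pH_grid must be strictly increasing")
  rows <- lapply(pH_grid, function(p) {
    st <- tryCatch(
      solve_speciation(model, solution_conditions(total_Fe, total_L, p)),
      error = function(e) stop(sprintf("pH %.3f: %s", p, conditionMessage(e)))
    )
    cc <- st$concentrations
    lig_free <- if (total_L > 0) cc[c("L", "HL", "H2L")] / total_L else
      cc[c("L", "HL", "H2L")] * 0
    c(pH = p, st$fe_fractions, lig_free)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("pH", "Fe", "FeL", "FeL2", "FeL3", "FeL2Hm1",
                  "L", "HL", "H2L")
  out
}
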