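model <- tiron_constants()

test_that("no-metal solutions distribute the ligand by protonation alone", {
  st <- solve_speciation(model, solution_conditions(0, 1e-3, 6.0))
  cc <- st$concentrations
  expect_equal(unname(cc[c("Fe", "FeL", "FeL2", "FeL3", "FeL2Hm1")]),
               rep(0, 5))
  h <- 1e-6
  alpha <- 1 + 10^model$logK1H * h + 10^(model$logK1H + model$logK2H) * h^2
  expect_equal(cc[["L"]], 1e-3 / alpha, tolerance = 1e-12)
  expect_equal(cc[["HL"]], cc[["L"]] * 10^model$logK1H * h, tolerance = 1e-12)
})

test_that("mass balances close to 1e-10 relative across a totals x pH grid", {
  for (FeT in c(1e-5, 2e-4, 1.88e-3, 1e-2)) {
    for (LT in c(5e-4, 9e-3, 9.4e-2)) {
      for (pH in seq(0, 11.5, length.out = 20)) {
        st <- solve_speciation(model, solution_conditions(FeT, LT, pH))
        cc <- st$concentrations
        expect_true(all(cc >= 0))
        fe <- sum(cc[c("Fe", "FeL", "FeL2", "FeL3", "FeL2Hm1")])
        lg <- cc[["L"]] + cc[["HL"]] + cc[["H2L"]] + cc[["FeL"]] +
          2 * cc[["FeL2"]] + 3 * cc[["FeL3"]] + 2 * cc[["FeL2Hm1"]]
        expect_lt(abs(fe - FeT) / FeT, 1e-10)
        expect_lt(abs(lg - LT) / LT, 1e-10)
      }
    }
  }
})

test_that("solver matches the grid+bisection oracle to 6 significant figures", {
  # frozen instance: dilute 1:5 solution at physiological pH
  st <- solve_speciation(model, solution_conditions(1e-4, 5e-4, 7.4))
  expect_equal(st$concentrations[["L"]], 1.00785103776e-09, tolerance = 1e-7)
  expect_equal(st$concentrations[["Fe"]], 1.86845476583e-22, tolerance = 1e-7)

  set.seed(42)
  for (i in 1:50) {
    FeT <- 10^runif(1, -5, -2)
    LT <- FeT * 10^runif(1, 0.2, 2)
    pH <- runif(1, 1, 11)
    st <- solve_speciation(model, solution_conditions(FeT, LT, pH))
    or <- oracle_speciation(model$logK1H, model$logK2H, model$logK_FeL,
                            model$logK_FeL2, model$logK_FeL3,
                            model$logK_FeL2Hm1, FeT, LT, pH)
    expect_equal(st$concentrations[["L"]], or$conc[["L"]], tolerance = 1e-6)
    expect_equal(st$concentrations[["Fe"]], or$conc[["Fe"]], tolerance = 1e-6)
    expect_equal(st$concentrations[["FeL2"]], or$conc[["FeL2"]],
                 tolerance = 1e-6)
  }
})

test_that("the bis complex dominates near pH 4.3 at a 1:50 ratio", {
  st <- solve_speciation(model, solution_conditions(1.88e-3, 94.0e-3, 4.3))
  expect_gte(st$fe_fractions[["FeL2"]], 0.90)
})

test_that("distribution curves are normalized, continuous and cross at the oracle pH", {
  d <- distribution_curve(model, 2e-4, 9e-3, seq(0, 10, 0.1))
  fe_cols <- c("Fe", "FeL", "FeL2", "FeL3", "FeL2Hm1")
  expect_equal(rowSums(d[fe_cols]), rep(1, nrow(d)), tolerance = 1e-9)
  expect_true(all(as.matrix(d[fe_cols]) >= 0 & as.matrix(d[fe_cols]) <= 1))

  fine <- distribution_curve(model, 2e-4, 9e-3, seq(2, 9, 0.01))
  jumps <- apply(abs(apply(as.matrix(fine[fe_cols]), 2, diff)), 1, max)
  expect_lt(max(jumps), 0.02)

  # FeL/FeL2 crossover fixed by bisection on the oracle fraction difference
  i <- which(d$FeL2 > d$FeL)[1]
  expect_gt(d$pH[i - 1], 3.6)
  expect_lt(d$pH[i], 3.81)
  g <- distribution_curve(model, 2e-4, 9e-3, c(3.715, 3.716))
  expect_lt(abs(g$FeL[1] - g$FeL2[1]) /
              max(g$FeL[1], 1e-12), 0.01) # crossover at pH 3.7153
})

test_that("tris-complex abundance responds monotonically to its constant", {
  weak <- species_model(logK_FeL3 = model$logK_FeL3 - 5)
  base <- solve_speciation(model, solution_conditions(2e-4, 9e-3, 8.0))
  low <- solve_speciation(weak, solution_conditions(2e-4, 9e-3, 8.0))
  expect_lt(low$fe_fractions[["FeL3"]], base$fe_fractions[["FeL3"]])
})

test_that("absorbance simulation obeys Beer-Lambert", {
  eps0 <- matrix(0, 3, 2, dimnames = list(c("FeL", "FeL2", "FeL3"),
                                          c("480", "562")))
  td0 <- simulate_observable(model, "absorbance", 1.9e-4, 9.1e-3,
                             pH = seq(2, 9, 1), eps = eps0)
  expect_true(all(as.matrix(td0$points[c("A480", "A562")]) == 0))

  eps1 <- matrix(c(0, 1000, 0), 3, 1,
                 dimnames = list(c("FeL", "FeL2", "FeL3"), "562"))
  td1 <- simulate_observable(model, "absorbance", 1.9e-4, 9.1e-3,
                             pH = 4.3, eps = eps1)
  st <- solve_speciation(model, solution_conditions(1.9e-4, 9.1e-3, 4.3))
  expect_equal(td1$points$A562, 1000 * st$concentrations[["FeL2"]],
               tolerance = 1e-12)

  # a species declared absorbing but missing from the eps table is an error
  eps_bad <- eps1[c("FeL", "FeL2"), , drop = FALSE]
  expect_error(simulate_observable(model, "absorbance", 1.9e-4, 9.1e-3,
                                   pH = 4.3, eps = eps_bad),
               "missing molar absorptivity")
})

test_that("absorbance has no more transition regions than the speciation", {
  # finite differences of A(pH) change sign at most as often as the
  # underlying species fractions swap dominance
  eps <- matrix(c(1800, 2600, 2100), 3, 1,
                dimnames = list(c("FeL", "FeL2", "FeL3"), "562"))
  pH <- seq(1, 10, 0.05)
  td <- simulate_observable(model, "absorbance", 1.9e-4, 9.1e-3, pH, eps = eps)
  dA <- diff(td$points$A562)
  sign_changes <- sum(diff(sign(dA[abs(dA) > 1e-8])) != 0)
  expect_lte(sign_changes, 3) # Fe->FeL->FeL2->FeL3 transitions
})

test_that("base-volume titrations consume base monotonically and honour pA", {
  td <- simulate_observable(model, "base-volume", 2e-3, 4e-3,
                            pH = seq(2.5, 11, 0.5),
                            acid0 = 0.01, V0_mL = 6, base_conc = 0.1)
  expect_true(all(diff(td$points$V_base_mL) > 0))
  tdm <- simulate_observable(model, "base-volume", 2e-3, 4e-3,
                             pH = seq(2.5, 11, 0.5),
                             acid0 = 0.01, emulate_measured = TRUE)
  expect_equal(tdm$points$pH, td$points$pH + model$pA)
  expect_equal(tdm$points$V_base_mL, td$points$V_base_mL)
})

test_that("noiseless refinement recovers a perturbed stability constant", {
  truth <- tiron_constants()
  td <- make_titration(truth, pH = seq(2, 10, 0.25))
  start <- species_model(logK_FeL2 = truth$logK_FeL2 + 0.4)
  fit <- refine_constants(list(td), start, free = "logK_FeL2")
  expect_true(fit$converged)
  expect_lt(abs(fit$model$logK_FeL2 - 14.49), 1e-3)
  expect_lt(fit$coefficients["logK_FeL2", "sigma"], 1e-3)
})

test_that("refinement with no free parameters echoes the fixed model", {
  td <- make_titration(model, pH = seq(2, 10, 0.5))
  fit <- refine_constants(list(td), model, free = character(0))
  expect_equal(fit$model$logK_FeL2, model$logK_FeL2)
  expect_lt(fit$objective, 1e-20)
})

test_that("noisy replicate refinements are unbiased and calibrated", {
  truth <- tiron_constants()
  start <- species_model(logK_FeL2 = truth$logK_FeL2 + 0.2)
  fits <- lapply(1:12, function(s) {
    td <- make_titration(truth, pH = seq(2, 10, 0.5),
                         noise = noise_spec("absolute-gaussian", 0.005,
                                            seed = s))
    refine_constants(list(td), start, free = "logK_FeL2")
  })
  est <- vapply(fits, function(f) f$model$logK_FeL2, numeric(1))
  sig <- vapply(fits, function(f) f$coefficients["logK_FeL2", "sigma"],
                numeric(1))
  # bias within 3 standard errors of the replicate mean
  expect_lt(abs(mean(est) - truth$logK_FeL2),
            3 * stats::sd(est) / sqrt(length(est)))
  # replicate spread consistent with the reported curvature uncertainty
  expect_gt(stats::sd(est) / mean(sig), 0.5)
  expect_lt(stats::sd(est) / mean(sig), 2)
})

test_that("invalid inputs are rejected with clear errors", {
  expect_error(solution_conditions(-1e-3, 1e-3, 7), "must be >= 0")
  expect_error(species_model(logK1H = 5, logK2H = 7), "stronger")
  expect_error(distribution_curve(model, 1e-3, 1e-3, c(2, 1)),
               "strictly increasing")
})
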