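rate <- tiron_rate_constants()
eq <- tiron_constants()

test_that("trace fitting recovers a noiseless rate constant exactly", {
  tr <- make_traces(kd = 1e-4, times = seq(0, 4e4, length.out = 40))[[1]]
  fit <- fit_trace(tr)
  expect_equal(fit$kd, 1e-4, tolerance = 1e-8)
  expect_equal(fit$A0, 0.75, tolerance = 1e-8)
  expect_equal(fit$Ap, 0.10, tolerance = 1e-8)
  fitf <- fit_trace(tr, fix_endpoints = TRUE)
  expect_equal(fitf$kd, 1e-4, tolerance = 1e-4)
})

test_that("degenerate and under-sampled traces are caught", {
  flat <- kinetic_trace(seq(0, 100, 10), rep(0.5, 11))
  expect_error(fit_trace(flat), "degenerate trace")
  short <- make_traces(kd = 1e-4, times = c(0, 500, 1500, 3000))[[1]]
  fit <- fit_trace(short)
  expect_true("fewer than 5 points" %in% fit$flags)
  expect_true("span < 2 half-lives" %in% fit$flags)
  lowx <- kinetic_trace(seq(0, 1e4, 500),
                        0.1 + 0.6 * exp(-8e-5 * seq(0, 1e4, 500)),
                        CDTA_t = 1e-3, Fe_t = 1e-4)
  expect_true("CDTA excess below 20-fold" %in% fit_trace(lowx)$flags)
})

test_that("noisy replicate trace fits are unbiased", {
  kds <- vapply(1:10, function(s) {
    tr <- make_traces(kd = 8e-5, times = seq(0, 4e4, length.out = 40),
                      noise = noise_spec("absolute-gaussian", 0.002,
                                         seed = 100 + s))[[1]]
    fit_trace(tr)$kd
  }, numeric(1))
  expect_lt(abs(mean(kds) / 8e-5 - 1), 0.05)
  expect_true(all(abs(kds / 8e-5 - 1) < 0.15))
})

test_that("the rate law reduces to k0 when the tris complex dominates", {
  pure3 <- kinetic_rate_model(k0 = 8e-5, k1 = 0, k4 = 0,
                              logK_FeL3_kin = 9.20)
  kd <- observed_kd(pure3, eq, pH = 9.0, total_Fe = 1e-4, total_L = 1e-2,
                    CDTA = 0)
  expect_equal(kd, 8e-5, tolerance = 1e-3)
})

test_that("the pathway-weighted rate law reproduces the tabulated kd at pH 7.4", {
  kd <- observed_kd(rate, eq, pH = 7.4, total_Fe = 1e-4, total_L = 5e-4,
                    CDTA = 0)
  expect_equal(kd, 1.1e-4, tolerance = 0.10)
  # frozen oracle value with the proton+CDTA pathway active
  kd5 <- observed_kd(rate, eq, pH = 5.0, total_Fe = 1e-4, total_L = 5e-4,
                     CDTA = 8e-3)
  expect_equal(kd5, 0.0949936449842, tolerance = 1e-9)
})

test_that("kd grows with acidity and with CDTA", {
  kds <- vapply(seq(7.5, 5.0, -0.5), function(p)
    observed_kd(rate, eq, p, 1e-4, 5e-4, 2e-3), numeric(1))
  expect_true(all(diff(kds) > 0))
  kdc <- vapply(c(0, 2e-3, 5e-3, 8e-3), function(cd)
    observed_kd(rate, eq, 6.0, 1e-4, 5e-4, cd), numeric(1))
  expect_true(all(diff(kdc) > 0))
})

test_that("half-life conversion and the comparative inertness ordering hold", {
  expect_equal(half_life(log(2)), 1 / 3600, tolerance = 1e-12)
  expect_equal(half_life(1.1e-4), 1.8, tolerance = 0.03)
  expect_equal(half_life(2.9e-6), 66, tolerance = 0.03)
  expect_error(half_life(0), "kd must be > 0")
  kd_tiron <- observed_kd(rate, eq, 7.4, 1e-4, 5e-4, 0)
  kd_edta <- hydroxide_kd(5e-6, 1.0, 1.4e3, 7.4)
  kd_cdta <- hydroxide_kd(3.2e-7, 3.6e-3, 1.2, 7.4)
  expect_true(kd_tiron > kd_edta && kd_edta > kd_cdta)
  expect_true(half_life(kd_tiron) < half_life(kd_edta))
})

test_that("rate-constant refinement recovers a noiseless kd surface", {
  grid <- expand.grid(pH = seq(5.0, 7.5, 0.5), CDTA = c(0, 2e-3, 5e-3, 8e-3))
  grid$kd <- mapply(function(p, cd)
    observed_kd(rate, eq, p, 1e-4, 5e-4, cd), grid$pH, grid$CDTA)
  start <- kinetic_rate_model(k0 = 2e-4, k1 = 1e3, k4 = 2e6,
                              logK_FeL3_kin = 8.5)
  fit <- refine_rate_constants(grid, start, eq)
  expect_true(fit$converged)
  expect_equal(fit$model$k0, 8e-5, tolerance = 0.01)
  expect_equal(fit$model$k1, 3.9e3, tolerance = 0.01)
  expect_equal(fit$model$k4, 7e5, tolerance = 0.01)
  expect_equal(fit$model$logK_FeL3_kin, 9.20, tolerance = 0.01)
})

test_that("refinement tolerates noise and flags unidentifiable designs", {
  grid <- expand.grid(pH = seq(5.0, 7.5, 0.5), CDTA = c(0, 2e-3, 5e-3, 8e-3))
  kd0 <- mapply(function(p, cd)
    observed_kd(rate, eq, p, 1e-4, 5e-4, cd), grid$pH, grid$CDTA)
  start <- kinetic_rate_model(k0 = 2e-4, k1 = 2e3, k4 = 2e6,
                              logK_FeL3_kin = 9.0)
  for (s in 1:5) {
    set.seed(200 + s)
    g <- grid
    g$kd <- kd0 * (1 + 0.05 * rnorm(length(kd0)))
    fit <- refine_rate_constants(g, start, eq)
    expect_lt(abs(fit$model$k0 / 8e-5 - 1), 0.15)
    expect_lt(abs(fit$model$k1 / 3.9e3 - 1), 0.15)
    expect_lt(abs(fit$model$k4 / 7e5 - 1), 0.15)
  }
  no_cdta <- expand.grid(pH = seq(5.0, 7.5, 0.25), CDTA = 0)
  no_cdta$kd <- vapply(no_cdta$pH, function(p)
    observed_kd(rate, eq, p, 1e-4, 5e-4, 0), numeric(1))
  expect_warning(refine_rate_constants(no_cdta, start, eq),
                 "rank-deficient")
})

test_that("end-to-end: traces through trace fits to rate constants", {
  grid <- expand.grid(pH = c(5.5, 6.0, 6.5, 7.0), CDTA = c(2e-3, 8e-3))
  grid$kd_true <- mapply(function(p, cd)
    observed_kd(rate, eq, p, 1e-4, 5e-4, cd), grid$pH, grid$CDTA)
  grid$kd <- vapply(seq_len(nrow(grid)), function(i) {
    tmax <- min(5 / grid$kd_true[i], 5e4)
    tr <- make_traces(grid$kd_true[i],
                      times = seq(0, tmax, length.out = 30))[[1]]
    fit_trace(tr)$kd
  }, numeric(1))
  start <- kinetic_rate_model(k0 = 3e-4, k1 = 1e3, k4 = 3e6,
                              logK_FeL3_kin = 9.0)
  fit <- refine_rate_constants(grid[c("pH", "CDTA", "kd")], start, eq)
  expect_lt(abs(fit$model$k1 / 3.9e3 - 1), 0.01)
  expect_lt(abs(fit$model$k4 / 7e5 - 1), 0.01)
})
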