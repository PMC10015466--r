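feL2 <- tiron_relax_params("FeL2")
feL3 <- tiron_relax_params("FeL3")
feL1 <- tiron_relax_params("FeL1")

test_that("electron relaxation is symmetric at zero field and vanishes with Delta2", {
  lowf <- field_point(1e-6)
  Te <- electron_relaxation(lowf, 298.15, 12.2e20, 5.6)
  expect_equal(Te$T1e, Te$T2e, tolerance = 1e-10)
  Te0 <- electron_relaxation(field_point(60), 298.15, 0, 5.6)
  expect_identical(Te0$T1e, Inf)
  expect_identical(Te0$T2e, Inf)
  # frozen closed-form value at 60 MHz with the bis-complex parameters
  Te60 <- electron_relaxation(field_point(60), 298.15, 12.2e20, 5.6)
  expect_equal(Te60$T1e, 1.4299174205e-10, tolerance = 1e-9)
})

test_that("inner-sphere term obeys its structural limits", {
  expect_equal(inner_sphere_r1(feL3, field_point(c(0.01, 60))), c(0, 0))
  # slow exchange: r1 -> Pm/tauM, field-independent
  slow <- feL2
  slow$tauM <- 272e6 # x 1e6
  r <- inner_sphere_r1(slow, field_point(c(0.1, 10, 400)))
  Pm <- 2e-3 / physical_constants()$water_molarity
  expect_equal(r, rep(Pm / (272e6 * 1e-9), 3), tolerance = 1e-3)
  # frozen transcription-oracle value (mono complex, 60 MHz, 298.15 K)
  expect_equal(inner_sphere_r1(feL1, field_point(60)), 2.29868918276,
               tolerance = 1e-9)
})

test_that("second-sphere term follows the 1/r^6 law and its oracle value", {
  half <- feL3
  half$r_ss <- feL3$r_ss / 2
  lo <- field_point(0.01)
  expect_equal(second_sphere_r1(half, lo) / second_sphere_r1(feL3, lo),
               2^6, tolerance = 0.01)
  expect_equal(second_sphere_r1(feL3, lo), 2.24234892091, tolerance = 1e-9)
})

test_that("outer-sphere term vanishes with fast diffusion and matches its oracle", {
  fast <- feL3
  fast$D <- 1e6
  expect_lt(outer_sphere_r1(fast, field_point(20)), 1e-8)
  expect_equal(outer_sphere_r1(feL3, field_point(20)), 1.15906233131,
               tolerance = 1e-9)
  # closest-approach insensitivity over 3.4-3.6 A
  p34 <- feL1; p34$a <- 3.4
  p36 <- feL1; p36$a <- 3.6
  r34 <- total_r1(p34, 20)$r1
  r36 <- total_r1(p36, 20)$r1
  expect_lt(abs(r34 - r36) / r36, 0.05)
})

test_that("total relaxivity is the component sum with shares closing to 100", {
  tr <- total_r1(feL2, c(0.01, 1, 32, 60, 120, 500))
  expect_equal(tr$r1, tr$IS + tr$SS + tr$OS, tolerance = 1e-12)
  expect_equal(tr$IS_pct + tr$SS_pct + tr$OS_pct, rep(100, 6),
               tolerance = 1e-9)
  none <- relax_params(q = 0, Delta2 = 9.7e20, tauv = 6.9, q_ss = 0, D = 1e6)
  expect_lt(total_r1(none, 20)$r1, 1e-8)
})

test_that("model reproduces the tabulated relaxivities within 15 percent", {
  printed <- list(FeL3 = c(2.8, 3.2), FeL2 = c(5.4, 6.5), FeL1 = c(3.4, 3.3))
  for (cx in names(printed)) {
    r <- total_r1(tiron_relax_params(cx), c(60, 120))$r1
    expect_lt(max(abs(r - printed[[cx]]) / printed[[cx]]), 0.15)
  }
})

test_that("components stay non-negative over the field x temperature grid", {
  freqs <- 10^seq(log10(0.01), log10(500), length.out = 50)
  for (T in c(283, 288, 298, 310)) {
    tr <- total_r1(feL2, freqs, T)
    expect_true(all(tr$IS >= 0 & tr$SS >= 0 & tr$OS >= 0))
  }
})

test_that("inner-sphere dispersion is non-increasing when rotation dominates", {
  p <- feL1
  p$Delta2 <- 1e18 # negligible electron relaxation: tau_d ~ tauR
  r <- inner_sphere_r1(p, field_point(10^seq(1, log10(500), length.out = 40)))
  expect_true(all(diff(r) <= 1e-12))
})

test_that("temperature laws scale correctly", {
  expect_identical(temperature_scale(70, 16, 298.15, "arrhenius-time"), 70)
  expect_equal(temperature_scale(272, 56.2, 310, "eyring-exchange"),
               109.970916048, tolerance = 1e-9)
  expect_gt(temperature_scale(70, 16, 283, "arrhenius-time"),
            temperature_scale(70, 16, 310, "arrhenius-time"))
  expect_gt(temperature_scale(2.24e-5, 20, 310, "arrhenius-rate"),
            temperature_scale(2.24e-5, 20, 283, "arrhenius-rate"))
  expect_error(temperature_scale(1, 1, 298, "bogus"))
})

test_that("forward model matches the flat transcription oracle on random draws", {
  set.seed(7)
  for (i in 1:100) {
    d <- rand_relax_draw()
    p <- relax_params_from_draw(d)
    nu <- 10^runif(1, log10(0.01), log10(500))
    T <- runif(1, 280, 320)
    got <- total_r1(p, nu, T)
    want <- do.call(oracle_r1, c(list(nu_MHz = nu, T = T), d))
    expect_equal(got$IS, want[["IS"]], tolerance = 1e-10)
    expect_equal(got$SS, want[["SS"]], tolerance = 1e-10)
    expect_equal(got$OS, want[["OS"]], tolerance = 1e-10)
    expect_equal(got$r1, want[["r1"]], tolerance = 1e-10)
  }
})

test_that("parameter validation rejects unphysical values", {
  expect_error(relax_params(q = -1, Delta2 = 1e20, tauv = 5), "non-negative")
  expect_error(relax_params(q = 1, r = -2, tauR = 50, tauM = 100,
                            Delta2 = 1e20, tauv = 5), "r \\(Angstrom\\)")
  expect_error(field_point(-10), "positive")
})
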