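test_that("trimolecular equilibrium handles limits and validates input", {
  ## no binding
  st <- solve_trimolecular_equilibrium(0, 10e-6, 5e-6)
  expect_identical(st$complex, 0)
  expect_identical(st$free_dimer, 10e-6)
  ## no duplex
  st <- solve_trimolecular_equilibrium(1e13, 10e-6, 0)
  expect_identical(st$complex, 0)
  expect_identical(st$free_dimer, 10e-6)
  ## saturating limit: C -> min(A/2, D)
  st <- solve_trimolecular_equilibrium(1e20, 10e-6, 5e-6)
  expect_lt(st$free_duplex / 5e-6, 1e-3)
  expect_equal(st$complex, 5e-6, tolerance = 1e-3)

  expect_error(solve_trimolecular_equilibrium(-1, 1e-6, 1e-6), "non-negative")
  expect_error(solve_trimolecular_equilibrium(Inf, 1e-6, 1e-6), "finite")
  expect_error(solve_trimolecular_equilibrium(1e12, -1e-6, 1e-6), "non-negative")
})

test_that("equilibrium solver agrees with brute-force grid and cubic oracles", {
  cases <- list(c(1e12, 20e-6, 5e-6),
                c(3e13, 1.8e-6, 0.9e-6),
                c(1e10, 50e-6, 20e-6))
  for (cs in cases) {
    st <- solve_trimolecular_equilibrium(cs[1], cs[2], cs[3])
    expect_equal(st$complex, oracle_trimolecular_cubic(cs[1], cs[2], cs[3]),
                 tolerance = 1e-9)
  }
  ## the spec's dense-grid scan case
  st <- solve_trimolecular_equilibrium(1e12, 20e-6, 5e-6)
  expect_equal(st$complex, oracle_trimolecular_grid(1e12, 20e-6, 5e-6),
               tolerance = 1e-6)
  ## residual bound
  resid <- 1e12 * st$free_dimer^2 * st$free_duplex - st$complex
  expect_lt(abs(resid), 1e-10 * max(1, 5e-6))
})

test_that("mass balance holds to 1e-10 relative at every point", {
  for (K in c(1e8, 1e12, 1e14, 1e20)) {
    for (r in seq(0, 4, by = 0.5)) {
      st <- solve_trimolecular_equilibrium(K, r * 5e-6, 5e-6)
      expect_lt(abs(st$free_dimer + 2 * st$complex - r * 5e-6),
                1e-10 * max(1e-12, r * 5e-6))
      expect_lt(abs(st$free_duplex + st$complex - 5e-6), 1e-10 * 5e-6)
      expect_gte(st$free_dimer, -1e-20)
      expect_gte(st$free_duplex, -1e-20)
    }
  }
})

test_that("speciation curve saturates at the 2:1 dimer:duplex ratio", {
  sc <- speciation_curve(1e20, 5e-6, seq(0, 4, by = 0.1))
  expect_identical(sc$complex[sc$ratio == 0], 0)
  expect_true(all(diff(sc$bound_fraction) >= -1e-12))
  expect_equal(min(sc$ratio[sc$bound_fraction >= 0.99]), 2.0)
  ## realistic constant: near- but sub-complete saturation at stoichiometry
  st <- solve_trimolecular_equilibrium(3e13, 2 * 5e-6, 5e-6)
  frac <- st$complex / 5e-6
  expect_equal(st$complex, oracle_trimolecular_cubic(3e13, 10e-6, 5e-6),
               tolerance = 1e-9)
  expect_gt(frac, 0.90)
  expect_lt(frac, 0.99)
})

test_that("bound fraction is monotone in K_A and in dimer:duplex ratio", {
  Ks <- 10^seq(8, 18, by = 1)
  fr_K <- vapply(Ks, function(K)
    solve_trimolecular_equilibrium(K, 10e-6, 5e-6)$complex, numeric(1))
  expect_true(all(diff(fr_K) > 0))
  sc <- speciation_curve(5e12, 5e-6, seq(0, 4, by = 0.2))
  expect_true(all(diff(sc$bound_fraction) >= -1e-12))
})

test_that("sequential model reduces, converges, and matches its 2-D oracle", {
  ## K2 = 0: pure one-site, no doubly-bound species
  s <- sequential_two_site_speciation(1e6, 0, 10e-6, 5e-6)
  expect_identical(s$A4D, 0)
  expect_error(sequential_two_site_speciation(-1, 1, 1e-6, 1e-6),
               "non-negative")

  ## equal-step case against the independent grid scan
  K <- sqrt(3e13)
  s <- sequential_two_site_speciation(K, K, 10e-6, 5e-6)
  o <- oracle_sequential_grid(K, K, 10e-6, 5e-6)
  expect_equal(s$A2D, o$A2D, tolerance = 1e-3)
  expect_equal(s$A4D, o$A4D, tolerance = 1e-3)

  ## cooperative limit: intermediate vanishes monotonically and the
  ## speciation converges to the tri-molecular solution
  Kmac <- 3e13
  ratios <- c(1, 1e2, 1e4, 1e6)
  inter <- vapply(ratios, function(rt) {
    max_intermediate_fraction(sqrt(Kmac / rt), sqrt(Kmac / rt) * rt, 5e-6)
  }, numeric(1))
  expect_true(all(diff(inter) < 0))
  s6 <- sequential_two_site_speciation(sqrt(Kmac / 1e6), sqrt(Kmac / 1e6) * 1e6,
                                       10e-6, 5e-6)
  tri <- solve_trimolecular_equilibrium(Kmac, 10e-6, 5e-6)
  expect_lt(max(abs(c(s6$frac_A4D - tri$complex / 5e-6,
                      s6$frac_D - tri$free_duplex / 5e-6))), 1e-3)
})

test_that("simulated isotherms obey trivial limits and heat conservation", {
  p <- make_test_protocol()
  ## K_A = 0: every normalized heat equals the offset
  sim <- simulate_isotherm(binding_parameters(0, -19, offset = 0.37), p,
                           noise_sd = 0, seed = 1)
  expect_equal(sim$ndh, rep(0.37, 25), tolerance = 1e-12)
  expect_true(all(diff(sim$molar_ratio) > 0))

  ## heat conservation with dilution disabled at saturating K
  sim <- simulate_isotherm(binding_parameters(1e20, -19), p, noise_sd = 0,
                           seed = 1, dilution = FALSE)
  V0 <- 200e-6
  raw_heats <- (sim$ndh) * (2e-6 * 8e-6)   # kcal per injection
  expect_equal(sum(raw_heats), V0 * -19 * sim$complex[25], tolerance = 1e-9)
})

test_that("noiseless isotherm inflects at duplex:dimer ratio 0.5", {
  ## high-resolution protocol so the numerical derivative is clean
  p <- titration_protocol(cell_conc = 5e-6, syringe_conc = 10e-6,
                          injection_volumes = rep(1, 60))
  sim <- simulate_isotherm(binding_parameters(1e14, -19), p, noise_sd = 0,
                           seed = 1)
  slope <- diff(sim$ndh) / diff(sim$molar_ratio)
  mid <- (sim$molar_ratio[-1] + sim$molar_ratio[-length(sim$molar_ratio)]) / 2
  expect_lt(abs(mid[which.max(slope)] - 0.5), 0.05)
})

test_that("fit recovers its own noiseless simulation to 6 significant digits", {
  p <- make_test_protocol(cell_conc = 10e-6, syringe_conc = 45e-6)
  truth <- binding_parameters(1e12, -15, offset = 0)
  sim <- simulate_isotherm(truth, p, noise_sd = 0, seed = 1)
  fit <- fit_isotherm(sim)
  expect_true(fit$converged)
  expect_equal(fit$K_A, 1e12, tolerance = 1e-6)
  expect_equal(fit$dH, -15, tolerance = 1e-6)
  expect_lt(abs(fit$offset), 1e-5)
  expect_equal(fit$dG_kcal_mol, -1.98720425864083e-3 * 298.15 * log(1e12),
               tolerance = 1e-9)
})

test_that("a coarse grid search brackets the optimizer's minimum", {
  p <- make_test_protocol()
  sim <- simulate_isotherm(binding_parameters(3e13, -19), p, noise_sd = 0.19,
                           seed = 11)
  fit <- fit_isotherm(sim)
  grid <- expand.grid(logK = seq(12, 15, by = 0.25),
                      dH = seq(-25, -13, by = 1))
  sse <- mapply(function(lk, dh) {
    m <- simulate_isotherm(binding_parameters(10^lk, dh, fit$offset), p,
                           noise_sd = 0, seed = 1)
    sum((sim$ndh - m$ndh)^2)
  }, grid$logK, grid$dH)
  best <- grid[which.min(sse), ]
  expect_lt(abs(best$logK - fit$log10_K_A), 0.25)
  expect_lt(abs(best$dH - fit$dH), 1)
})

test_that("fit flags a flat, K-uninformative isotherm instead of failing silently", {
  p <- make_test_protocol(cell_conc = 1e-7, syringe_conc = 5e-7)
  sim <- simulate_isotherm(binding_parameters(1e8, -10), p, noise_sd = 0.05,
                           seed = 3)
  fit <- fit_isotherm(sim)
  expect_true(fit$k_lower_bound)
})

test_that("simulate -> fit round trip is exact across the fittable regime", {
  ## steepness K_A * A^2 between 10 and 1e3
  for (steep in c(10, 100, 1000)) {
    A <- 2e-6
    K <- steep / A^2
    p <- make_test_protocol(cell_conc = A, syringe_conc = 4.5 * A)
    sim <- simulate_isotherm(binding_parameters(K, -19), p, noise_sd = 0,
                             seed = 1)
    fit <- fit_isotherm(sim)
    expect_lt(abs(fit$log10_K_A - log10(K)), 1e-4)
    expect_lt(abs(fit$dH + 19), 1e-4)
  }
})

test_that("median recovered log10 K_A is within 0.3 over noise seeds", {
  A <- 1.8e-6
  K <- 3e13
  p <- make_test_protocol(cell_conc = A, syringe_conc = 8e-6)
  recovered <- vapply(1:10, function(s) {
    sim <- simulate_isotherm(binding_parameters(K, -19), p,
                             noise_sd = 0.19, seed = s)
    fit_isotherm(sim)$log10_K_A
  }, numeric(1))
  expect_lt(abs(median(recovered) - log10(K)), 0.3)
})
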