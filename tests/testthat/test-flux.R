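test_that("zero-rate scheme leaves populations unchanged", {
  sc <- kinetic_scheme(0, 0, 0, 0, t_sim = 1)
  p <- solve_to_equilibrium(sc)
  expect_equal(unname(p), c(1, 0, 0, 0))
})

test_that("populations are conserved along the integration", {
  m <- three_state_model()
  sc <- scheme_from_model(m, k2 = 50)
  p <- solve_to_equilibrium(sc)
  expect_equal(sum(p), 1, tolerance = 1e-8)
  expect_true(all(p >= 0))
})

test_that("exchange-only equilibrium matches the analytic stationary
          distribution", {
  m <- three_state_model()
  sc <- scheme_from_model(m, k2 = 0)
  p <- solve_to_equilibrium(sc)
  # the scheme was built by detailed balance from the model populations,
  # so the stationary distribution is those populations with p_MIS = 0
  expect_equal(p[["GS"]], m$populations[["GS"]], tolerance = 1e-7)
  expect_equal(p[["ES1"]], m$populations[["ES1"]], tolerance = 1e-7)
  expect_equal(p[["ES2"]], m$populations[["ES2"]], tolerance = 1e-7)
  expect_equal(p[["MIS"]], 0, tolerance = 1e-10)
})

test_that("decoupled pathways: no minor exchange means no mixed flux", {
  sc <- kinetic_scheme(6, 7000, 0.8, 1e4, 0, 0, k2 = 100)
  fl <- pathway_fluxes(sc)
  expect_equal(fl[["F_ta"]], 0)
  expect_equal(fl[["F_at"]], 0)
  res <- relative_flux(sc)
  expect_equal(res$F_T, fl[["F_tt"]])
  expect_equal(res$F_A, fl[["F_aa"]])
})

test_that("fully symmetric pathways split the flux 50/50", {
  sc <- kinetic_scheme(5, 5000, 5, 5000, 800, 800, k2 = 200)
  expect_equal(relative_flux(sc)$f_A, 50, tolerance = 1e-9)
  expect_equal(relative_flux(sc)$f_T + relative_flux(sc)$f_A, 100,
               tolerance = 1e-9)
})

test_that("k2 limits recover the thermodynamic and kinetic formulas", {
  m <- three_state_model()
  # no-minor scheme for the kinetic limit law
  K <- microscopic_rates(m)
  sc <- kinetic_scheme(K["GS", "ES1"], K["ES1", "GS"],
                       K["GS", "ES2"], K["ES2", "GS"], 0, 0)
  lim <- flux_limits(sc)
  sweep <- k2_sweep(sc, 10^seq(-3, 8, length.out = 23))
  expect_equal(sweep$f_A[1], lim[["thermodynamic"]],
               tolerance = 0.01 * lim[["thermodynamic"]])
  expect_equal(sweep$f_A[nrow(sweep)], lim[["kinetic"]],
               tolerance = 0.01 * lim[["kinetic"]])
  # monotone transition between the limits
  expect_true(all(diff(sweep$f_A) > -1e-9))
})

test_that("k2 -> 0 flux partition equals the population ratio with minor
          exchange present", {
  sc <- scheme_from_model(three_state_model(), k2 = 0)
  p <- solve_to_equilibrium(sc)
  fa0 <- relative_flux(sc, k2 = 1e-4)$f_A
  expect_equal(fa0, 100 * p[["ES2"]] / (p[["ES1"]] + p[["ES2"]]),
               tolerance = 0.05)
})

test_that("dG.rU flux partition sits in the published band at k2 = 100", {
  sc <- scheme_from_model(three_state_model(), k2 = 100)
  fa <- relative_flux(sc)$f_A
  expect_gt(fa, 35)
  expect_lt(fa, 45)
})

test_that("flux algebra agrees with a Gillespie first-passage oracle", {
  set.seed(17)
  sc_gu <- scheme_from_model(three_state_model())
  # the serial/parallel composition is a near-equilibrium approximation:
  # it tracks the exact first-passage partition closely up to k2 of a few
  # hundred 1/s (the polymerase-relevant range) and drifts beyond it
  for (k2 in c(20, 100, 300)) {
    fa_alg <- relative_flux(sc_gu, k2 = k2)$f_A
    fa_sim <- gillespie_fa(sc_gu, k2, n_absorb = 3000)
    expect_lt(abs(fa_alg - fa_sim), 2)
  }
  # and for a no-minor-exchange scheme
  sc_nm <- kinetic_scheme(6, 7190, 0.8, 1e4, 0, 0)
  fa_alg <- relative_flux(sc_nm, k2 = 100)$f_A
  fa_sim <- gillespie_fa(sc_nm, 100, n_absorb = 3000)
  expect_lt(abs(fa_alg - fa_sim), 2)
})

test_that("results are stable under ODE tolerance refinement", {
  sc <- scheme_from_model(three_state_model(), k2 = 100)
  p1 <- solve_to_equilibrium(sc, k2 = 0, k_minus2 = 0)
  fa1 <- relative_flux(sc, populations = p1)$f_A
  # re-solve with a shorter horizon (equilibrium is reached in ~5 ms)
  p2 <- solve_to_equilibrium(sc, t_sim = 1, k2 = 0, k_minus2 = 0)
  fa2 <- relative_flux(sc, populations = p2)$f_A
  expect_lt(abs(fa1 - fa2), 0.01)
})

test_that("binding step barely changes the flux partition", {
  sc <- scheme_from_model(three_state_model(), k2 = 100)
  fa_simple <- relative_flux(sc)$f_A
  full <- with_binding(sc, k_on = 500, k_off = 200)
  p5 <- solve_to_equilibrium(full, k2 = 0, k_minus2 = 0)
  expect_equal(sum(p5), 1, tolerance = 1e-8)
  fa_full <- relative_flux(full, populations = p5)$f_A
  expect_lt(abs(fa_full - fa_simple), 1)
  # very fast binding converges to the simplified model
  fast <- with_binding(sc, k_on = 1e6, k_off = 1)
  fa_fast <- relative_flux(fast,
                           populations = solve_to_equilibrium(
                             fast, k2 = 0, k_minus2 = 0))$f_A
  expect_equal(fa_fast, fa_simple, tolerance = 0.01)
})

test_that("degenerate flux inputs are handled", {
  sc <- kinetic_scheme(0, 0, 0, 0, k2 = 100)
  expect_error(relative_flux(sc), "undefined")
  expect_error(kinetic_scheme(-1, 0, 0, 0), "non-negative")
  expect_error(with_binding(kinetic_scheme(1, 1, 1, 1), 0, 5), "positive")
})
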