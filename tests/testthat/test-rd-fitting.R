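# Shared fixtures for the fitting tests: one small noisy 2-state dataset
# (both nuclei) and its 2-state fit, reused across blocks to keep the
# suite fast.
rd_truth <- duplex_model("dT.rG", 7.4)
rd_noisy <- simulate_rd_dataset(rd_truth, grid = small_grid(), seed = 101,
                                n_mc = 60)
rd_fit2 <- bmfit(rd_noisy, nstates = 2, n_starts = 3)

test_that("noiseless data refit recovers the generating parameters
          essentially exactly", {
  ds0 <- simulate_rd_dataset(rd_truth, grid = small_grid(), noise = 0)
  fit <- bmfit(ds0, nstates = 2, n_starts = 3)
  cf <- coef(fit)
  expect_equal(cf[["p_ES1"]], 8.3e-4, tolerance = 1e-3)
  expect_equal(cf[["kex_GS_ES1"]], 7200, tolerance = 1e-3)
  expect_equal(cf[["dw_ES1_G-N1"]], 34.9, tolerance = 1e-3)
  expect_equal(cf[["dw_ES1_T-N3"]], 25.7, tolerance = 1e-3)
  expect_equal(cf[["r2_G-N1"]], 14, tolerance = 1e-3)
})

test_that("noisy 2-state recovery stays within the published parameter
          uncertainties", {
  cf <- coef(rd_fit2)
  expect_equal(cf[["p_ES1"]], 8.3e-4, tolerance = 0.15)
  expect_equal(cf[["kex_GS_ES1"]], 7200, tolerance = 0.15)
  expect_true(rd_fit2$converged)
})

test_that("the 3-state fit dominates the 2-state fit and collapses onto
          it on noiseless 2-state data", {
  fit3 <- bmfit(rd_noisy, nstates = 3, n_starts = 3)
  # nested-model dominance on noisy data
  expect_lte(fit3$chi2, rd_fit2$chi2 + 1e-3 * rd_fit2$chi2)
  # collapse identity: with a 2-state generator and no noise both models
  # reach an essentially perfect fit (compared in rate units)
  ds0 <- simulate_rd_dataset(rd_truth, grid = small_grid(), noise = 0)
  ds0$r1rho_sd <- rep(1, nrow(ds0))
  c2 <- bmfit(ds0, nstates = 2, n_starts = 2)$chi2
  c3 <- bmfit(ds0, nstates = 3, n_starts = 2)$chi2
  expect_lt(c2, 1e-6)
  expect_lt(c3, 1e-6)
})

test_that("an undetectably small anion is not claimed from 2-state data", {
  # dT.rG at pH 7.4: the generator has no anionic state, mirroring its
  # population falling below the experiment's detection limit.  On the
  # full acquisition grid a 3-state fit should not be supported by BIC,
  # and the spurious second state it fits should carry a population well
  # below the tautomer's.
  ds <- simulate_rd_dataset(rd_truth, seed = 42)
  f2 <- bmfit(ds, nstates = 2, n_starts = 3)
  f3 <- bmfit(ds, nstates = 3, n_starts = 4)
  w <- model_weights(f2, f3)
  expect_gt(w$bic_weight[w$model == "2-state"], 0.5)
  expect_lt(coef(f3)[["p_ES2"]], 1e-3)
})

test_that("fit is invariant to record ordering", {
  perm <- sample(nrow(rd_noisy))
  ds_perm <- rd_noisy[perm, ]
  fit_perm <- bmfit(ds_perm, nstates = 2, n_starts = 3)
  expect_equal(fit_perm$chi2, rd_fit2$chi2, tolerance = 1e-6)
  nm <- names(coef(rd_fit2))
  expect_equal(coef(fit_perm)[nm], coef(rd_fit2), tolerance = 1e-4)
})

test_that("Monte Carlo uncertainties vanish with the observed errors and
          scale linearly with them", {
  # tiny observed errors -> tiny parameter errors
  ds0 <- simulate_rd_dataset(rd_truth, nuclei = "G-N1",
                             grid = small_grid(), noise = 0)
  fit0 <- bmfit(ds0, nstates = 2, n_starts = 2)
  fit0 <- monte_carlo_uncertainty(fit0, n_iter = 30, seed = 1)
  expect_lt(fit0$sd[["p_ES1"]] / coef(fit0)[["p_ES1"]], 1e-2)
  # doubling the observed errors roughly doubles the parameter errors
  ds1 <- simulate_rd_dataset(rd_truth, nuclei = "G-N1",
                             grid = small_grid(), seed = 7, n_mc = 60)
  f1 <- bmfit(ds1, nstates = 2, n_starts = 2)
  f1 <- monte_carlo_uncertainty(f1, n_iter = 200, seed = 2)
  ds2 <- ds1
  ds2$r1rho_sd <- 2 * ds1$r1rho_sd
  f2 <- bmfit(ds2, nstates = 2, n_starts = 2)
  f2 <- monte_carlo_uncertainty(f2, n_iter = 200, seed = 2)
  # linear response holds for the well-conditioned parameters; the
  # population of a single-nucleus fit leaves the linear regime once the
  # errors are large enough for refits to wander between near-degenerate
  # solutions
  for (nm in c("dw_ES1_G-N1", "r1_G-N1")) {
    ratio <- f2$sd[[nm]] / f1$sd[[nm]]
    expect_gt(ratio, 1.4)
    expect_lt(ratio, 2.6)
  }
})

test_that("degenerate Monte Carlo settings are flagged", {
  expect_warning(monte_carlo_uncertainty(rd_fit2, n_iter = 1),
                 "degenerate")
})

test_that("information-criterion weights behave as probabilities", {
  refit <- bmfit(rd_noisy, nstates = 2, n_starts = 3)
  w <- model_weights(rd_fit2, refit, labels = c("a", "b"))
  expect_equal(w$akaike_weight, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(w$bic_weight), 1, tolerance = 1e-12)
  # different data are refused
  other <- simulate_rd_dataset(rd_truth, grid = small_grid(), seed = 999,
                               n_mc = 20)
  fit_other <- bmfit(other, nstates = 2, n_starts = 2)
  expect_error(model_weights(rd_fit2, fit_other), "identical dataset")
})

test_that("model selection identifies the generating model", {
  # 2-state data: the 2-state model should win the Akaike comparison in
  # the large majority of replicates
  g <- default_grid(powers = c(600, 1200, 2000), n_offsets = 11)
  wins <- 0L
  n_rep <- 12L
  for (s in seq_len(n_rep)) {
    ds <- simulate_rd_dataset(rd_truth, nuclei = "G-N1", grid = g,
                              seed = 300 + s, n_mc = 40)
    f2 <- bmfit(ds, nstates = 2, n_starts = 2)
    f3 <- bmfit(ds, nstates = 3, n_starts = 2)
    w <- model_weights(f2, f3)
    wins <- wins + (w$akaike_weight[w$model == "2-state"] > 0.5)
  }
  expect_gte(wins / n_rep, 0.75)
  # 3-state data from the dG.rU parameters: the anion is detectable and
  # the 3-state model should win decisively
  truth3 <- duplex_model("dG.rU", 7.4)
  ds3 <- simulate_rd_dataset(truth3, grid = default_grid(
    powers = c(1200, 2000), n_offsets = 11), seed = 77, n_mc = 40)
  f2 <- bmfit(ds3, nstates = 2, n_starts = 2)
  f3 <- bmfit(ds3, nstates = 3, n_starts = 4)
  w <- model_weights(f2, f3)
  expect_gt(w$akaike_weight[w$model == "3-state"], 0.5)
})

test_that("fitted-model methods are mutually consistent", {
  expect_equal(fitted(rd_fit2) + residuals(rd_fit2, "response"),
               rd_fit2$data$r1rho, tolerance = 1e-12)
  expect_equal(deviance(rd_fit2),
               sum(residuals(rd_fit2, "pearson")^2), tolerance = 1e-12)
  pred <- predict(rd_fit2)
  expect_equal(pred, fitted(rd_fit2), tolerance = 1e-12)
  nd <- data.frame(nucleus = "G-N1", power_hz = 1000, offset_hz = 0)
  expect_equal(predict(rd_fit2, nd, type = "r2eff"),
               r2eff_transform(predict(rd_fit2, nd),
                               rd_fit2$model$r1[["G-N1"]], pi / 2),
               tolerance = 1e-9)
  sims <- simulate(rd_fit2, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "rd_dataset")
  expect_identical(nrow(sims[[1]]), nrow(rd_fit2$data))
})

test_that("parameter recovery coverage: truth inside 2 sd for most
          parameters across seeds", {
  g <- default_grid(powers = c(800, 2000), n_offsets = 9)
  true_vals <- c(p_ES1 = 8.3e-4, kex_GS_ES1 = 7200,
                 `dw_ES1_G-N1` = 34.9, `r1_G-N1` = 2, `r2_G-N1` = 14)
  hits <- misses <- 0L
  for (s in 1:10) {
    ds <- simulate_rd_dataset(rd_truth, nuclei = "G-N1", grid = g,
                              seed = 500 + s, n_mc = 40)
    f <- bmfit(ds, nstates = 2, n_starts = 2)
    f <- monte_carlo_uncertainty(f, n_iter = 50, seed = s)
    for (nm in names(true_vals)) {
      ok <- abs(coef(f)[[nm]] - true_vals[[nm]]) <= 2 * f$sd[[nm]]
      if (ok) hits <- hits + 1L else misses <- misses + 1L
    }
  }
  expect_gte(hits / (hits + misses), 0.8)
})
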