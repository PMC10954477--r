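test_that("anion population follows the Henderson-Hasselbalch form", {
  expect_equal(anion_population(9.0, 9.0), 0.5)
  expect_equal(anion_population(10.32, 7.4), 1.2e-3, tolerance = 0.01)
  expect_gt(anion_population(8, 14), 0.999)
  expect_true(anion_population(11, 3) > 0)
})

test_that("rate extrapolation applies the ln-linear fold change", {
  expect_equal(extrapolate_rate(5, 7.4, 7.4), 5)
  expect_equal(extrapolate_rate(1, 7.4, 7.8), 10^0.4, tolerance = 1e-9)
  expect_equal(extrapolate_rate(7, 6, 9, slope = 0), 7)
})

test_that("forward rate from pKa matches the printed kinetics", {
  # dT.rG: kb ~ 1e4, pKa_app 11.5 -> kf ~ 0.79 at pH 7.4
  expect_equal(forward_rate_from_pka(1e4, 8.3e-4, 11.5, 7.4), 0.79,
               tolerance = 0.01)
  expect_equal(forward_rate_from_pka(1e4, 8.3e-4, 20, 7.4), 0,
               tolerance = 1e-6)
  # dG.rU at its measurement pH 7.8: reproduces the fitted ~14 1/s
  m <- duplex_model("dG.rU", 7.8)
  K <- microscopic_rates(m)
  pka <- apparent_pka(7.8, m$populations[["ES2"]],
                      m$populations[["GS"]], m$populations[["ES1"]])
  expect_equal(forward_rate_from_pka(K["ES2", "GS"],
                                     m$populations[["ES1"]], pka, 7.8),
               14, tolerance = 0.1)
})

test_that("population -> apparent pKa -> population is the identity", {
  p1 <- 8.3e-4
  for (ph in c(6.8, 7.4, 7.8, 8.4)) {
    p2 <- anion_population(11.5, ph)
    pka <- apparent_pka(ph, p2, 1 - p1 - p2, p1)
    # fold the tautomer consistently: Eq.-1 pKa differs from the pure
    # two-species pKa by log10(1/(1 - p1 - p2) + ...) ~ 0 at these dilutions
    expect_equal(anion_population(pka, ph), p2, tolerance = 1e-5)
  }
})

test_that("pH retargeting preserves tautomer kinetics and detailed balance", {
  m78 <- duplex_model("dG.rU", 7.8)
  m74 <- model_at_ph(m78, 7.4, pka_app = 10.32)
  expect_equal(m74$kex[["GS:ES1"]], m78$kex[["GS:ES1"]])
  expect_equal(m74$populations[["ES1"]], m78$populations[["ES1"]])
  # backward anion rate unchanged
  expect_equal(microscopic_rates(m74)["ES2", "GS"],
               microscopic_rates(m78)["ES2", "GS"], tolerance = 1e-9)
  expect_equal(m74$populations[["ES2"]], anion_population(10.32, 7.4),
               tolerance = 1e-12)
})

test_that("2-state model gains an anionic state on retargeting", {
  m <- duplex_model("dT.rG", 7.4)
  m2 <- model_at_ph(m, 7.4, pka_app = 11.5, ph_from = 7.8,
                    k_backward = 1e4, dw_es2 = c("G-N1" = 1, "T-N3" = 58))
  expect_length(m2$states, 3)
  expect_equal(m2$populations[["ES2"]], anion_population(11.5, 7.4),
               tolerance = 1e-12)
  expect_equal(microscopic_rates(m2)["GS", "ES2"], 0.79, tolerance = 0.01)
})

test_that("slope and pKa extrapolation routes agree on the flux profile", {
  # dT.rG: anion measured at pH 7.8, retargeted to 7.4 both ways
  m78 <- duplex_model("dT.rG", 7.8)
  pka <- apparent_pka(7.8, m78$populations[["ES2"]],
                      m78$populations[["GS"]], m78$populations[["ES1"]])
  m_pka <- model_at_ph(m78, 7.4, pka_app = pka, method = "pka")
  m_slope <- model_at_ph(m78, 7.4, method = "slope")
  k2g <- 10^seq(1, 4, length.out = 7)
  fa_pka <- k2_sweep(scheme_from_model(m_pka, k2 = 100), k2g)$f_A
  fa_slope <- k2_sweep(scheme_from_model(m_slope, k2 = 100), k2g)$f_A
  expect_lt(max(abs(fa_pka - fa_slope)), 5)
})
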