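test_that("no-exchange model reduces to R1 cos2 + R2 sin2", {
  m <- exchange_model(c(0.999, 0.001), 1500, c(N = 0), r1 = 2, r2 = 14)
  cond <- spinlock_condition(1000, 500)
  th <- tilt_angle(cond)
  closed <- 2 * cos(th)^2 + 14 * sin(th)^2
  # exact up to the O(((R2 - R1)/omega_eff)^2) relaxation-anisotropy wobble
  expect_equal(r1rho_bm(m, cond, "N"), closed, tolerance = 1e-4)
  # end-to-end: flat R2+Rex profile equal to R2 at every offset
  offs <- seq(-3000, 3000, length.out = 7)
  r <- r1rho_profile(m, "N", rep(1000, 7), offs)
  r2eff <- r2eff_transform(r, 2, tilt_angle(rep(1000, 7), offs))
  expect_equal(r2eff, rep(14, 7), tolerance = 1e-6)
})

test_that("exchange part of the evolution matrix conserves magnetization", {
  set.seed(42)
  cond <- spinlock_condition(800, 300)
  for (ns in c(2, 3)) {
    m <- random_model(ns)
    # isolate the exchange coupling by differencing against the same model
    # with all exchange switched off
    still <- exchange_model(m$populations, m$kex * 0, m$dw,
                            r1 = m$r1, r2 = m$r2)
    X <- build_bm_matrix(m, cond, "N") - build_bm_matrix(still, cond, "N")
    n <- length(m$states)
    for (ax in 1:3) {
      idx <- 3 * (seq_len(n) - 1) + ax
      expect_equal(colSums(X[idx, idx, drop = FALSE]), rep(0, n),
                   tolerance = 1e-9, ignore_attr = TRUE)
      # and the exchange coupling acts identically on each axis
      expect_equal(X[idx, idx], X[1:n * 3, 1:n * 3], tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("off-diagonal exchange blocks carry kf and kb", {
  m <- two_state_model(p_es = 8.3e-4, kex = 7200)
  A <- build_bm_matrix(m, spinlock_condition(1000, 0), "G-N1")
  kf <- 8.3e-4 * 7200
  kb <- (1 - 8.3e-4) * 7200
  for (ax in 1:3) {
    expect_equal(A[3 + ax, ax], kf, tolerance = 1e-10)
    expect_equal(A[ax, 3 + ax], kb, tolerance = 1e-10)
  }
})

test_that("matrix-exponential propagation matches an ODE integrator", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (rep in 1:4) {
    m <- random_model(sample(2:3, 1))
    cond <- spinlock_condition(stats::runif(1, 400, 2000),
                               stats::runif(1, -4000, 4000))
    A <- build_bm_matrix(m, cond, "N")
    m0 <- initial_magnetization(m, cond, "N")
    sol <- deSolve::lsoda(as.numeric(m0), c(0, cond$delays),
                          function(t, y, p) list(as.numeric(A %*% y)),
                          NULL, rtol = 1e-10, atol = 1e-13,
                          maxsteps = 5e5)
    detect <- rep(attr(m0, "axis"), length(m$states))
    ode_I <- as.numeric(sol[-1, -1] %*% detect)
    sim <- simulate_decay(m, cond, "N")
    expect_equal(sim$intensities, ode_I, tolerance = 1e-8)
  }
})

test_that("initial magnetization follows populations and alignment rules", {
  # single excited state with zero population: unit vector along (sin, 0, cos)
  m <- exchange_model(c(1, 0), 1000, c(N = 10))
  cond <- spinlock_condition(1000, 500)
  m0 <- initial_magnetization(m, cond, "N")
  th <- tilt_angle(cond)
  expect_equal(as.numeric(m0)[1:3], c(sin(th), 0, cos(th)),
               tolerance = 1e-12)
  # equilibrated populations: GS block carries p_GS of the total magnitude
  m <- two_state_model(p_es = 8.3e-4)
  m0 <- initial_magnetization(m, cond, "G-N1")
  mag <- vapply(1:2, function(i)
    sqrt(sum(as.numeric(m0)[3 * (i - 1) + (1:3)]^2)), numeric(1))
  expect_equal(mag[1] / sum(mag), 1 - 8.3e-4, tolerance = 1e-9)
  # fast exchange (kex/|dw| large) switches to average-field alignment
  fast <- exchange_model(c(0.98, 0.02), 5e5, c(N = 1))
  expect_identical(attr(initial_magnetization(fast, cond, "N"),
                        "alignment"), "average")
  slow <- exchange_model(c(0.98, 0.02), 500, c(N = 30))
  expect_identical(attr(initial_magnetization(slow, cond, "N"),
                        "alignment"), "gs")
})

test_that("decay curves start at the initial magnitude and follow the
          closed form without exchange", {
  m <- exchange_model(c(0.999, 0.001), 2000, c(N = 0), r1 = 1.5, r2 = 12)
  cond <- spinlock_condition(800, -600, delays = c(0, 0.03, 0.06, 0.12))
  sim <- simulate_decay(m, cond, "N")
  expect_equal(sim$intensities[1], 1, tolerance = 1e-9)
  th <- tilt_angle(cond)
  rate <- 1.5 * cos(th)^2 + 12 * sin(th)^2
  expect_equal(sim$intensities, exp(-rate * cond$delays), tolerance = 1e-6)
})

test_that("on-resonance R2+Rex decreases monotonically with power", {
  m <- two_state_model()
  powers <- seq(400, 2000, by = 400)
  r <- r1rho_profile(m, "G-N1", powers, rep(0, length(powers)))
  r2eff <- r2eff_transform(r, m$r1[["G-N1"]],
                           tilt_angle(powers, rep(0, length(powers))))
  expect_true(all(diff(r2eff) < 0))
})

test_that("dispersion peak sits near -dw, approaching -dw in slow exchange", {
  larmor <- 70.95
  offs <- seq(-45, -25, by = 0.5) * larmor
  # slow exchange: kex << |dw|
  slow <- exchange_model(c(1 - 1e-3, 1e-3), 500, c(N = 34.9))
  r <- r1rho_profile(slow, "N", rep(600, length(offs)), offs)
  r2eff <- r2eff_transform(r, 2, tilt_angle(rep(600, length(offs)), offs))
  peak_ppm <- offs[which.max(r2eff)] / larmor
  expect_equal(peak_ppm, -34.9, tolerance = 0.02)
})

test_that("fast-exchange closed form agrees with the full simulation", {
  larmor <- 70.95
  dw_ppm <- 2
  dw_rad <- dw_ppm * 2 * pi * larmor
  kex <- 20 * dw_rad
  p_es <- 0.02
  m <- exchange_model(c(1 - p_es, p_es), kex, c(N = dw_ppm),
                      r1 = 2, r2 = 14)
  for (off in c(-400, 0, 300)) {
    r <- r1rho_profile(m, "N", 1000, off)
    # population-average frame
    om_avg <- 2 * pi * off + p_es * dw_rad
    th <- atan2(2 * pi * 1000, om_avg)
    om_eff <- sqrt((2 * pi * 1000)^2 + om_avg^2)
    rex_sim <- r2eff_transform(r, 2, th) - 14
    rex_cf <- rex_fast_exchange(1 - p_es, p_es, dw_rad, kex, om_eff)
    expect_equal(rex_sim, rex_cf, tolerance = 0.05 * rex_cf)
  }
})

test_that("compiled grid path reproduces the reference implementation", {
  for (mk in list(two_state_model(), three_state_model())) {
    g <- small_grid()
    nuc <- mk$nuclei[1]
    expect_equal(
      r1rho_profile(mk, nuc, g$power_hz, g$offset_hz, engine = "cpp"),
      r1rho_profile(mk, nuc, g$power_hz, g$offset_hz, engine = "r"),
      tolerance = 1e-10)
  }
})

test_that("r2eff transform is exact and guards the poles", {
  expect_equal(r2eff_transform(20, 2, pi / 3), (20 - 2 * 0.25) / 0.75)
  expect_equal(r2eff_transform(20, 2, pi / 3), 26)
  expect_equal(r2eff_transform(17, 5, pi / 2), 17)
  expect_error(r2eff_transform(20, 2, 0), "undefined")
  expect_error(r2eff_transform(20, 2, pi), "undefined")
  out <- r2eff_transform(20, 2, pi / 3, sd = 0.3)
  expect_equal(out[, "sd"], 0.3 / sin(pi / 3)^2, ignore_attr = TRUE)
})

test_that("fast-exchange Rex vanishes without shift difference or population", {
  expect_equal(rex_fast_exchange(0.99, 0.01, 0, 1e4, 5e3), 0)
  expect_equal(rex_fast_exchange(1, 0, 1e4, 1e4, 5e3), 0)
})

test_that("spin-lock condition validation and tilt-angle range", {
  expect_error(spinlock_condition(-100, 0), "positive")
  expect_error(spinlock_condition(100, 0, delays = 0.1), "two")
  th <- vapply(c(-5000, -1, 0, 1, 5000), function(o)
    tilt_angle(spinlock_condition(400, o)), numeric(1))
  expect_true(all(th > 0 & th < pi))
})
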