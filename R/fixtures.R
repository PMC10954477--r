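# Synthetic-data generators: ground-truth exchange models for the two
# RNA:DNA hybrid duplexes, noisy R1rho datasets over the standard
# acquisition grid, and noisy chemical-shift titration series.

# Published central fit values for the two hybrids.  dT.rG at pH 7.4 is a
# 2-state (tautomer-only) system: the anion falls below detection there.
# At pH 7.8 the anionic ES2 becomes observable in both duplexes; its
# backward rate follows from the forward rate and population.  The anionic
# 15N shifts for dT.rG were not determined experimentally; the fixture
# reuses the dG.rU anion shifts as a synthetic stand-in (the flux and
# extrapolation layers never use them).
.duplex_registry <- function() {
  anion_dw <- function(g, n3) c(g, n3)
  list(
    "dT.rG" = list(
      "7.4" = list(
        p = c(GS = 1 - 8.3e-4, ES1 = 8.3e-4), kex = 7200,
        dw = matrix(c(34.9, 25.7), ncol = 1,
                    dimnames = list(c("G-N1", "T-N3"), NULL))),
      "7.8" = local({
        p1 <- 8.3e-4; p2 <- 2e-4; kf2 <- 2
        kb2 <- kf2 * (1 - p1 - p2) / p2
        list(p = c(GS = 1 - p1 - p2, ES1 = p1, ES2 = p2),
             kex = c(7200, kf2 + kb2, 0),
             dw = matrix(c(34.9, 25.7, anion_dw(1, 58)), ncol = 2,
                         dimnames = list(c("G-N1", "T-N3"), NULL)))
      })),
    "dG.rU" = list(
      "7.4" = list(
        p = c(GS = 1 - 1.9e-3 - 1.2e-3, ES1 = 1.9e-3, ES2 = 1.2e-3),
        kex = c(4000, 5000, 13000),
        dw = matrix(c(21, 36, anion_dw(1, 58)), ncol = 2,
                    dimnames = list(c("G-N1", "U-N3"), NULL))),
      "7.8" = local({
        p1 <- 1.9e-3; p2 <- 3e-3; kf2 <- 14
        kb2 <- kf2 * (1 - p1 - p2) / p2
        list(p = c(GS = 1 - p1 - p2, ES1 = p1, ES2 = p2),
             kex = c(4000, kf2 + kb2, 13000),
             dw = matrix(c(21, 36, anion_dw(1, 58)), ncol = 2,
                         dimnames = list(c("G-N1", "U-N3"), NULL)))
      })))
}

#' Ground-truth exchange model for a duplex context
#'
#' Returns the tabulated central exchange parameters for the dT.rG or dG.rU
#' RNA:DNA hybrid at pH 7.4 or 7.8 as an [exchange_model()]: a 2-state
#' tautomer-only model for dT.rG at pH 7.4 (the anionic state is below the
#' detection limit there) and 3-state triangular models otherwise.
#' Relaxation rates default to R1 = 2, R2 = 14 1/s, typical of imino 15N in
#' a dodecamer duplex at 700 MHz.
#'
#' @param duplex `"dT.rG"` or `"dG.rU"`.
#' @param ph 7.4 or 7.8.
#' @param dw_scale scale factor on all chemical-shift differences
#'   (0 gives a no-dispersion control model).
#' @param r1,r2,larmor_mhz passed to [exchange_model()].
#' @return An [exchange_model()] with attributes `duplex` and `ph`.
#' @export
duplex_model <- function(duplex = c("dT.rG", "dG.rU"), ph = 7.4,
                         dw_scale = 1, r1 = 2, r2 = 14, larmor_mhz = 70.95) {
  duplex <- match.arg(duplex)
  reg <- .duplex_registry()[[duplex]]
  key <- sprintf("%.1f", ph)
  if (!key %in% names(reg))
    stop(sprintf("no tabulated parameters for %s at pH %s", duplex, key),
         call. = FALSE)
  par <- reg[[key]]
  m <- exchange_model(par$p, par$kex, par$dw * dw_scale,
                      r1 = r1, r2 = r2, larmor_mhz = larmor_mhz)
  attr(m, "duplex") <- duplex
  attr(m, "ph") <- ph
  m
}

#' Standard acquisition grid
#'
#' The spin-lock power / offset grid emulating the acquisition ranges of
#' off-resonance 15N R1rho experiments: powers between 400 and 2000 Hz with
#' offsets spanning +/- `offset_span` times each power, and 3-4 relaxation
#' delays up to 120 ms.
#'
#' @param powers spin-lock powers in Hz.
#' @param n_offsets number of offsets per power (evenly spaced).
#' @param offset_span half-width of the offset range in units of the power.
#' @param delays relaxation delays in seconds.
#' @return Data frame with columns `power_hz`, `offset_hz` and attribute
#'   `delays`.
#' @export
default_grid <- function(powers = c(400, 800, 1200, 1600, 2000),
                         n_offsets = 13, offset_span = 3.5,
                         delays = c(0, 0.04, 0.08, 0.12)) {
  g <- do.call(rbind, lapply(powers, function(w) {
    data.frame(power_hz = w,
               offset_hz = seq(-offset_span * w, offset_span * w,
                               length.out = n_offsets))
  }))
  structure(g, delays = sort(delays))
}

#' Simulate a noisy relaxation-dispersion dataset
#'
#' Full forward emulation of the experiment: for every nucleus and grid
#' condition a decay curve is simulated from the ground-truth model,
#' Gaussian intensity noise of standard deviation `noise` (in units of the
#' t = 0 intensity) is added, and R1rho with its Monte Carlo uncertainty is
#' extracted by [fit_monoexp()] exactly as for measured data.  The
#' generating model is stored in the `truth` attribute for recovery tests.
#'
#' @param model ground-truth [exchange_model()], e.g. from [duplex_model()].
#' @param nuclei nuclei to simulate (default: all in the model).
#' @param grid acquisition grid from [default_grid()].
#' @param noise fractional intensity noise (default 0.015).
#' @param n_mc Monte Carlo resamples per curve for the R1rho uncertainty.
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return An [rd_dataset()] with attributes `truth`, `noise` and `seed`.
#' @export
simulate_rd_dataset <- function(model, nuclei = model$nuclei,
                                grid = default_grid(), noise = 0.015,
                                n_mc = 100, seed = NULL) {
  delays <- attr(grid, "delays") %||% c(0, 0.04, 0.08, 0.12)
  out <- with_seed(seed, {
    do.call(rbind, lapply(nuclei, function(nuc) {
      r <- vapply(seq_len(nrow(grid)), function(i) {
        cond <- spinlock_condition(grid$power_hz[i], grid$offset_hz[i],
                                   delays, model$larmor_mhz)
        curve <- simulate_decay(model, cond, nuc, noise_sd = noise)
        if (noise == 0) {
          est <- .monoexp_rate(curve$delays, curve$intensities)
          return(c(est, 1e-6))
        }
        # tolerant reduction: rapidly decaying conditions can draw a
        # non-positive late-delay intensity, which the core fitter simply
        # leaves out (as an analyst would discard a point below the
        # noise floor)
        est <- .monoexp_rate(curve$delays, curve$intensities,
                             want_i0 = TRUE)
        mu <- est[2] * exp(-est[1] * curve$delays)
        draws <- vapply(seq_len(n_mc), function(j)
          .monoexp_rate(curve$delays,
                        mu + stats::rnorm(length(mu), 0, noise)),
          numeric(1))
        c(est[1], stats::sd(draws[is.finite(draws)]))
      }, numeric(2))
      data.frame(nucleus = nuc, power_hz = grid$power_hz,
                 offset_hz = grid$offset_hz, r1rho = r[1, ],
                 r1rho_sd = r[2, ])
    }))
  })
  ds <- rd_dataset(out$nucleus, out$power_hz, out$offset_hz, out$r1rho,
                   out$r1rho_sd, larmor_mhz = model$larmor_mhz,
                   delays = delays, duplex = attr(model, "duplex"),
                   ph = attr(model, "ph"))
  attr(ds, "truth") <- model
  attr(ds, "noise") <- noise
  attr(ds, "seed") <- seed
  ds
}

#' Measured pH grids of the nucleotide titrations
#'
#' The pH series at which the rUTP and dTTP N3/C4 chemical-shift titrations
#' were recorded.
#' @return Numeric vector of pH values.
#' @export
ph_grid_rutp <- function() {
  c(6.92, 7.41, 8.0, 8.13, 8.15, 8.22, 8.24, 8.27, 8.42, 8.78, 8.87,
    9.10, 9.20, 9.48, 9.93, 10.4, 11.2, 12.9, 13.5)
}

#' @rdname ph_grid_rutp
#' @export
ph_grid_dttp <- function() {
  c(6.89, 7.40, 8.08, 8.39, 8.62, 9.65, 9.81, 10.3, 10.8, 11.1, 11.5,
    11.8, 12.0, 12.9, 13.6)
}

#' Simulate a noisy chemical-shift titration
#'
#' Generates 13C and 15N chemical shifts over a pH grid from a
#' Henderson-Hasselbalch transition with the given pKa and per-nucleus
#' deprotonation shift changes, adds Gaussian noise to each shift, and
#' returns a [titration_series()].  Shift changes default to values typical
#' of pyrimidine N3 deprotonation (large downfield 15N shift, smaller 13C
#' carbonyl shift).
#'
#' @param pka transition pKa.
#' @param ph pH grid (default: the rUTP grid).
#' @param dd_13c,dd_15n total 13C / 15N shift change on deprotonation, ppm.
#' @param noise_sd Gaussian noise per shift, ppm (default 0.01).
#' @param seed optional RNG seed.
#' @return A [titration_series()].
#' @export
simulate_titration <- function(pka, ph = ph_grid_rutp(), dd_13c = 3,
                               dd_15n = 12, noise_sd = 0.01, seed = NULL) {
  frac <- 10^(ph - pka) / (1 + 10^(ph - pka))  # deprotonated fraction
  with_seed(seed, {
    s13 <- dd_13c * frac + stats::rnorm(length(ph), 0, noise_sd)
    s15 <- dd_15n * frac + stats::rnorm(length(ph), 0, noise_sd)
    titration_series(ph, s13, s15)
  })
}
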