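# Bloch-McConnell forward model (reference R implementation).
#
# Magnetization is ordered in per-state blocks (Mx, My, Mz).  The rotating
# frame is that of the applied RF field; state i precesses at
# Omega_i = 2*pi*offset_hz + dw_i (rad/s), where offset_hz is the carrier
# offset from the GS resonance, so the GS sits at +offset and an excited
# state with positive dw resonates further downfield (its dispersion peak
# appears at offset = -dw).  Relaxation decays toward zero: for spin-lock
# periods of at most ~120 ms the thermal-recovery term is negligible and R1
# is a fitted parameter, so the homogeneous form is used throughout.

# per-state offsets in rad/s for one nucleus
.state_offsets <- function(model, cond, nucleus) {
  if (!nucleus %in% model$nuclei)
    stop(sprintf("nucleus '%s' has no chemical-shift entry in the model",
                 nucleus), call. = FALSE)
  dw_rad <- c(0, model$dw[nucleus, ]) * 2 * pi * cond$larmor_mhz
  2 * pi * cond$offset_hz + dw_rad
}

#' Bloch-McConnell evolution matrix
#'
#' Builds the homogeneous rotating-frame generator for n-site exchange under
#' an off-resonance spin lock applied along x: per-state precession about z
#' at the state offset, nutation about x at \eqn{\omega_1}, transverse (R2)
#' and longitudinal (R1) relaxation decaying to zero, and per-axis exchange
#' coupling with microscopic rates from [microscopic_rates()].
#'
#' @param model an [exchange_model()].
#' @param cond a [spinlock_condition()].
#' @param nucleus nucleus label (a rowname of `model$dw`).
#' @return A 3n x 3n matrix, states in blocks of (Mx, My, Mz).
#' @export
build_bm_matrix <- function(model, cond, nucleus) {
  stopifnot(inherits(model, "exchange_model"),
            inherits(cond, "spinlock_condition"))
  Om <- .state_offsets(model, cond, nucleus)
  n <- length(Om)
  om1 <- 2 * pi * cond$power_hz
  r1 <- model$r1[[nucleus]]; r2 <- model$r2[[nucleus]]
  K <- microscopic_rates(model)
  A <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    o <- 3 * (i - 1)
    A[o + 1, o + 1] <- -r2; A[o + 2, o + 2] <- -r2; A[o + 3, o + 3] <- -r1
    A[o + 1, o + 2] <- -Om[i]; A[o + 2, o + 1] <- Om[i]
    A[o + 2, o + 3] <- -om1;   A[o + 3, o + 2] <- om1
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || K[i, j] <= 0) next
    for (ax in 1:3) {
      A[3 * (i - 1) + ax, 3 * (i - 1) + ax] <-
        A[3 * (i - 1) + ax, 3 * (i - 1) + ax] - K[i, j]
      A[3 * (j - 1) + ax, 3 * (i - 1) + ax] <-
        A[3 * (j - 1) + ax, 3 * (i - 1) + ax] + K[i, j]
    }
  }
  A
}

# Should the initial magnetization be aligned along the population-average
# effective field (fast exchange) or the GS effective field (slow exchange)?
# Decided by the kex/|dw| ratio of the majorly populated ES.
.use_average_alignment <- function(model, nucleus, threshold = 5) {
  if (length(model$states) == 2L) {
    major <- "ES1"
  } else {
    major <- if (model$populations[["ES2"]] > model$populations[["ES1"]])
      "ES2" else "ES1"
  }
  kex <- model$kex[[paste0("GS:", major)]]
  dw_rad <- abs(model$dw[nucleus, major]) * 2 * pi * model$larmor_mhz
  if (dw_rad == 0) return(TRUE)
  kex / dw_rad > threshold
}

#' Initial magnetization for a spin-lock period
#'
#' The 5 ms equilibration element of the experiment is modeled by assuming
#' the magnetization is distributed across states according to their
#' equilibrium populations, all aligned along a common axis in the x-z plane.
#' The axis is the GS effective field when the majorly populated excited
#' state is in slow exchange (\eqn{k_{ex}/|\Delta\omega|} below
#' `alignment_threshold`), and the population-average effective field
#' otherwise.
#'
#' @inheritParams build_bm_matrix
#' @param alignment_threshold dimensionless cutoff on
#'   \eqn{k_{ex}/|\Delta\omega|} of the major excited state (default 5).
#' @return Numeric vector of length 3n with attributes `axis` (the shared
#'   unit alignment vector), `theta` (its tilt angle) and `alignment`
#'   (`"gs"` or `"average"`).
#' @export
initial_magnetization <- function(model, cond, nucleus,
                                  alignment_threshold = 5) {
  Om <- .state_offsets(model, cond, nucleus)
  p <- model$populations
  avg <- .use_average_alignment(model, nucleus, alignment_threshold)
  Om_align <- if (avg) sum(p * Om) else Om[1]
  theta <- atan2(2 * pi * cond$power_hz, Om_align)
  axis <- c(sin(theta), 0, cos(theta))
  m0 <- as.numeric(vapply(p, function(pi) pi * axis, numeric(3)))
  structure(m0, axis = axis, theta = theta,
            alignment = if (avg) "average" else "gs")
}

# exp(A t) %*% v via eigendecomposition, with a scaling-and-squaring
# fallback for (numerically) defective generators
.propagate <- function(A, v, times) {
  e <- tryCatch(eigen(A), error = function(e) NULL)
  if (!is.null(e) && is.finite(rcond(e$vectors)) && rcond(e$vectors) > 1e-13) {
    c0 <- solve(e$vectors, v)
    vapply(times, function(t) Re(e$vectors %*% (c0 * exp(e$values * t))),
           numeric(length(v)))
  } else {
    vapply(times, function(t) {
      s <- max(0L, ceiling(log2(max(1, norm(A, "I") * t))))
      X <- A * (t / 2^s)
      E <- diag(nrow(A)); term <- diag(nrow(A))
      for (k in 1:20) { term <- term %*% X / k; E <- E + term }
      for (k in seq_len(s)) E <- E %*% E
      as.numeric(E %*% v)
    }, numeric(length(v)))
  }
}

#' Simulate a spin-lock decay curve
#'
#' Propagates the initial magnetization under the Bloch-McConnell generator
#' by matrix exponentiation and records, at each relaxation delay, the total
#' magnetization projected onto the initial alignment axis.  Optionally adds
#' Gaussian intensity noise (constant standard deviation in units of the
#' t = 0 intensity, emulating thermal noise in 1D peak intensities).
#'
#' @inheritParams initial_magnetization
#' @param noise_sd Gaussian noise standard deviation in intensity units
#'   (the noiseless t = 0 intensity is 1); 0 for a noiseless curve.
#' @param seed optional RNG seed for the noise draw.
#' @return A `"decay_curve"`: list with `delays`, `intensities`, `noise_sd`.
#' @export
simulate_decay <- function(model, cond, nucleus, alignment_threshold = 5,
                           noise_sd = 0, seed = NULL) {
  A <- build_bm_matrix(model, cond, nucleus)
  m0 <- initial_magnetization(model, cond, nucleus, alignment_threshold)
  axis <- attr(m0, "axis")
  detect <- rep(axis, length(model$states))
  M <- .propagate(A, as.numeric(m0), cond$delays)
  I <- as.numeric(detect %*% M)
  if (any(!is.finite(I)))
    stop(sprintf("magnetization propagation overflowed at delay %g s",
                 cond$delays[which(!is.finite(I))[1]]), call. = FALSE)
  if (noise_sd > 0)
    I <- I + with_seed(seed, stats::rnorm(length(I), 0, noise_sd))
  structure(list(delays = cond$delays, intensities = I, noise_sd = noise_sd),
            class = "decay_curve")
}

#' R1rho for one condition (reference path)
#'
#' Simulates the noiseless decay and extracts R1rho by the same
#' mono-exponential fit applied to experimental curves, so that simulated
#' and fitted R1rho are defined identically.
#'
#' @inheritParams initial_magnetization
#' @return R1rho in 1/s.
#' @export
r1rho_bm <- function(model, cond, nucleus, alignment_threshold = 5) {
  curve <- simulate_decay(model, cond, nucleus, alignment_threshold)
  .monoexp_rate(curve$delays, curve$intensities)
}

#' R1rho over a grid of conditions
#'
#' Vectorised forward model: computes R1rho for one nucleus over many
#' (power, offset) combinations.  `engine = "cpp"` uses the compiled
#' propagation (identical algorithm, used inside [bmfit()]); `engine = "r"`
#' uses the reference implementation.
#'
#' @inheritParams initial_magnetization
#' @param power_hz,offset_hz vectors of equal length defining the grid.
#' @param delays relaxation delays shared by all conditions.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return Numeric vector of R1rho values (1/s).
#' @export
r1rho_profile <- function(model, nucleus, power_hz, offset_hz,
                          delays = c(0, 0.04, 0.08, 0.12),
                          alignment_threshold = 5, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(length(power_hz) == length(offset_hz))
  if (engine == "r") {
    return(vapply(seq_along(power_hz), function(i) {
      cond <- spinlock_condition(power_hz[i], offset_hz[i], delays,
                                 model$larmor_mhz)
      r1rho_bm(model, cond, nucleus, alignment_threshold)
    }, numeric(1)))
  }
  avg <- .use_average_alignment(model, nucleus, alignment_threshold)
  dw_rad <- c(0, model$dw[nucleus, ]) * 2 * pi * model$larmor_mhz
  .r1rho_grid_cpp(model$populations, microscopic_rates(model), dw_rad,
                  as.numeric(power_hz), as.numeric(offset_hz),
                  as.numeric(sort(delays)),
                  model$r1[[nucleus]], model$r2[[nucleus]], avg)
}

#' Transform R1rho to R2 + Rex
#'
#' Removes the longitudinal contribution from a rotating-frame relaxation
#' rate: \eqn{R_2 + R_{ex} = (R_{1\rho} - R_1\cos^2\theta)/\sin^2\theta}.
#' An uncertainty, if given, is propagated through the same linear map.
#'
#' @param r1rho rotating-frame relaxation rate(s), 1/s.
#' @param r1 longitudinal relaxation rate, 1/s.
#' @param theta effective-field tilt angle(s) in radians (see
#'   [tilt_angle()]); must not be 0 or pi.
#' @param sd optional standard deviation(s) of `r1rho`.
#' @return `R2 + Rex` (1/s); with `sd` supplied, a two-column matrix
#'   (`r2eff`, `sd`).
#' @export
r2eff_transform <- function(r1rho, r1, theta, sd = NULL) {
  s2 <- sin(theta)^2
  if (any(s2 < .Machine$double.eps))
    stop("theta = 0 or pi: R2 + Rex is undefined on the z axis",
         call. = FALSE)
  val <- (r1rho - r1 * cos(theta)^2) / s2
  if (is.null(sd)) return(val)
  cbind(r2eff = val, sd = sd / s2)
}

#' Closed-form fast-exchange Rex (2-state)
#'
#' The fast-exchange limit of a 2-state dispersion,
#' \eqn{R_{ex} = p_{GS} p_{ES} \Delta\omega^2 k_{ex} / (k_{ex}^2 +
#' \omega_{eff}^2)}, used as an independent oracle for the Bloch-McConnell
#' simulation when \eqn{k_{ex} \gg |\Delta\omega|}.
#'
#' @param p_gs,p_es ground- and excited-state populations.
#' @param delta_omega_rad chemical-shift difference in rad/s.
#' @param kex exchange rate in 1/s.
#' @param omega_eff effective-field amplitude in rad/s (in the
#'   population-average frame).
#' @return Rex in 1/s.
#' @export
rex_fast_exchange <- function(p_gs, p_es, delta_omega_rad, kex, omega_eff) {
  p_gs * p_es * delta_omega_rad^2 * kex / (kex^2 + omega_eff^2)
}
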