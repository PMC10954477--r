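# Equilibrium kinetic-flux model for misincorporation through the
# tautomeric (ES1) and anionic (ES2) Watson-Crick-like states.
#
# Pathway fluxes are composed from serial/parallel rules: serial chains
# combine harmonically (1/F = sum 1/F_i), parallel branches add.  The four
# routes into the misincorporated state MIS are
#   F_tt: GS -> ES1 -> MIS            F_ta: GS -> ES2 -> ES1 -> MIS
#   F_aa: GS -> ES2 -> MIS            F_at: GS -> ES1 -> ES2 -> MIS
# with F_T = F_tt + F_ta, F_A = F_aa + F_at and
# f_A = 100 * F_A / (F_T + F_A).
#
# The step fluxes use the equilibrium populations of the exchange network
# itself (k2 = k-2 = 0): these are the NMR-measured populations, and with
# them the flux partition interpolates exactly between its thermodynamic
# (k2 -> 0) and kinetic (k2 -> inf) limits.  Solving the full system
# including a fast catalytic step would distort the stationary populations
# (the ES1 -> MIS -> ES2 cycle breaks detailed balance) without
# representing the pre-catalytic equilibrium the model is built on.

#' Misincorporation kinetic scheme
#'
#' Microscopic rate constants of the wobble/tautomer/anion exchange network
#' together with the downstream catalytic step \eqn{k_2} (acting equally on
#' both Watson-Crick-like states), its reverse \eqn{k_{-2}}, and optional
#' binding rates for the pre-binding species of the full model.
#'
#' @param k_gs_es1,k_es1_gs,k_gs_es2,k_es2_gs,k_es1_es2,k_es2_es1
#'   exchange rate constants in 1/s (all non-negative; minor ES1:ES2
#'   exchange may be 0).
#' @param k2 rate of the step acting on the Watson-Crick-like states, 1/s.
#' @param k_minus2 its reverse (default: equal to `k2`).
#' @param k_on,k_off optional binding rates for the 5-state full model.
#' @param t_sim integration time used by [solve_to_equilibrium()]
#'   (default 10 s).
#' @param p0 initial populations (GS first; default all in GS, or all in
#'   the pre-bound species when binding rates are given).
#' @return An object of class `"kinetic_scheme"`.
#' @seealso [scheme_from_model()], [relative_flux()], [k2_sweep()]
#' @export
kinetic_scheme <- function(k_gs_es1, k_es1_gs, k_gs_es2, k_es2_gs,
                           k_es1_es2 = 0, k_es2_es1 = 0, k2 = 0,
                           k_minus2 = k2, k_on = NULL, k_off = NULL,
                           t_sim = 10, p0 = NULL) {
  r <- c(k_gs_es1 = k_gs_es1, k_es1_gs = k_es1_gs, k_gs_es2 = k_gs_es2,
         k_es2_gs = k_es2_gs, k_es1_es2 = k_es1_es2, k_es2_es1 = k_es2_es1,
         k2 = k2, k_minus2 = k_minus2)
  if (any(r < 0)) stop("all rates must be non-negative", call. = FALSE)
  binding <- !is.null(k_on) || !is.null(k_off)
  if (binding) {
    if (is.null(k_on) || is.null(k_off) || k_on <= 0 || k_off <= 0)
      stop("binding requires positive k_on and k_off", call. = FALSE)
  }
  n <- if (binding) 5L else 4L
  if (is.null(p0)) {
    p0 <- numeric(n); p0[1] <- 1
  }
  if (length(p0) != n || abs(sum(p0) - 1) > 1e-9 || any(p0 < 0))
    stop(sprintf("p0 must be %d non-negative populations summing to 1", n),
         call. = FALSE)
  structure(list(rates = as.list(r), k_on = k_on, k_off = k_off,
                 binding = binding, t_sim = t_sim, p0 = p0),
            class = "kinetic_scheme")
}

#' Kinetic scheme from a fitted exchange model
#'
#' Converts an [exchange_model()]'s populations and edge exchange rates
#' into the microscopic rates of a [kinetic_scheme()] via
#' [microscopic_rates()].  A 2-state model yields a scheme with no anionic
#' pathway (all ES2 rates 0).
#'
#' @param model an [exchange_model()].
#' @param k2,k_minus2,k_on,k_off,t_sim passed to [kinetic_scheme()].
#' @return A `"kinetic_scheme"`.
#' @export
scheme_from_model <- function(model, k2 = 0, k_minus2 = k2, k_on = NULL,
                              k_off = NULL, t_sim = 10) {
  stopifnot(inherits(model, "exchange_model"))
  K <- microscopic_rates(model)
  three <- length(model$states) == 3L
  kinetic_scheme(
    k_gs_es1 = K["GS", "ES1"], k_es1_gs = K["ES1", "GS"],
    k_gs_es2 = if (three) K["GS", "ES2"] else 0,
    k_es2_gs = if (three) K["ES2", "GS"] else 0,
    k_es1_es2 = if (three) K["ES1", "ES2"] else 0,
    k_es2_es1 = if (three) K["ES2", "ES1"] else 0,
    k2 = k2, k_minus2 = k_minus2, k_on = k_on, k_off = k_off,
    t_sim = t_sim)
}

# generator of dp/dt = Q p; states (G,) GS, ES1, ES2, MIS
.scheme_generator <- function(scheme, k2 = scheme$rates$k2,
                              k_minus2 = scheme$rates$k_minus2,
                              binding = scheme$binding) {
  r <- scheme$rates
  Q4 <- matrix(0, 4, 4,
               dimnames = list(c("GS", "ES1", "ES2", "MIS"), NULL))
  add <- function(Q, from, to, k) {
    Q[from, from] <- Q[from, from] - k
    Q[to, from] <- Q[to, from] + k
    Q
  }
  Q4 <- add(Q4, 1, 2, r$k_gs_es1); Q4 <- add(Q4, 2, 1, r$k_es1_gs)
  Q4 <- add(Q4, 1, 3, r$k_gs_es2); Q4 <- add(Q4, 3, 1, r$k_es2_gs)
  Q4 <- add(Q4, 2, 3, r$k_es1_es2); Q4 <- add(Q4, 3, 2, r$k_es2_es1)
  Q4 <- add(Q4, 2, 4, k2); Q4 <- add(Q4, 3, 4, k2)
  Q4 <- add(Q4, 4, 2, k_minus2); Q4 <- add(Q4, 4, 3, k_minus2)
  if (!binding) {
    colnames(Q4) <- rownames(Q4)
    return(Q4)
  }
  Q <- matrix(0, 5, 5,
              dimnames = list(c("G", "GS", "ES1", "ES2", "MIS"),
                              c("G", "GS", "ES1", "ES2", "MIS")))
  Q[2:5, 2:5] <- Q4
  Q <- add(Q, 1, 2, scheme$k_on); Q <- add(Q, 2, 1, scheme$k_off)
  Q
}

#' Integrate a kinetic scheme to equilibrium
#'
#' Solves \eqn{dp/dt = Q\,p} from the scheme's initial populations with a
#' stiff ODE solver up to `t_sim` (default 10 s, far beyond the ~5 ms
#' relaxation time of these networks) and checks that the derivative norm
#' has fallen below `tol`, warning otherwise.
#'
#' @param scheme a [kinetic_scheme()].
#' @param t_sim integration time in seconds.
#' @param tol equilibrium criterion on \eqn{\|dp/dt\|_\infty}.
#' @param k2,k_minus2 override the scheme's catalytic rates (used
#'   internally to obtain the exchange-only equilibrium with both 0).
#' @return Named vector of equilibrium populations (sums to 1).
#' @export
solve_to_equilibrium <- function(scheme, t_sim = scheme$t_sim, tol = 1e-9,
                                 k2 = scheme$rates$k2,
                                 k_minus2 = scheme$rates$k_minus2) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  Q <- .scheme_generator(scheme, k2, k_minus2)
  deriv <- function(t, y, parms) list(as.numeric(Q %*% y))
  sol <- deSolve::lsoda(scheme$p0, c(0, t_sim), deriv, NULL,
                        rtol = 1e-10, atol = 1e-14)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff ODE solve failed for rates: ",
         paste(sprintf("%s=%g", names(scheme$rates), unlist(scheme$rates)),
               collapse = ", "), call. = FALSE)
  p <- stats::setNames(as.numeric(sol[nrow(sol), -1]), rownames(Q))
  dp <- as.numeric(Q %*% p)
  if (max(abs(dp)) > tol)
    warning(sprintf("system not at equilibrium after %g s (|dp/dt| = %.2g)",
                    t_sim, max(abs(dp))))
  p
}

# exchange(+binding)-only equilibrium populations used by the flux algebra
.exchange_equilibrium <- function(scheme) {
  solve_to_equilibrium(scheme, k2 = 0, k_minus2 = 0)
}

#' Pathway fluxes into the misincorporated state
#'
#' Serial-harmonic composition of the four routes into MIS (see the
#' pathway definitions in [relative_flux()]).  A zero step flux anywhere in
#' a chain gives that pathway zero flux (continuity limit), not an error.
#'
#' @param scheme a [kinetic_scheme()].
#' @param populations equilibrium populations (named, containing `GS`,
#'   `ES1`, `ES2`); default: the exchange-only equilibrium of `scheme`.
#' @param k2 catalytic rate to evaluate at (default: the scheme's).
#' @return Named vector `c(F_tt, F_ta, F_aa, F_at)` in 1/s.
#' @export
pathway_fluxes <- function(scheme, populations = NULL,
                           k2 = scheme$rates$k2) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  p <- populations %||% .exchange_equilibrium(scheme)
  r <- scheme$rates
  serial <- function(...) {
    f <- c(...)
    if (any(f <= 0)) 0 else 1 / sum(1 / f)
  }
  c(F_tt = serial(p[["GS"]] * r$k_gs_es1, p[["ES1"]] * k2),
    F_ta = serial(p[["GS"]] * r$k_gs_es2, p[["ES2"]] * r$k_es2_es1,
                  p[["ES1"]] * k2),
    F_aa = serial(p[["GS"]] * r$k_gs_es2, p[["ES2"]] * k2),
    F_at = serial(p[["GS"]] * r$k_gs_es1, p[["ES1"]] * r$k_es1_es2,
                  p[["ES2"]] * k2))
}

#' Relative misincorporation flux through the anionic pathway
#'
#' Computes the equilibrium populations, the four pathway fluxes, the
#' tautomer and anion totals \eqn{F_T = F_{tt} + F_{ta}},
#' \eqn{F_A = F_{aa} + F_{at}}, and the percentage partition
#' \eqn{f_A = 100\, F_A / (F_T + F_A)}, \eqn{f_T = 100 - f_A}.
#'
#' @inheritParams pathway_fluxes
#' @return An object of class `"flux_result"`: list with `populations`,
#'   `fluxes`, `F_T`, `F_A`, `f_A`, `f_T`, `k2`.
#' @examples
#' sc <- scheme_from_model(duplex_model("dG.rU", 7.4), k2 = 100)
#' relative_flux(sc)
#' @export
relative_flux <- function(scheme, k2 = scheme$rates$k2,
                          populations = NULL) {
  p <- populations %||% .exchange_equilibrium(scheme)
  fl <- pathway_fluxes(scheme, p, k2)
  FT <- fl[["F_tt"]] + fl[["F_ta"]]
  FA <- fl[["F_aa"]] + fl[["F_at"]]
  if (FT + FA <= 0)
    stop("total flux is zero: relative flux undefined", call. = FALSE)
  structure(list(populations = p, fluxes = fl, F_T = FT, F_A = FA,
                 f_A = 100 * FA / (FT + FA), f_T = 100 * FT / (FT + FA),
                 k2 = k2),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("Misincorporation flux at k2 = %g 1/s\n", x$k2))
  cat(sprintf("  f_A = %.1f%% (anionic), f_T = %.1f%% (tautomeric)\n",
              x$f_A, x$f_T))
  cat(sprintf("  F_T = %.3g 1/s, F_A = %.3g 1/s\n", x$F_T, x$F_A))
  cat("  equilibrium populations:",
      paste(sprintf("%s = %.4g", names(x$populations), x$populations),
            collapse = ", "), "\n")
  invisible(x)
}

#' Sweep the catalytic rate
#'
#' Evaluates the flux partition over a grid of \eqn{k_2} values (the
#' equilibrium populations are computed once: they do not depend on
#' \eqn{k_2}).
#'
#' @param scheme a [kinetic_scheme()].
#' @param k2 grid of catalytic rates, 1/s (default: log-spaced
#'   \eqn{10^{-1}}..\eqn{10^{6}}).
#' @return Data frame of class `"k2_sweep"` with columns `k2`, `f_A`,
#'   `f_T`, `F_T`, `F_A`.
#' @export
k2_sweep <- function(scheme, k2 = 10^seq(-1, 6, length.out = 29)) {
  stopifnot(all(k2 > 0))
  p <- .exchange_equilibrium(scheme)
  rows <- lapply(k2, function(k) {
    f <- relative_flux(scheme, k2 = k, populations = p)
    data.frame(k2 = k, f_A = f$f_A, f_T = f$f_T, F_T = f$F_T, F_A = f$F_A)
  })
  structure(do.call(rbind, rows), class = c("k2_sweep", "data.frame"))
}

#' @export
plot.k2_sweep <- function(x, ylim = c(0, 100), ...) {
  graphics::plot(x$k2, x$f_A, log = "x", type = "l", lwd = 2,
                 col = "forestgreen", ylim = ylim,
                 xlab = expression(k[2] ~ (s^-1)),
                 ylab = expression(f[A] ~ "(%)"), ...)
  invisible(x)
}

#' Limiting flux partitions
#'
#' The thermodynamic limit (\eqn{k_2 \to 0}),
#' \eqn{f_A = 100\,p_{ES2}/(p_{ES1} + p_{ES2})}, and the kinetic limit
#' (\eqn{k_2 \to \infty}, no minor exchange),
#' \eqn{f_A = 100\,k_{GS \to ES2}/(k_{GS \to ES1} + k_{GS \to ES2})}.
#'
#' @param scheme a [kinetic_scheme()].
#' @return Named vector `c(thermodynamic, kinetic)` in percent.
#' @export
flux_limits <- function(scheme) {
  p <- .exchange_equilibrium(scheme)
  r <- scheme$rates
  c(thermodynamic = 100 * p[["ES2"]] / (p[["ES1"]] + p[["ES2"]]),
    kinetic = 100 * r$k_gs_es2 / (r$k_gs_es1 + r$k_gs_es2))
}

#' Add the binding step (full five-state model)
#'
#' Extends a simplified scheme with the pre-binding species G
#' (G <-> GS at `k_on`/`k_off`), giving the full kinetic model.  All
#' downstream calculations ([solve_to_equilibrium()], [relative_flux()],
#' [k2_sweep()]) operate on the extended scheme unchanged.
#'
#' @param scheme a [kinetic_scheme()] without binding.
#' @param k_on,k_off binding rates, 1/s (positive).
#' @return A `"kinetic_scheme"` with binding.
#' @export
with_binding <- function(scheme, k_on, k_off) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  r <- scheme$rates
  kinetic_scheme(r$k_gs_es1, r$k_es1_gs, r$k_gs_es2, r$k_es2_gs,
                 r$k_es1_es2, r$k_es2_es1, k2 = r$k2,
                 k_minus2 = r$k_minus2, k_on = k_on, k_off = k_off,
                 t_sim = scheme$t_sim)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  r <- x$rates
  cat(sprintf("Kinetic scheme (%s)\n",
              if (x$binding) "full, with binding" else "simplified"))
  cat(sprintf("  GS<->ES1: %.4g / %.4g 1/s;  GS<->ES2: %.4g / %.4g 1/s\n",
              r$k_gs_es1, r$k_es1_gs, r$k_gs_es2, r$k_es2_gs))
  if (r$k_es1_es2 > 0 || r$k_es2_es1 > 0)
    cat(sprintf("  minor ES1<->ES2: %.4g / %.4g 1/s\n",
                r$k_es1_es2, r$k_es2_es1))
  cat(sprintf("  k2 = %.4g, k-2 = %.4g 1/s; t_sim = %g s\n",
              r$k2, r$k_minus2, x$t_sim))
  if (x$binding)
    cat(sprintf("  binding: k_on = %.4g, k_off = %.4g 1/s\n",
                x$k_on, x$k_off))
  invisible(x)
}
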