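# pH-dependent extrapolation of the anionic excited state.
#
# Model assumptions, as established by pH-series relaxation-dispersion
# measurements: tautomer (ES1) kinetics are pH independent; for the anionic
# ES2 the backward rate k_ES2->GS is pH independent (late transition state)
# and all pH dependence enters through the forward rate / population.

#' Anionic population at a given pH
#'
#' Henderson-Hasselbalch extrapolation of the anionic excited-state
#' population, \eqn{p_{ES2} = 10^{pH - pK_a^{app}} /
#' (1 + 10^{pH - pK_a^{app}})}.
#'
#' @param pka_app apparent pKa of the anionic transition.
#' @param ph target pH.
#' @return Population in (0, 1).
#' @examples
#' anion_population(10.32, 7.4)   # dG.rU-like: ~1.2e-3
#' @export
anion_population <- function(pka_app, ph) {
  stopifnot(is.finite(pka_app))
  x <- 10^(ph - pka_app)
  x / (1 + x)
}

#' Extrapolate a rate constant in pH
#'
#' Applies the linear \eqn{\ln k = a \cdot pH + b} model: the fold change
#' between two pH values is \eqn{\exp(a \,\Delta pH)}, with the slope `a`
#' shared across duplexes.  The default slope, \eqn{a = \ln 10}, is the
#' hydroxide-mediated deprotonation expectation and is consistent with the
#' observed ~2.5-fold rise of the dG.rU anionic forward rate over 0.4 pH
#' units.
#'
#' @param k_from rate constant at `ph_from`, 1/s.
#' @param ph_from,ph_to source and target pH.
#' @param slope d ln(k)/d pH (default `log(10)`).
#' @return Rate constant at `ph_to`, 1/s.
#' @export
extrapolate_rate <- function(k_from, ph_from, ph_to, slope = log(10)) {
  stopifnot(is.finite(slope))
  k_from * exp(slope * (ph_to - ph_from))
}

#' Anionic forward rate from the apparent pKa
#'
#' With a pH-independent backward rate, the forward rate at any pH follows
#' from the pKa-derived population:
#' \eqn{k_{GS \to ES2} = k_{ES2 \to GS} \; p_{ES2} / (1 - p_{ES2} - p_{ES1})}.
#'
#' @param k_backward the (pH-independent) backward rate
#'   \eqn{k_{ES2 \to GS}}, 1/s.
#' @param p_es1 tautomeric excited-state population (pH independent).
#' @param pka_app apparent pKa of the anionic transition.
#' @param ph target pH.
#' @return Forward rate \eqn{k_{GS \to ES2}} at `ph`, 1/s.
#' @export
forward_rate_from_pka <- function(k_backward, p_es1, pka_app, ph) {
  stopifnot(k_backward > 0, p_es1 >= 0, p_es1 < 1)
  p2 <- anion_population(pka_app, ph)
  if (p2 + p_es1 >= 1)
    stop("p_ES2 + p_ES1 >= 1: no ground state left", call. = FALSE)
  k_backward * p2 / (1 - p2 - p_es1)
}

#' Retarget an exchange model to another pH
#'
#' Builds the exchange model expected at `ph_to` from a model characterised
#' at one pH.  Tautomer (ES1) parameters are left untouched.  The anionic
#' ES2 is updated by one of two routes: `method = "pka"` keeps the backward
#' rate fixed and sets the population from the apparent pKa
#' ([anion_population()]); `method = "slope"` scales the forward rate by
#' the \eqn{\ln k = a\,pH + b} fold change ([extrapolate_rate()]) and
#' rederives the population with the backward rate fixed.  Minor (ES1:ES2)
#' exchange, when present, is scaled by the same fold change as the
#' anionic forward rate.  A 2-state input model gains an ES2 state when
#' `k_backward` is supplied.
#'
#' @param model an [exchange_model()]; its source pH is taken from the
#'   model's `ph` attribute unless `ph_from` is given.
#' @param ph_to target pH.
#' @param pka_app apparent pKa of the anionic transition
#'   (required for `method = "pka"`).
#' @param ph_from source pH.
#' @param method `"pka"` (default) or `"slope"`.
#' @param slope d ln(k)/d pH for `method = "slope"` and for the minor-
#'   exchange fold change (default `log(10)`).
#' @param k_backward anionic backward rate in 1/s, required when `model`
#'   is 2-state (no ES2 yet); e.g. derived from a higher-pH measurement.
#' @param dw_es2 per-nucleus chemical-shift differences of the added ES2
#'   (ppm) when `model` is 2-state.
#' @return An [exchange_model()] at `ph_to` (attribute `ph` updated).
#' @export
model_at_ph <- function(model, ph_to, pka_app = NULL,
                        ph_from = attr(model, "ph"),
                        method = c("pka", "slope"), slope = log(10),
                        k_backward = NULL, dw_es2 = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "exchange_model"))
  if (is.null(ph_from) && method == "slope")
    stop("'ph_from' is required (model has no pH attribute)", call. = FALSE)
  p1 <- model$populations[["ES1"]]

  if (length(model$states) == 2L) {
    # add the anionic state from pKa + backward rate
    if (is.null(k_backward) || is.null(pka_app))
      stop("2-state model: supply 'k_backward' and 'pka_app' to add ES2",
           call. = FALSE)
    kb <- k_backward
    kexm <- 0
    dw2 <- dw_es2 %||% stats::setNames(rep(0, length(model$nuclei)),
                                       model$nuclei)
    dw2 <- dw2[model$nuclei]
  } else {
    K <- microscopic_rates(model)
    kb <- K["ES2", "GS"]
    kexm <- model$kex[["ES1:ES2"]]
    dw2 <- model$dw[, "ES2"]
  }

  if (method == "pka") {
    if (is.null(pka_app)) stop("'pka_app' is required", call. = FALSE)
    p2_new <- anion_population(pka_app, ph_to)
    if (p2_new + p1 >= 1)
      stop("extrapolated p_ES2 + p_ES1 >= 1", call. = FALSE)
    kf_new <- kb * p2_new / (1 - p2_new - p1)
    fold <- if (!is.null(ph_from)) exp(slope * (ph_to - ph_from)) else 1
  } else {
    K <- microscopic_rates(model)
    kf_old <- K["GS", "ES2"]
    fold <- exp(slope * (ph_to - ph_from))
    kf_new <- kf_old * fold
    q <- kf_new / kb
    p2_new <- (1 - p1) * q / (1 + q)
  }

  dw_new <- cbind(ES1 = model$dw[, "ES1"], ES2 = dw2)
  rownames(dw_new) <- model$nuclei
  out <- exchange_model(
    populations = c(GS = 1 - p1 - p2_new, ES1 = p1, ES2 = p2_new),
    kex = c(model$kex[["GS:ES1"]], kf_new + kb, kexm * fold),
    dw = dw_new, r1 = model$r1, r2 = model$r2,
    larmor_mhz = model$larmor_mhz)
  attr(out, "duplex") <- attr(model, "duplex")
  attr(out, "ph") <- ph_to
  out
}
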