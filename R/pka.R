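# pKa determination: combined chemical-shift perturbations,
# Henderson-Hasselbalch titration fits, and apparent pKa from
# excited-state populations.

#' Combined chemical-shift perturbation
#'
#' Weighted Euclidean combination of 13C and 15N chemical-shift changes,
#' \eqn{\Delta\delta_{obs} = \sqrt{(\alpha_{13C}\Delta\delta_{13C})^2 +
#' (\alpha_{15N}\Delta\delta_{15N})^2}}.  The default weights are the
#' BMRB-derived heteronuclear normalisation factors
#' \eqn{\alpha_{13C=O} = 0.341} and \eqn{\alpha_{15N} = 0.154}.
#'
#' @param delta_13c,delta_15n chemical-shift changes in ppm.
#' @param alpha_13c,alpha_15n positive weight factors.
#' @return Combined shift perturbation(s) in ppm.
#' @export
combined_csp <- function(delta_13c, delta_15n, alpha_13c = 0.341,
                         alpha_15n = 0.154) {
  if (alpha_13c <= 0 || alpha_15n <= 0)
    stop("weights must be positive", call. = FALSE)
  if (any(is.na(delta_13c)) || any(is.na(delta_15n)))
    stop("missing chemical shift", call. = FALSE)
  sqrt((alpha_13c * delta_13c)^2 + (alpha_15n * delta_15n)^2)
}

#' Chemical-shift titration series
#'
#' pH-indexed 13C/15N chemical shifts with their combined shift
#' perturbation relative to a reference point (by default the lowest-pH
#' point, where the site is protonated).
#'
#' @param ph sample pH values.
#' @param shift_13c,shift_15n chemical shifts in ppm.
#' @param reference `"lowest"` (lowest pH) or an index into the sorted
#'   series.
#' @param alpha_13c,alpha_15n CSP weights, see [combined_csp()].
#' @return Data frame of class `"titration_series"` with columns `ph`,
#'   `shift_13c`, `shift_15n`, `dd_13c`, `dd_15n`, `csp`, sorted by pH.
#' @export
titration_series <- function(ph, shift_13c, shift_15n, reference = "lowest",
                             alpha_13c = 0.341, alpha_15n = 0.154) {
  stopifnot(length(ph) == length(shift_13c),
            length(ph) == length(shift_15n))
  o <- order(ph)
  ph <- ph[o]; shift_13c <- shift_13c[o]; shift_15n <- shift_15n[o]
  ref <- if (identical(reference, "lowest")) 1L else as.integer(reference)
  dd13 <- shift_13c - shift_13c[ref]
  dd15 <- shift_15n - shift_15n[ref]
  structure(
    data.frame(ph = ph, shift_13c = shift_13c, shift_15n = shift_15n,
               dd_13c = dd13, dd_15n = dd15,
               csp = combined_csp(dd13, dd15, alpha_13c, alpha_15n)),
    reference = ref, class = c("titration_series", "data.frame"))
}

#' Henderson-Hasselbalch titration fit
#'
#' Fits a single-site protonation transition to combined chemical-shift
#' perturbations,
#' \deqn{\Delta\delta_{obs}(pH) = \Delta\delta_{deprot} +
#'   \frac{\Delta\delta_{prot} - \Delta\delta_{deprot}}
#'        {1 + 10^{(pH - pK_a)}},}
#' by nonlinear least squares.  Parameter uncertainties are the square
#' roots of the diagonal of the covariance matrix of the fit.
#'
#' @param x a [titration_series()], or a numeric vector of pH values.
#' @param csp combined shift perturbations (when `x` is numeric).
#' @param start optional named start values (`pka`, `dd_prot`, `dd_deprot`).
#' @return An object of class `"hhfit"` with elements `pka`, `pka_sd`,
#'   `dd_protonated`, `dd_deprotonated`, `cov`, `fitted`, `residuals`,
#'   `data`.
#' @examples
#' tt <- simulate_titration(9.87, seed = 1)
#' fit <- hhfit(tt)
#' fit
#' @export
hhfit <- function(x, csp = NULL, start = NULL) {
  if (inherits(x, "titration_series")) {
    ph <- x$ph; csp <- x$csp
  } else {
    ph <- as.numeric(x)
  }
  stopifnot(length(ph) == length(csp))
  if (length(ph) < 4L)
    stop("at least 4 pH points are required", call. = FALSE)

  if (is.null(start)) {
    lo <- min(csp); hi <- max(csp)
    mid <- (lo + hi) / 2
    start <- list(pka = ph[which.min(abs(csp - mid))],
                  dd_prot = csp[which.min(ph)], dd_deprot = csp[which.max(ph)])
  }
  d <- data.frame(ph = ph, csp = csp)
  fit <- minpack.lm::nlsLM(
    csp ~ dd_deprot + (dd_prot - dd_deprot) / (1 + 10^(ph - pka)),
    data = d, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 3, 3))
  if (abs(cf[["dd_prot"]] - cf[["dd_deprot"]]) < 1e-12)
    stop("fit degenerate: protonated and deprotonated endpoints coincide",
         call. = FALSE)
  out <- structure(
    list(pka = cf[["pka"]], pka_sd = sqrt(vc[rownames(vc) == "pka",
                                             colnames(vc) == "pka"]),
         dd_protonated = cf[["dd_prot"]],
         dd_deprotonated = cf[["dd_deprot"]],
         cov = vc, fitted = stats::fitted(fit),
         residuals = stats::residuals(fit), data = d, nls = fit),
    class = "hhfit")
  if (out$pka < min(ph) - 0.5 || out$pka > max(ph) + 0.5)
    warning("fitted pKa lies outside the sampled pH range: ",
            "transition not identifiable from these data")
  out
}

#' @export
print.hhfit <- function(x, ...) {
  cat(sprintf("Henderson-Hasselbalch fit: pKa = %.3f +/- %.3f\n",
              x$pka, x$pka_sd))
  cat(sprintf("  endpoints (ppm): protonated %.4f, deprotonated %.4f\n",
              x$dd_protonated, x$dd_deprotonated))
  cat(sprintf("  %d pH points, residual sd %.4g ppm\n",
              nrow(x$data), stats::sd(x$residuals)))
  invisible(x)
}

#' @export
coef.hhfit <- function(object, ...) {
  c(pka = object$pka, dd_protonated = object$dd_protonated,
    dd_deprotonated = object$dd_deprotonated)
}

#' @export
summary.hhfit <- function(object, ...) {
  se <- sqrt(diag(object$cov))
  tab <- cbind(Estimate = coef(object)[c("pka", "dd_protonated",
                                         "dd_deprotonated")],
               `Std. Error` = se[c("pka", "dd_prot", "dd_deprot")])
  rownames(tab) <- c("pKa", "dd_protonated", "dd_deprotonated")
  structure(list(coefficients = tab, n = nrow(object$data),
                 sigma = stats::sd(object$residuals)),
            class = "summary.hhfit")
}

#' @export
print.summary.hhfit <- function(x, ...) {
  cat("Henderson-Hasselbalch titration fit\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nn = %d, residual sd = %.4g ppm\n", x$n, x$sigma))
  invisible(x)
}

#' @export
predict.hhfit <- function(object, newdata = NULL, ...) {
  ph <- if (is.null(newdata)) object$data$ph else
    (if (is.data.frame(newdata)) newdata$ph else newdata)
  object$dd_deprotonated +
    (object$dd_protonated - object$dd_deprotonated) / (1 + 10^(ph - object$pka))
}

#' @export
residuals.hhfit <- function(object, ...) object$residuals

#' @export
plot.hhfit <- function(x, ...) {
  ph <- x$data$ph
  grid <- seq(min(ph), max(ph), length.out = 200)
  graphics::plot(ph, x$data$csp, xlab = "pH",
                 ylab = expression(Delta * delta[obs] ~ "(ppm)"),
                 pch = 19, ...)
  graphics::lines(grid, predict(x, grid), col = "steelblue", lwd = 2)
  graphics::abline(v = x$pka, lty = 3, col = "grey40")
  invisible(x)
}

#' Species populations from a titration fit
#'
#' Converts an observed combined shift perturbation into deprotonated
#' (anionic) and protonated fractions using the fitted endpoints:
#' \eqn{p_{deprot} = (\Delta\delta_{prot} - \Delta\delta_{obs}) /
#' (\Delta\delta_{prot} - \Delta\delta_{deprot})}.  Values outside
#' \[0, 1\]
#' (possible from noise) are clamped with a warning.
#'
#' @param csp observed combined shift perturbation(s), ppm.
#' @param fit an [hhfit()].
#' @return Matrix with columns `deprotonated`, `protonated` summing to 1.
#' @export
species_populations <- function(csp, fit) {
  stopifnot(inherits(fit, "hhfit"))
  den <- fit$dd_protonated - fit$dd_deprotonated
  if (abs(den) < 1e-300)
    stop("endpoints coincide: populations undefined", call. = FALSE)
  p <- (fit$dd_protonated - csp) / den
  if (any(p < 0 | p > 1)) {
    warning("population(s) outside [0, 1] clamped")
    p <- pmin(1, pmax(0, p))
  }
  cbind(deprotonated = p, protonated = 1 - p)
}

#' Apparent pKa from excited-state populations
#'
#' The apparent pKa of the anionic transition implied by equilibrium
#' populations measured at a single pH:
#' \eqn{pK_a^{app} = pH - \log_{10}\!\big(p_{anion} / (p_{wobble} +
#' p_{tautomer})\big)}.  If population standard deviations are supplied the
#' uncertainty is propagated to first order.
#'
#' @param ph measurement pH.
#' @param p_anion,p_wobble,p_tautomer equilibrium populations of the
#'   anionic excited state, the wobble ground state and the tautomeric
#'   excited state (`p_anion` must be positive).
#' @param sd_anion,sd_wobble,sd_tautomer optional standard deviations.
#' @return The apparent pKa, or (with uncertainties supplied) a named
#'   vector `c(pka_app, sd)`.
#' @examples
#' apparent_pka(7.8, p_anion = 0.003, p_wobble = 1 - 0.003 - 0.0019,
#'              p_tautomer = 0.0019)
#' @export
apparent_pka <- function(ph, p_anion, p_wobble, p_tautomer,
                         sd_anion = NULL, sd_wobble = NULL,
                         sd_tautomer = NULL) {
  if (any(c(p_anion, p_wobble, p_tautomer) < 0))
    stop("populations must be non-negative", call. = FALSE)
  if (p_anion <= 0)
    stop("p_anion must be positive: apparent pKa undefined", call. = FALSE)
  if (p_anion + p_wobble + p_tautomer > 1 + 1e-9)
    stop("populations exceed 1", call. = FALSE)
  neutral <- p_wobble + p_tautomer
  val <- ph - log10(p_anion / neutral)
  if (is.null(sd_anion) && is.null(sd_wobble) && is.null(sd_tautomer))
    return(val)
  sa <- sd_anion %||% 0; sw <- sd_wobble %||% 0; st <- sd_tautomer %||% 0
  ln10 <- log(10)
  var <- (sa / (p_anion * ln10))^2 +
    (sw / (neutral * ln10))^2 + (st / (neutral * ln10))^2
  c(pka_app = val, sd = sqrt(var))
}
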