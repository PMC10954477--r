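# Global fitting of R1rho datasets to 2-state / 3-state triangular
# Bloch-McConnell exchange models.
#
# Populations and exchange rates are shared across nuclei; chemical-shift
# differences and R1/R2 are per nucleus.  Optimisation is multi-start
# Levenberg-Marquardt on transformed parameters (log10 for populations and
# rates) with box bounds; starts are built from the data (dispersion-peak
# positions for dw, a coarse grid for populations and rates).

.bm_bounds <- function(par_names) {
  lower <- upper <- stats::setNames(numeric(length(par_names)), par_names)
  for (nm in par_names) {
    if (startsWith(nm, "lp"))      { lower[nm] <- -6;   upper[nm] <- -1 }
    else if (startsWith(nm, "lk")) { lower[nm] <- 2;    upper[nm] <- 6 }
    else if (startsWith(nm, "dw")) { lower[nm] <- -100; upper[nm] <- 100 }
    else if (startsWith(nm, "r1")) { lower[nm] <- 0.01; upper[nm] <- 20 }
    else if (startsWith(nm, "r2")) { lower[nm] <- 0.1;  upper[nm] <- 100 }
  }
  list(lower = lower, upper = upper)
}

# transformed parameter vector -> exchange_model
.bm_unpack <- function(par, nuclei, nstates, minor, larmor_mhz) {
  p1 <- 10^par[["lp1"]]
  if (nstates == 2L) {
    dw <- matrix(par[paste0("dw1.", nuclei)], ncol = 1,
                 dimnames = list(nuclei, NULL))
    exchange_model(c(1 - p1, p1), 10^par[["lk1"]], dw,
                   r1 = stats::setNames(par[paste0("r1.", nuclei)], nuclei),
                   r2 = stats::setNames(par[paste0("r2.", nuclei)], nuclei),
                   larmor_mhz = larmor_mhz)
  } else {
    p2 <- 10^par[["lp2"]]
    dw <- cbind(par[paste0("dw1.", nuclei)], par[paste0("dw2.", nuclei)])
    rownames(dw) <- nuclei
    kexm <- if (minor) 10^par[["lkm"]] else 0
    exchange_model(c(1 - p1 - p2, p1, p2),
                   c(10^par[["lk1"]], 10^par[["lk2"]], kexm), dw,
                   r1 = stats::setNames(par[paste0("r1.", nuclei)], nuclei),
                   r2 = stats::setNames(par[paste0("r2.", nuclei)], nuclei),
                   larmor_mhz = larmor_mhz)
  }
}

# natural-scale coefficient vector of a fitted model
.bm_coef <- function(model) {
  out <- c(p_ES1 = unname(model$populations[["ES1"]]),
           if (length(model$states) == 3L)
             c(p_ES2 = unname(model$populations[["ES2"]])),
           stats::setNames(as.numeric(model$kex),
                           paste0("kex_", sub(":", "_", names(model$kex)))))
  for (st in colnames(model$dw))
    out <- c(out, stats::setNames(model$dw[, st],
                                  paste0("dw_", st, "_", rownames(model$dw))))
  c(out, stats::setNames(model$r1, paste0("r1_", names(model$r1))),
    stats::setNames(model$r2, paste0("r2_", names(model$r2))))
}

# forward-model R1rho for every dataset row, given a transformed par vector
.bm_predict_par <- function(par, dat, nuclei, nstates, minor, larmor_mhz,
                            delays, alignment_threshold) {
  model <- .bm_unpack(par, nuclei, nstates, minor, larmor_mhz)
  pred <- numeric(nrow(dat))
  for (nuc in nuclei) {
    i <- dat$nucleus == nuc
    pred[i] <- r1rho_profile(model, nuc, dat$power_hz[i], dat$offset_hz[i],
                             delays = delays,
                             alignment_threshold = alignment_threshold)
  }
  pred
}

# heuristic per-nucleus initial guesses from the observed profiles
.bm_heuristics <- function(dat, larmor_mhz) {
  out <- list()
  for (nuc in unique(dat$nucleus)) {
    d <- dat[dat$nucleus == nuc, ]
    r1_init <- max(0.5, min(d$r1rho))
    theta <- tilt_angle(d$power_hz, d$offset_hz)
    r2eff <- (d$r1rho - r1_init * cos(theta)^2) / sin(theta)^2
    far <- abs(d$offset_hz) >= 2 * d$power_hz
    r2_init <- if (any(far)) stats::median(r2eff[far]) else
      stats::quantile(r2eff, 0.25, names = FALSE)
    r2_init <- min(90, max(0.5, r2_init))
    peak <- which.max(r2eff)
    dw_init <- -d$offset_hz[peak] / larmor_mhz
    out[[nuc]] <- list(r1 = r1_init, r2 = r2_init, dw = dw_init,
                       r2eff = r2eff)
  }
  out
}

#' Global Bloch-McConnell fit of relaxation-dispersion data
#'
#' Fits observed R1rho values for one or more nuclei to a 2-state or
#' 3-state (triangular) chemical-exchange model by weighted least squares
#' against the Bloch-McConnell forward model, sharing populations and
#' exchange rates across nuclei while fitting per-nucleus chemical-shift
#' differences and relaxation rates.  Optimisation is multi-start
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]) on log-transformed
#' populations/rates with box bounds; among starts of equal residual sum
#' the one with the smallest ground-state exchange rate is kept.
#'
#' @param data an [rd_dataset()] (columns `nucleus`, `power_hz`,
#'   `offset_hz`, `r1rho`, `r1rho_sd`).
#' @param nstates 2 or 3.
#' @param nuclei nuclei to include (default: all; populations and rates
#'   are shared across them).
#' @param minor for `nstates = 3`: fit the ES1:ES2 minor exchange rate
#'   (default `TRUE`); `FALSE` fixes it to 0.
#' @param n_starts number of multi-start optimisations (ranked by initial
#'   residual sum from a larger candidate grid).
#' @param starts optional list of named transformed start vectors
#'   (advanced; replaces the candidate grid).
#' @param mc_iter Monte Carlo iterations for parameter uncertainties
#'   (0 = skip; see [monte_carlo_uncertainty()]).
#' @param seed RNG seed for the Monte Carlo step.
#' @param alignment_threshold passed to the forward model, see
#'   [initial_magnetization()].
#' @param control list overriding optimiser settings (`maxiter`, `ftol`,
#'   `ptol`).
#' @return An object of class `"bmfit"`: list with `model` (the fitted
#'   [exchange_model()]), `coefficients`, `sd`, `chi2`, `n_obs`, `n_par`,
#'   `aic`, `bic`, `converged`, `n_starts`, `fitted`, `data`, and the
#'   fit configuration.
#' @examples
#' \donttest{
#' truth <- duplex_model("dT.rG", 7.4)
#' ds <- simulate_rd_dataset(truth, grid = default_grid(c(600, 1600), 9),
#'                           seed = 1)
#' fit <- bmfit(ds, nstates = 2)
#' coef(fit)
#' }
#' @export
bmfit <- function(data, nstates = 2, nuclei = NULL, minor = TRUE,
                  n_starts = 4, starts = NULL, mc_iter = 0, seed = NULL,
                  alignment_threshold = 5, control = list()) {
  stopifnot(nstates %in% 2:3)
  if (!all(c("nucleus", "power_hz", "offset_hz", "r1rho", "r1rho_sd") %in%
           names(data)))
    stop("'data' must have columns nucleus, power_hz, offset_hz, r1rho, ",
         "r1rho_sd", call. = FALSE)
  nuclei <- nuclei %||% unique(data$nucleus)
  dat <- as.data.frame(data)[data$nucleus %in% nuclei, ]
  if (nrow(dat) == 0L) stop("no records for the requested nuclei",
                            call. = FALSE)
  if (any(dat$r1rho_sd <= 0))
    stop("all r1rho_sd must be positive", call. = FALSE)
  npow <- tapply(dat$power_hz, dat$nucleus, function(x) length(unique(x)))
  if (any(npow < 2))
    warning("fewer than 2 distinct spin-lock powers for: ",
            paste(names(npow)[npow < 2], collapse = ", "))
  larmor_mhz <- attr(data, "larmor_mhz") %||% 70.95
  delays <- attr(data, "delays") %||% c(0, 0.04, 0.08, 0.12)
  ctrl <- utils::modifyList(list(maxiter = 100, ftol = 1e-10, ptol = 1e-10),
                            control)
  wt <- 1 / dat$r1rho_sd

  resid_fn <- function(par) {
    pred <- .bm_predict_par(par, dat, nuclei, nstates, minor, larmor_mhz,
                            delays, alignment_threshold)
    r <- (dat$r1rho - pred) * wt
    r[!is.finite(r)] <- 1e6
    r
  }

  # candidate starts
  if (is.null(starts)) {
    h <- .bm_heuristics(dat, larmor_mhz)
    base <- unlist(c(
      lapply(nuclei, function(n) stats::setNames(h[[n]]$dw,
                                                 paste0("dw1.", n))),
      lapply(nuclei, function(n) stats::setNames(h[[n]]$r1,
                                                 paste0("r1.", n))),
      lapply(nuclei, function(n) stats::setNames(h[[n]]$r2,
                                                 paste0("r2.", n)))))
    if (nstates == 2L) {
      grid <- expand.grid(lp1 = log10(c(3e-4, 1e-3, 5e-3)),
                          lk1 = log10(c(2000, 6000, 20000)))
      starts <- lapply(seq_len(nrow(grid)), function(i)
        c(lp1 = grid$lp1[i], lk1 = grid$lk1[i], base))
    } else {
      # seed ES1 from a 2-state prefit, scan a small grid for ES2
      pre <- bmfit(data, nstates = 2, nuclei = nuclei,
                   n_starts = min(n_starts, 3), mc_iter = 0,
                   alignment_threshold = alignment_threshold,
                   control = control)
      pre_par <- c(lp1 = log10(pre$model$populations[["ES1"]]),
                   lk1 = log10(pre$model$kex[["GS:ES1"]]),
                   stats::setNames(pre$model$dw[nuclei, 1],
                                   paste0("dw1.", nuclei)),
                   stats::setNames(pre$model$r1[nuclei],
                                   paste0("r1.", nuclei)),
                   stats::setNames(pre$model$r2[nuclei],
                                   paste0("r2.", nuclei)))
      # dw_ES2 candidates per nucleus: a coarse grid over the plausible
      # shift-difference range plus the two strongest residual-dispersion
      # peaks left by the 2-state fit (and 0: a nucleus may not sense the
      # second excited state at all).  The candidates are only ranked by
      # their initial residual sum, so a generous list is cheap.
      res_r2eff <- dat$r1rho - pre$fitted
      dw2_cand <- lapply(nuclei, function(n) {
        i <- which(dat$nucleus == n)
        off <- dat$offset_hz[i]; r <- res_r2eff[i]
        p1 <- which.max(r)
        far <- abs(off - off[p1]) > 0.25 * diff(range(off))
        p2 <- if (any(far)) which(far)[which.max(r[far])] else p1
        unique(round(c(seq(-60, 60, by = 15),
                       -off[p1] / larmor_mhz, -off[p2] / larmor_mhz), 1))
      })
      names(dw2_cand) <- nuclei
      dw2_grid <- do.call(expand.grid, dw2_cand)
      cand <- lapply(seq_len(nrow(dw2_grid)), function(i) {
        s <- c(pre_par, lp2 = log10(1e-3), lk2 = log10(5000),
               stats::setNames(as.numeric(dw2_grid[i, ]),
                               paste0("dw2.", nuclei)))
        if (minor) s <- c(s, lkm = log10(1e4))
        s
      })
      # placing an unrefined extra dispersion peak usually *raises* the
      # initial residual sum, so pure initial-chi2 ranking would discard
      # every informative candidate.  Instead keep, for every distinct
      # dw2 value of every nucleus, the best combination containing it,
      # and let a short optimisation stage sort them out.
      b0 <- .bm_bounds(names(cand[[1]]))
      cand <- lapply(cand, function(s)
        pmin(b0$upper, pmax(b0$lower, s[names(cand[[1]])])))
      sse <- vapply(cand, function(s) sum(resid_fn(s)^2), numeric(1))
      keep <- integer(0)
      for (nuc in nuclei) {
        v <- dw2_grid[[nuc]]
        for (u in unique(v)) {
          i <- which(v == u)
          keep <- c(keep, i[which.min(sse[i])])
        }
      }
      keep <- unique(c(keep, order(sse)[seq_len(min(4, length(sse)))]))
      refined <- lapply(cand[keep], function(s) {
        # deliberately truncated refinement: suppress the maxiter warning
        f <- tryCatch(suppressWarnings(
          minpack.lm::nls.lm(par = s, fn = resid_fn, lower = b0$lower,
                             upper = b0$upper,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 10, ftol = 1e-8, ptol = 1e-8))),
          error = function(e) NULL)
        if (is.null(f)) NULL else
          list(par = stats::setNames(as.numeric(f$par), names(s)),
               dev = stats::deviance(f))
      })
      refined <- refined[!vapply(refined, is.null, logical(1))]
      refined <- refined[order(vapply(refined, `[[`, numeric(1), "dev"))]
      starts <- lapply(refined, `[[`, "par")
    }
  }
  par_names <- names(starts[[1]])
  b <- .bm_bounds(par_names)
  clamp <- function(s) pmin(b$upper, pmax(b$lower, s[par_names]))
  starts <- lapply(starts, clamp)

  # rank candidates by initial residual sum, optimise from the best few
  sse0 <- vapply(starts, function(s) sum(resid_fn(s)^2), numeric(1))
  use <- order(sse0)[seq_len(min(n_starts, length(starts)))]
  fits <- lapply(starts[use], function(s) {
    tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         lower = b$lower, upper = b$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = ctrl$maxiter, ftol = ctrl$ftol,
                           ptol = ctrl$ptol)),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("no optimisation start converged (", length(use), " attempted); ",
         "check data scaling and uncertainties", call. = FALSE)
  fits <- fits[ok]
  dev <- vapply(fits, stats::deviance, numeric(1))
  # tie-break equal-deviance starts by the smaller GS exchange rate
  best_dev <- min(dev)
  tied <- which(dev <= best_dev * (1 + 1e-6))
  kex1 <- vapply(fits[tied], function(f) f$par[["lk1"]], numeric(1))
  best <- fits[[tied[which.min(kex1)]]]

  par <- stats::setNames(as.numeric(best$par), par_names)
  model <- .bm_unpack(par, nuclei, nstates, minor, larmor_mhz)
  fitted <- .bm_predict_par(par, dat, nuclei, nstates, minor, larmor_mhz,
                            delays, alignment_threshold)
  chi2 <- sum(((dat$r1rho - fitted) * wt)^2)
  N <- nrow(dat); K <- length(par)
  out <- structure(list(
    model = model, par = par, coefficients = .bm_coef(model),
    sd = NULL, chi2 = chi2, n_obs = N, n_par = K,
    aic = N * log(chi2 / N) + 2 * K,
    bic = N * log(chi2 / N) + K * log(N),
    converged = best$info %in% 1:4, n_starts = length(use),
    nstates = nstates, minor = minor, nuclei = nuclei,
    larmor_mhz = larmor_mhz, delays = delays,
    alignment_threshold = alignment_threshold,
    fitted = fitted, data = dat, seed = seed, call = match.call()),
    class = "bmfit")
  if (mc_iter > 0)
    out <- monte_carlo_uncertainty(out, n_iter = mc_iter, seed = seed)
  out
}

#' Monte Carlo parameter uncertainties
#'
#' Resamples each observed R1rho from a normal distribution centred on the
#' fitted value with the observed standard deviation, refits from the
#' best-fit parameters, and reports the standard deviation of every
#' parameter across iterations.
#'
#' @param fit a converged [bmfit()].
#' @param n_iter number of Monte Carlo iterations (default 200).
#' @param seed optional RNG seed.
#' @return `fit` with `$sd` filled (natural-scale, aligned with
#'   `coef(fit)`) and the iteration draws in `attr(fit, "mc_draws")`.  If
#'   more than 20% of refits fail a warning is issued and
#'   `attr(fit, "mc_unreliable")` is set.
#' @export
monte_carlo_uncertainty <- function(fit, n_iter = 200, seed = NULL) {
  stopifnot(inherits(fit, "bmfit"))
  if (n_iter == 1L) {
    warning("n_iter = 1 gives degenerate uncertainties of 0")
    fit$sd <- stats::setNames(rep(0, length(fit$coefficients)),
                              names(fit$coefficients))
    return(fit)
  }
  dat <- fit$data
  b <- .bm_bounds(names(fit$par))
  wt <- 1 / dat$r1rho_sd
  draws <- with_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      y <- stats::rnorm(nrow(dat), fit$fitted, dat$r1rho_sd)
      resid_fn <- function(par) {
        pred <- .bm_predict_par(par, dat, fit$nuclei, fit$nstates,
                                fit$minor, fit$larmor_mhz, fit$delays,
                                fit$alignment_threshold)
        r <- (y - pred) * wt
        r[!is.finite(r)] <- 1e6
        r
      }
      # refits run on a fixed iteration budget; suppress the maxiter note
      f <- tryCatch(suppressWarnings(
        minpack.lm::nls.lm(par = fit$par, fn = resid_fn,
                           lower = b$lower, upper = b$upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 50, ftol = 1e-8, ptol = 1e-8))),
        error = function(e) NULL)
      if (is.null(f)) return(NULL)
      .bm_coef(.bm_unpack(stats::setNames(as.numeric(f$par),
                                          names(fit$par)),
                          fit$nuclei, fit$nstates, fit$minor,
                          fit$larmor_mhz))
    })
  })
  # 3-state draws can return with ES1/ES2 interchanged (the triangular
  # model is symmetric under relabelling); align each draw to the point
  # estimate by whichever assignment is closer in shift-difference space
  if (fit$nstates == 3L) {
    ref <- fit$coefficients
    nms <- names(ref)
    swap_names <- function(x) {
      nm <- names(x)
      nm2 <- gsub("ES1", "ESx", nm, fixed = TRUE)
      nm2 <- gsub("ES2", "ES1", nm2, fixed = TRUE)
      nm2 <- gsub("ESx", "ES2", nm2, fixed = TRUE)
      # the minor edge rate is symmetric under the relabelling
      nm2[nm2 == "kex_ES2_ES1"] <- "kex_ES1_ES2"
      stats::setNames(x, nm2)[nms]
    }
    dw_nms <- grep("^dw_", nms, value = TRUE)
    draws <- lapply(draws, function(d) {
      if (is.null(d)) return(NULL)
      alt <- swap_names(d)
      if (sum((alt[dw_nms] - ref[dw_nms])^2) <
          sum((d[dw_nms] - ref[dw_nms])^2)) alt else d
    })
  }
  ok <- !vapply(draws, is.null, logical(1))
  if (mean(!ok) > 0.2) {
    warning(sprintf("%d of %d Monte Carlo refits failed: ",
                    sum(!ok), n_iter),
            "uncertainties may be unreliable")
    attr(fit, "mc_unreliable") <- TRUE
  }
  M <- do.call(rbind, draws[ok])
  fit$sd <- apply(M, 2, stats::sd)
  attr(fit, "mc_draws") <- M
  fit
}

#' @export
print.bmfit <- function(x, ...) {
  cat(sprintf("%d-state Bloch-McConnell fit (%s)\n", x$nstates,
              paste(x$nuclei, collapse = ", ")))
  cat(sprintf("  chi2 = %.2f on %d observations, %d parameters; %s\n",
              x$chi2, x$n_obs, x$n_par,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  AIC = %.1f, BIC = %.1f (%d starts)\n", x$aic, x$bic,
              x$n_starts))
  cf <- x$coefficients
  if (!is.null(x$sd)) {
    cat("  parameters (+/- Monte Carlo sd):\n")
    for (i in seq_along(cf))
      cat(sprintf("    %-16s %12.5g +/- %.3g\n", names(cf)[i], cf[i],
                  x$sd[i]))
  } else {
    cat("  parameters:\n")
    for (i in seq_along(cf))
      cat(sprintf("    %-16s %12.5g\n", names(cf)[i], cf[i]))
  }
  invisible(x)
}

#' @export
coef.bmfit <- function(object, ...) object$coefficients

#' @export
fitted.bmfit <- function(object, ...) object$fitted

#' @export
residuals.bmfit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$data$r1rho - object$fitted
  if (type == "pearson") r / object$data$r1rho_sd else r
}

#' @export
deviance.bmfit <- function(object, ...) object$chi2

#' @export
summary.bmfit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients)
  if (!is.null(object$sd)) tab <- cbind(tab, `MC sd` = object$sd)
  structure(list(coefficients = tab, chi2 = object$chi2,
                 n_obs = object$n_obs, n_par = object$n_par,
                 aic = object$aic, bic = object$bic,
                 converged = object$converged, nstates = object$nstates),
            class = "summary.bmfit")
}

#' @export
print.summary.bmfit <- function(x, ...) {
  cat(sprintf("Global %d-state Bloch-McConnell fit\n\n", x$nstates))
  print(round(x$coefficients, 5))
  cat(sprintf("\nchi2 = %.2f (n = %d, k = %d), AIC = %.1f, BIC = %.1f\n",
              x$chi2, x$n_obs, x$n_par, x$aic, x$bic))
  invisible(x)
}

#' Predict from a fitted exchange model
#'
#' @param object a [bmfit()].
#' @param newdata data frame with columns `nucleus`, `power_hz`,
#'   `offset_hz` (default: the fitted conditions).
#' @param type `"r1rho"` or `"r2eff"` (the latter removes the R1
#'   contribution via [r2eff_transform()]).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.bmfit <- function(object, newdata = NULL,
                          type = c("r1rho", "r2eff"), ...) {
  type <- match.arg(type)
  nd <- newdata %||% object$data
  pred <- .bm_predict_par(object$par, nd, object$nuclei, object$nstates,
                          object$minor, object$larmor_mhz, object$delays,
                          object$alignment_threshold)
  if (type == "r1rho") return(pred)
  theta <- tilt_angle(nd$power_hz, nd$offset_hz)
  r1 <- unname(object$model$r1[nd$nucleus])
  r2eff_transform(pred, r1, theta)
}

#' Simulate datasets from a fitted model
#'
#' Parametric-bootstrap style simulation: regenerates noisy datasets from
#' the fitted exchange model on the fitted acquisition grid.
#'
#' @param object a [bmfit()].
#' @param nsim number of datasets.
#' @param seed RNG seed.
#' @param noise fractional intensity noise (default 0.015).
#' @param ... unused.
#' @return A list of [rd_dataset()]s (length `nsim`).
#' @export
simulate.bmfit <- function(object, nsim = 1, seed = NULL, noise = 0.015,
                           ...) {
  grid <- unique(object$data[, c("power_hz", "offset_hz")])
  attr(grid, "delays") <- object$delays
  with_seed(seed, {
    lapply(seq_len(nsim), function(i)
      simulate_rd_dataset(object$model, nuclei = object$nuclei,
                          grid = grid, noise = noise))
  })
}

#' Plot dispersion profiles and fit
#'
#' Displays observed and fitted \eqn{R_2 + R_{ex}} against the carrier
#' offset (kHz), one panel per nucleus, spin-lock powers colour-coded —
#' the standard presentation of off-resonance dispersion data.
#'
#' @param x a [bmfit()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.bmfit <- function(x, ...) {
  dat <- x$data
  powers <- sort(unique(dat$power_hz))
  cols <- grDevices::hcl.colors(max(3, length(powers)), "Zissou 1")
  old <- graphics::par(mfrow = c(1, length(x$nuclei)))
  on.exit(graphics::par(old))
  for (nuc in x$nuclei) {
    d <- dat[dat$nucleus == nuc, ]
    theta <- tilt_angle(d$power_hz, d$offset_hz)
    obs <- r2eff_transform(d$r1rho, x$model$r1[[nuc]], theta,
                           sd = d$r1rho_sd)
    graphics::plot(NA, xlim = range(d$offset_hz) / 1000,
                   ylim = range(obs[, "r2eff"]) + c(-1, 1),
                   xlab = expression(Omega[eff] / 2 * pi ~ "(kHz)"),
                   ylab = expression(R[2] + R[ex] ~ (s^-1)),
                   main = nuc, ...)
    for (k in seq_along(powers)) {
      i <- d$power_hz == powers[k]
      graphics::points(d$offset_hz[i] / 1000, obs[i, "r2eff"],
                       col = cols[k], pch = 19, cex = 0.7)
      o <- seq(min(d$offset_hz[i]), max(d$offset_hz[i]), length.out = 80)
      nd <- data.frame(nucleus = nuc, power_hz = powers[k], offset_hz = o)
      graphics::lines(o / 1000, predict(x, nd, type = "r2eff"),
                      col = cols[k])
    }
    graphics::legend("topright", legend = paste(powers, "Hz"),
                     col = cols[seq_along(powers)], lty = 1, cex = 0.6,
                     bty = "n")
  }
  invisible(x)
}

#' Identify the anionic state of a 3-state fit
#'
#' In G.T/U mismatch exchange the two excited states have distinct
#' chemical-shift signatures: tautomerization perturbs both the G imino
#' nitrogen and the T/U N3, whereas ionization (deprotonation of N3)
#' leaves the G imino shift almost unchanged.  The fitted triangular model
#' is symmetric under relabelling of its excited states, so the anion is
#' assigned as the excited state with the smaller chemical-shift
#' difference on the guanine imino nitrogen.
#'
#' @param fit a 3-state [bmfit()].
#' @param g_nucleus label of the guanine imino nitrogen (default the
#'   first fitted nucleus matching `"G"`).
#' @return `"ES1"` or `"ES2"`.
#' @export
anion_state <- function(fit, g_nucleus = NULL) {
  stopifnot(inherits(fit, "bmfit"), fit$nstates == 3L)
  g_nucleus <- g_nucleus %||% grep("^G", fit$nuclei, value = TRUE)[1]
  if (is.na(g_nucleus) || !g_nucleus %in% fit$nuclei)
    stop("specify 'g_nucleus' (no fitted nucleus labelled G...)",
         call. = FALSE)
  dw <- fit$model$dw
  if (abs(dw[g_nucleus, "ES1"]) < abs(dw[g_nucleus, "ES2"])) "ES1" else
    "ES2"
}
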