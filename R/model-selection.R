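#' Information-criterion model comparison
#'
#' Ranks competing fits of the same dataset by Akaike and Bayesian
#' information criteria computed from the weighted residual sum,
#' \eqn{AIC = N\ln(\chi^2/N) + 2K} and
#' \eqn{BIC = N\ln(\chi^2/N) + K\ln N}, and converts the criterion
#' differences \eqn{\Delta_i} to weights
#' \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}}.
#'
#' @param ... two or more [bmfit()] objects fitted to the identical
#'   dataset, or a single list of them.
#' @param labels optional model labels.
#' @return Data frame of class `"bm_model_comparison"` with one row per
#'   model: `n_par`, `chi2`, `aic`, `bic`, `akaike_weight`, `bic_weight`,
#'   ordered by AIC.  Weights in each column sum to 1.
#' @examples
#' \donttest{
#' ds <- simulate_rd_dataset(duplex_model("dT.rG", 7.4),
#'                           grid = default_grid(c(600, 1600), 9), seed = 2)
#' f2 <- bmfit(ds, nstates = 2)
#' f3 <- bmfit(ds, nstates = 3)
#' model_weights(f2, f3)
#' }
#' @export
model_weights <- function(..., labels = NULL) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "bmfit"))
    fits <- fits[[1]]
  if (length(fits) < 2L)
    stop("need at least two fits to compare", call. = FALSE)
  if (!all(vapply(fits, inherits, logical(1), "bmfit")))
    stop("all arguments must be 'bmfit' objects", call. = FALSE)
  ref <- fits[[1]]$data
  for (f in fits[-1]) {
    d <- f$data
    if (nrow(d) != nrow(ref) ||
        !isTRUE(all.equal(d[order(d$nucleus, d$power_hz, d$offset_hz),
                            c("nucleus", "power_hz", "offset_hz", "r1rho")],
                          ref[order(ref$nucleus, ref$power_hz,
                                    ref$offset_hz),
                              c("nucleus", "power_hz", "offset_hz",
                                "r1rho")],
                          check.attributes = FALSE)))
      stop("fits were not performed on the identical dataset",
           call. = FALSE)
  }
  labels <- labels %||% vapply(fits, function(f)
    sprintf("%d-state", f$nstates), character(1))
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  wts <- function(ic) {
    d <- ic - min(ic)
    w <- exp(-d / 2)
    w / sum(w)
  }
  out <- data.frame(model = labels,
                    n_par = vapply(fits, function(f) f$n_par, numeric(1)),
                    chi2 = vapply(fits, function(f) f$chi2, numeric(1)),
                    aic = aic, bic = bic,
                    akaike_weight = wts(aic), bic_weight = wts(bic))
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  class(out) <- c("bm_model_comparison", "data.frame")
  out
}
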