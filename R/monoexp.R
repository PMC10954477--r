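# Mono-exponential decay fitting.
#
# .monoexp_rate is the algorithmic core shared (by construction) with the
# compiled fast path: log-linear initialisation over positive intensities,
# then six Gauss-Newton refinement steps on I(t) = I0 * exp(-R t).

.monoexp_rate <- function(delays, I, want_i0 = FALSE) {
  pos <- which(I > 0)
  if (length(pos) < 2L) return(if (want_i0) c(NA_real_, NA_real_) else NA_real_)
  t <- delays[pos]; y <- log(I[pos])
  n <- length(t)
  st <- sum(t); stt <- sum(t * t); sy <- sum(y); sty <- sum(t * y)
  det <- n * stt - st * st
  if (det <= 0) return(if (want_i0) c(NA_real_, NA_real_) else NA_real_)
  R <- -(n * sty - st * sy) / det
  I0 <- exp((sy * stt - st * sty) / det)
  for (it in 1:6) {
    mu <- I0 * exp(-R * delays)
    j1 <- mu / I0
    j2 <- -delays * mu
    res <- I - mu
    a11 <- sum(j1 * j1); a12 <- sum(j1 * j2); a22 <- sum(j2 * j2)
    g1 <- sum(j1 * res); g2 <- sum(j2 * res)
    d <- a11 * a22 - a12 * a12
    if (!is.finite(d) || d <= 0) break
    I0 <- I0 + (a22 * g1 - a12 * g2) / d
    R <- R + (a11 * g2 - a12 * g1) / d
  }
  if (want_i0) c(R, I0) else R
}

#' Fit a mono-exponential decay
#'
#' Least-squares fit of \eqn{I(t) = I_0 e^{-R_{1\rho} t}} to a spin-lock
#' decay curve.  The uncertainty is estimated by a Monte Carlo procedure:
#' the fitted curve is resampled `n_mc` times with Gaussian noise of
#' standard deviation `noise_sd` and refit, and the standard deviation of
#' the refitted rates is reported.
#'
#' @param curve a `"decay_curve"` from [simulate_decay()], or a numeric
#'   vector of delays (s).
#' @param intensities peak intensities (only when `curve` is numeric);
#'   must be positive.
#' @param noise_sd intensity noise standard deviation used for the Monte
#'   Carlo error (defaults to the curve's own `noise_sd`, or 0).
#' @param n_mc number of Monte Carlo resamples (default 500).
#' @param seed optional RNG seed for the resampling.
#' @return List with `r1rho` (1/s), `sd` (1/s) and `i0`.
#' @export
fit_monoexp <- function(curve, intensities = NULL, noise_sd = NULL,
                        n_mc = 500, seed = NULL) {
  if (inherits(curve, "decay_curve")) {
    delays <- curve$delays
    I <- curve$intensities
    noise_sd <- noise_sd %||% curve$noise_sd %||% 0
  } else {
    delays <- curve
    I <- intensities
    noise_sd <- noise_sd %||% 0
  }
  if (length(delays) != length(I))
    stop("delays and intensities must have the same length", call. = FALSE)
  if (length(unique(delays)) < 2L)
    stop("at least two distinct delays are required", call. = FALSE)
  if (any(I <= 0))
    stop("intensities must be positive", call. = FALSE)
  est <- .monoexp_rate(delays, I, want_i0 = TRUE)
  if (!is.finite(est[1])) stop("mono-exponential fit failed", call. = FALSE)
  sd <- 0
  if (noise_sd > 0 && n_mc > 1L) {
    mu <- est[2] * exp(-est[1] * delays)
    rates <- with_seed(seed, {
      vapply(seq_len(n_mc), function(i) {
        .monoexp_rate(delays, mu + stats::rnorm(length(mu), 0, noise_sd))
      }, numeric(1))
    })
    sd <- stats::sd(rates[is.finite(rates)])
  } else if (noise_sd > 0 && n_mc == 1L) {
    warning("n_mc = 1 gives a degenerate uncertainty of 0")
  }
  list(r1rho = est[1], sd = sd, i0 = est[2])
}
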