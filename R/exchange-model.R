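#' Multi-state chemical-exchange model
#'
#' Defines an n-site (n = 2 or 3) chemical-exchange model between a wobble
#' ground state (GS) and up to two excited states: ES1, the rapidly
#' interconverting tautomeric species, and ES2, the anionic species.  The
#' model is parameterised the way relaxation-dispersion fits report it: state
#' populations, edge exchange rates \eqn{k_{ex} = k_f + k_b}, and per-nucleus
#' chemical-shift differences \eqn{\Delta\omega} of each excited state from
#' the ground state (in ppm, GS identically 0).  Microscopic forward/backward
#' rates follow from detailed balance on every edge
#' (\eqn{p_i k_{i \to j} = p_j k_{j \to i}}).
#'
#' @param populations numeric vector of state populations, ground state
#'   first (length 2 or 3); must be non-negative and sum to 1.
#' @param kex edge exchange rates in 1/s.  A single value for a 2-state
#'   model (the GS:ES1 edge); for a 3-state triangular model a vector of
#'   three values in the order GS:ES1, GS:ES2, ES1:ES2 (names optional).
#'   The ES1:ES2 ("minor") exchange rate may be 0.
#' @param dw chemical-shift differences from the GS in ppm: a matrix with
#'   one row per nucleus (rownames are nucleus labels) and one column per
#'   excited state, or, for a single excited state, a named numeric vector.
#' @param r1,r2 longitudinal and transverse relaxation rates in 1/s, shared
#'   across states; either a scalar or a named per-nucleus vector.
#' @param larmor_mhz Larmor frequency of the observed nucleus in MHz, used
#'   to convert ppm to rad/s (default 70.95, 15N on a 700 MHz spectrometer).
#'
#' @return An object of class `"exchange_model"`.
#' @seealso [microscopic_rates()], [simulate_decay()], [bmfit()]
#' @examples
#' m <- exchange_model(
#'   populations = c(GS = 1 - 8.3e-4, ES1 = 8.3e-4), kex = 7200,
#'   dw = c("G-N1" = 34.9, "T-N3" = 25.7))
#' m
#' microscopic_rates(m)
#' @export
exchange_model <- function(populations, kex, dw, r1 = 2, r2 = 14,
                           larmor_mhz = 70.95) {
  n <- length(populations)
  if (!n %in% 2:3)
    stop("'populations' must have length 2 (GS, ES1) or 3 (GS, ES1, ES2)",
         call. = FALSE)
  if (any(populations < 0))
    stop("populations must be non-negative", call. = FALSE)
  if (abs(sum(populations) - 1) > 1e-12)
    stop("populations must sum to 1 (tolerance 1e-12)", call. = FALSE)
  states <- c("GS", "ES1", "ES2")[seq_len(n)]
  populations <- stats::setNames(as.numeric(populations), states)

  edges <- if (n == 2L) "GS:ES1" else c("GS:ES1", "GS:ES2", "ES1:ES2")
  if (length(kex) != length(edges))
    stop(sprintf("'kex' must have %d value(s) for a %d-state model",
                 length(edges), n), call. = FALSE)
  if (any(kex < 0)) stop("exchange rates must be non-negative", call. = FALSE)
  kex <- stats::setNames(as.numeric(kex), edges)

  # normalise dw to a nuclei x excited-states matrix (ppm)
  if (is.matrix(dw)) {
    if (ncol(dw) != n - 1L)
      stop("'dw' must have one column per excited state", call. = FALSE)
    if (is.null(rownames(dw)))
      stop("'dw' matrix must have nucleus labels as rownames", call. = FALSE)
  } else {
    if (n != 2L)
      stop("for a 3-state model supply 'dw' as a nuclei x 2 matrix",
           call. = FALSE)
    if (is.null(names(dw)))
      stop("'dw' must be named by nucleus", call. = FALSE)
    dw <- matrix(dw, ncol = 1, dimnames = list(names(dw), NULL))
  }
  colnames(dw) <- states[-1]
  if (any(!is.finite(dw))) stop("'dw' must be finite", call. = FALSE)

  nuclei <- rownames(dw)
  expand <- function(x, what) {
    if (length(x) == 1L) return(stats::setNames(rep(as.numeric(x),
                                                    length(nuclei)), nuclei))
    if (is.null(names(x)) || !all(nuclei %in% names(x)))
      stop(sprintf("per-nucleus '%s' must be named for every nucleus", what),
           call. = FALSE)
    stats::setNames(as.numeric(x[nuclei]), nuclei)
  }
  r1 <- expand(r1, "r1"); r2 <- expand(r2, "r2")
  if (any(r1 < 0) || any(r2 < 0))
    stop("relaxation rates must be non-negative", call. = FALSE)
  stop_if_not_number(larmor_mhz, "larmor_mhz", positive = TRUE)

  structure(
    list(states = states, populations = populations, kex = kex, dw = dw,
         r1 = r1, r2 = r2, larmor_mhz = larmor_mhz, nuclei = nuclei),
    class = "exchange_model")
}

#' Microscopic exchange rates of a model
#'
#' Converts edge `(population, kex)` pairs into the full matrix of
#' microscopic first-order rates using detailed balance on each edge:
#' \eqn{k_{i \to j} = k_{ex,ij}\, p_j / (p_i + p_j)}.  In the 2-state limit
#' this reduces to the familiar \eqn{k_f = p_{ES} k_{ex}},
#' \eqn{k_b = p_{GS} k_{ex}}.
#'
#' @param model an [exchange_model()].
#' @return An n x n matrix `K` with `K[i, j]` the rate (1/s) from state `i`
#'   to state `j`; diagonal is zero.
#' @export
microscopic_rates <- function(model) {
  stopifnot(inherits(model, "exchange_model"))
  p <- model$populations
  n <- length(p)
  K <- matrix(0, n, n, dimnames = list(model$states, model$states))
  edge <- function(i, j, kex) {
    if (p[i] + p[j] > 0) {
      K[i, j] <<- kex * p[j] / (p[i] + p[j])
      K[j, i] <<- kex * p[i] / (p[i] + p[j])
    }
  }
  edge(1, 2, model$kex[["GS:ES1"]])
  if (n == 3L) {
    edge(1, 3, model$kex[["GS:ES2"]])
    edge(2, 3, model$kex[["ES1:ES2"]])
  }
  K
}

#' @export
print.exchange_model <- function(x, ...) {
  n <- length(x$states)
  cat(sprintf("%d-state chemical-exchange model (%s)\n", n,
              paste(x$states, collapse = " / ")))
  cat("  populations:",
      paste(sprintf("%s = %.4g", names(x$populations), x$populations),
            collapse = ", "), "\n")
  cat("  kex (1/s):  ",
      paste(sprintf("%s = %.4g", names(x$kex), x$kex), collapse = ", "), "\n")
  cat("  dw (ppm):\n")
  print(round(x$dw, 3))
  cat(sprintf("  R1 = %s 1/s, R2 = %s 1/s, Larmor = %.2f MHz\n",
              paste(sprintf("%.3g", x$r1), collapse = "/"),
              paste(sprintf("%.3g", x$r2), collapse = "/"),
              x$larmor_mhz))
  invisible(x)
}
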