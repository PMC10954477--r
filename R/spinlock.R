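#' Spin-lock condition
#'
#' One off-resonance spin-lock condition of an R1rho experiment: the
#' spin-lock power \eqn{\omega_1/2\pi} in Hz, the carrier offset
#' \eqn{\Omega_{eff}/2\pi = (\omega_{obs} - \omega_{RF})/2\pi} in Hz measured
#' relative to the ground-state resonance of the observed nucleus, and the
#' relaxation delays sampled during the spin lock.
#'
#' @param power_hz spin-lock power in Hz (> 0).
#' @param offset_hz carrier offset from the GS resonance in Hz.
#' @param delays relaxation delays in seconds (at least two, non-negative).
#' @param larmor_mhz Larmor frequency of the observed nucleus in MHz.
#' @return An object of class `"spinlock_condition"`.
#' @examples
#' sl <- spinlock_condition(1000, -500)
#' tilt_angle(sl)
#' @export
spinlock_condition <- function(power_hz, offset_hz,
                               delays = c(0, 0.04, 0.08, 0.12),
                               larmor_mhz = 70.95) {
  stop_if_not_number(power_hz, "power_hz", positive = TRUE)
  stop_if_not_number(offset_hz, "offset_hz")
  stop_if_not_number(larmor_mhz, "larmor_mhz", positive = TRUE)
  if (length(delays) < 2L || any(delays < 0) || any(!is.finite(delays)))
    stop("'delays' must be at least two non-negative values", call. = FALSE)
  structure(list(power_hz = power_hz, offset_hz = offset_hz,
                 delays = sort(as.numeric(delays)), larmor_mhz = larmor_mhz),
            class = "spinlock_condition")
}

#' Effective-field tilt angle
#'
#' Angle between the effective field and the z axis,
#' \eqn{\theta = \mathrm{atan2}(\omega_1, \Omega)}, in radians.  For
#' `power_hz > 0` the angle lies strictly in (0, pi).
#'
#' @param x a [spinlock_condition()], or a spin-lock power in Hz.
#' @param offset_hz carrier offset in Hz (only when `x` is numeric).
#' @return Tilt angle in radians.
#' @export
tilt_angle <- function(x, offset_hz = NULL) {
  if (inherits(x, "spinlock_condition")) {
    power <- x$power_hz; offset <- x$offset_hz
  } else {
    power <- x; offset <- offset_hz
  }
  atan2(2 * pi * power, 2 * pi * offset)
}

#' @export
print.spinlock_condition <- function(x, ...) {
  cat(sprintf(
    "spin lock: %.0f Hz, offset %.0f Hz (theta = %.1f deg), %d delays <= %g s\n",
    x$power_hz, x$offset_hz, tilt_angle(x) * 180 / pi,
    length(x$delays), max(x$delays)))
  invisible(x)
}
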