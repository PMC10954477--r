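#' Relaxation-dispersion dataset
#'
#' A tidy container for observed or simulated R1rho values: one row per
#' (nucleus, spin-lock power, offset) with the fitted rate and its
#' uncertainty.  Metadata (duplex label, pH, temperature, Larmor frequency
#' and the relaxation-delay grid) travel as attributes.
#'
#' @param nucleus nucleus labels.
#' @param power_hz spin-lock powers in Hz.
#' @param offset_hz carrier offsets in Hz.
#' @param r1rho observed rotating-frame relaxation rates, 1/s.
#' @param r1rho_sd their standard deviations, 1/s (must be positive).
#' @param larmor_mhz Larmor frequency in MHz.
#' @param delays relaxation-delay grid used for the underlying decays.
#' @param duplex,ph,temperature optional metadata.
#' @return A data frame of class `"rd_dataset"`.
#' @export
rd_dataset <- function(nucleus, power_hz, offset_hz, r1rho, r1rho_sd,
                       larmor_mhz = 70.95, delays = c(0, 0.04, 0.08, 0.12),
                       duplex = NULL, ph = NULL, temperature = NULL) {
  d <- data.frame(nucleus = as.character(nucleus),
                  power_hz = as.numeric(power_hz),
                  offset_hz = as.numeric(offset_hz),
                  r1rho = as.numeric(r1rho),
                  r1rho_sd = as.numeric(r1rho_sd))
  if (any(!is.finite(d$r1rho)))
    stop("non-finite r1rho values", call. = FALSE)
  if (any(d$r1rho_sd <= 0))
    stop("every record needs a positive r1rho_sd", call. = FALSE)
  if (any(d$power_hz <= 0))
    stop("spin-lock powers must be positive", call. = FALSE)
  structure(d, larmor_mhz = larmor_mhz, delays = sort(as.numeric(delays)),
            duplex = duplex, ph = ph, temperature = temperature,
            class = c("rd_dataset", "data.frame"))
}

#' @export
print.rd_dataset <- function(x, ...) {
  nuc <- table(x$nucleus)
  cat(sprintf("R1rho dataset: %d records, %d nuclei (%s)\n", nrow(x),
              length(nuc),
              paste(sprintf("%s: %d", names(nuc), nuc), collapse = ", ")))
  meta <- c(duplex = attr(x, "duplex"), ph = attr(x, "ph"),
            temperature = attr(x, "temperature"))
  if (length(meta))
    cat("  ", paste(sprintf("%s = %s", names(meta), meta), collapse = ", "),
        "\n", sep = "")
  cat(sprintf("  powers %s Hz, offsets %.0f..%.0f Hz, Larmor %.2f MHz\n",
              paste(sort(unique(x$power_hz)), collapse = "/"),
              min(x$offset_hz), max(x$offset_hz), attr(x, "larmor_mhz")))
  NextMethod()
}

# subsetting keeps the metadata
#' @export
`[.rd_dataset` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("larmor_mhz", "delays", "duplex", "ph", "temperature",
                "truth", "noise", "seed"))
      attr(out, a) <- attr(x, a)
    class(out) <- class(x)
  }
  out
}
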