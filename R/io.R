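# Plain-text input/output: delimited R1rho tables and JSON results.

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an R1rho table
#'
#' Reads a delimited (TSV or CSV, by extension) relaxation-dispersion
#' table in either of two schemas: per-delay peak intensities
#' (`nucleus, spinlock_hz, offset_hz, delay_s, intensity[, noise_sd]`),
#' which are reduced to R1rho per condition with [fit_monoexp()], or
#' pre-computed rates (`nucleus, spinlock_hz, offset_hz, r1rho,
#' r1rho_err`).  Duplicate (nucleus, power, offset) rows in the rate
#' schema are kept and flagged as replicates.
#'
#' @param path file path.
#' @param larmor_mhz Larmor frequency to attach to the dataset.
#' @param n_mc Monte Carlo resamples for the intensity-schema R1rho
#'   uncertainties.
#' @param seed optional RNG seed for those resamples.
#' @return An [rd_dataset()].
#' @export
read_rd_table <- function(path, larmor_mhz = 70.95, n_mc = 500,
                          seed = NULL) {
  d <- .read_delim_auto(path)
  rate_cols <- c("nucleus", "spinlock_hz", "offset_hz", "r1rho",
                 "r1rho_err")
  int_cols <- c("nucleus", "spinlock_hz", "offset_hz", "delay_s",
                "intensity")
  if (all(rate_cols %in% names(d))) {
    if (any(d$r1rho_err < 0))
      stop("negative r1rho_err in ", path, call. = FALSE)
    key <- paste(d$nucleus, d$spinlock_hz, d$offset_hz)
    if (anyDuplicated(key))
      message(sum(duplicated(key)),
              " duplicate (nucleus, power, offset) rows kept as replicates")
    out <- rd_dataset(d$nucleus, d$spinlock_hz, d$offset_hz, d$r1rho,
                      d$r1rho_err, larmor_mhz = larmor_mhz)
  } else if (all(int_cols %in% names(d))) {
    key <- interaction(d$nucleus, d$spinlock_hz, d$offset_hz, drop = TRUE)
    rows <- lapply(split(d, key), function(g) {
      ns <- if ("noise_sd" %in% names(g)) g$noise_sd[1] else 0
      f <- fit_monoexp(g$delay_s, g$intensity, noise_sd = ns, n_mc = n_mc,
                       seed = seed)
      data.frame(nucleus = g$nucleus[1], power_hz = g$spinlock_hz[1],
                 offset_hz = g$offset_hz[1], r1rho = f$r1rho,
                 r1rho_sd = max(f$sd, 1e-6))
    })
    g1 <- d[!duplicated(key), ]
    delays <- sort(unique(d$delay_s))
    out <- do.call(rbind, rows)
    out <- rd_dataset(out$nucleus, out$power_hz, out$offset_hz, out$r1rho,
                      out$r1rho_sd, larmor_mhz = larmor_mhz,
                      delays = delays)
  } else {
    missing1 <- setdiff(rate_cols, names(d))
    missing2 <- setdiff(int_cols, names(d))
    stop(sprintf(
      "unrecognised header in %s: need %s (rate schema, missing %s) or %s (intensity schema, missing %s)",
      path, paste(rate_cols, collapse = ", "),
      paste(missing1, collapse = ", "),
      paste(int_cols, collapse = ", "),
      paste(missing2, collapse = ", ")), call. = FALSE)
  }
  message(sprintf("read %d R1rho records for %d nuclei from %s",
                  nrow(out), length(unique(out$nucleus)), basename(path)))
  out
}

#' Write an R1rho table
#'
#' Writes an [rd_dataset()] as a delimited rate-schema table readable by
#' [read_rd_table()].
#'
#' @param data an [rd_dataset()].
#' @param path output path (`.csv` writes comma-separated, anything else
#'   tab-separated).
#' @return `path`, invisibly.
#' @export
write_rd_table <- function(data, path) {
  out <- data.frame(nucleus = data$nucleus, spinlock_hz = data$power_hz,
                    offset_hz = data$offset_hz, r1rho = data$r1rho,
                    r1rho_err = data$r1rho_sd)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.serialize_result <- function(x) {
  if (inherits(x, "bmfit")) {
    list(type = "bmfit", nstates = x$nstates, nuclei = as.list(x$nuclei),
         coefficients = as.list(x$coefficients),
         sd = if (!is.null(x$sd)) as.list(x$sd),
         chi2 = x$chi2, n_obs = x$n_obs, n_par = x$n_par,
         aic = x$aic, bic = x$bic, converged = x$converged,
         n_starts = x$n_starts, larmor_mhz = x$larmor_mhz)
  } else if (inherits(x, "hhfit")) {
    list(type = "hhfit", pka = x$pka, pka_sd = x$pka_sd,
         dd_protonated = x$dd_protonated,
         dd_deprotonated = x$dd_deprotonated, n = nrow(x$data))
  } else if (inherits(x, "flux_result")) {
    list(type = "flux_result", k2 = x$k2, f_A = x$f_A, f_T = x$f_T,
         F_T = x$F_T, F_A = x$F_A, populations = as.list(x$populations),
         fluxes = as.list(x$fluxes))
  } else if (inherits(x, "exchange_model")) {
    list(type = "exchange_model",
         populations = as.list(x$populations), kex = as.list(x$kex),
         dw = as.data.frame(x$dw), nuclei = as.list(x$nuclei),
         r1 = as.list(x$r1), r2 = as.list(x$r2),
         larmor_mhz = x$larmor_mhz)
  } else stop("unsupported result type: ", paste(class(x), collapse = "/"),
              call. = FALSE)
}

#' Write a result object as JSON
#'
#' Serialises a [bmfit()], [hhfit()], [relative_flux()] result or
#' [exchange_model()] to schema-versioned JSON (the schema version is the
#' package version), recording the RNG seed when one is known.
#'
#' @param x the result object.
#' @param path output path.
#' @param seed RNG seed to record (defaults to the object's, if any).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, seed = NULL) {
  payload <- .serialize_result(x)
  payload$schema_version <-
    as.character(utils::packageVersion("rdflux"))
  payload$seed <- seed %||% (if (!is.null(x$seed)) x$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON result written by [write_results()]
#'
#' @param path file path.
#' @return A list with the serialised fields; numeric vectors are
#'   restored with names.
#' @export
read_results <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(out$type, "exchange_model")) {
    dw <- as.matrix(out$dw)
    rownames(dw) <- unlist(out$nuclei)
    out$dw <- dw
  }
  out
}
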