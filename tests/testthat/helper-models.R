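# shared fixtures (built in code, no stored data)

two_state_model <- function(p_es = 8.3e-4, kex = 7200,
                            dw = c("G-N1" = 34.9, "T-N3" = 25.7),
                            r1 = 2, r2 = 14) {
  exchange_model(c(1 - p_es, p_es), kex, dw, r1 = r1, r2 = r2)
}

three_state_model <- function() duplex_model("dG.rU", 7.4)

small_grid <- function(powers = c(600, 1600), n_offsets = 9)
  default_grid(powers = powers, n_offsets = n_offsets)

# random small exchange models for property-style checks
random_model <- function(nstates = 2) {
  p_es <- stats::runif(nstates - 1, 5e-4, 5e-2)
  p <- c(1 - sum(p_es), p_es)
  kex <- stats::runif(if (nstates == 2) 1 else 3, 500, 3e4)
  dw <- matrix(stats::runif(nstates - 1, -40, 40), nrow = 1,
               dimnames = list("N", NULL))
  exchange_model(p, kex, dw, r1 = stats::runif(1, 1, 3),
                 r2 = stats::runif(1, 8, 25))
}

# jump-chain (Gillespie) first-passage oracle for the flux partition:
# simulate single molecules from GS until absorption into MIS and record
# whether the last state visited was the anion (ES2) or the tautomer (ES1)
gillespie_fa <- function(scheme, k2, n_absorb = 2000) {
  r <- scheme$rates
  W <- rbind(
    GS  = c(0, r$k_gs_es1, r$k_gs_es2, 0),
    ES1 = c(r$k_es1_gs, 0, r$k_es1_es2, k2),
    ES2 = c(r$k_es2_gs, r$k_es2_es1, 0, k2))
  cnt <- c(ES1 = 0, ES2 = 0)
  s <- 1L
  n <- 0L
  while (n < n_absorb) {
    nxt <- sample.int(4L, 1L, prob = W[s, ])
    if (nxt == 4L) {
      cnt[s - 1L] <- cnt[s - 1L] + 1L
      n <- n + 1L
      s <- 1L
    } else s <- nxt
  }
  100 * cnt[["ES2"]] / sum(cnt)
}
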