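# rdflux

Wobble G·T and G·U mismatches occasionally masquerade as Watson–Crick
pairs by tautomerizing or ionizing, and these short-lived
Watson–Crick-like states are the chemical intermediates behind many
replication, transcription and translation errors.  Off-resonance ¹⁵N
R1ρ relaxation-dispersion NMR can detect them at populations of ~0.1%
and lifetimes of microseconds.  **rdflux** is an R package for the
complete quantitative chain used in such studies, with the RNA:DNA
hybrid duplexes dT·rG and dG·rU as built-in model systems:

* **Forward simulation** of spin-lock decay curves under n-site
  Bloch–McConnell exchange, and **global fitting** of R1ρ datasets to
  2-state and triangular 3-state exchange models
  (`bmfit()`), with shared populations/rates across nuclei, Monte-Carlo
  uncertainties and AIC/BIC model weights.
* **pKa determination** from ¹³C/¹⁵N chemical-shift titrations
  (`hhfit()`) and from excited-state populations (`apparent_pka()`).
* **pH extrapolation** of the anionic excited state (`model_at_ph()`).
* An **equilibrium kinetic-flux model** that partitions misincorporation
  flux between the tautomeric and anionic pathways (`relative_flux()`,
  `k2_sweep()`).
* **Synthetic-data generators** (`duplex_model()`,
  `simulate_rd_dataset()`, `simulate_titration()`) that emulate the real
  acquisition grid and noise, so every stage is testable end to end.

The intended users are NMR spectroscopists and computational biophysicists
analysing relaxation-dispersion data of nucleic acids, and anyone who
wants to reproduce or perturb the flux arithmetic connecting measured
exchange parameters to error rates.

## The models in brief

Magnetization of each exchanging state evolves under the Bloch–McConnell
generator (spin lock ω₁ along x, per-state offset Ω + Δω, shared R₁/R₂,
detailed-balance exchange rates k_f = p_ES·k_ex, k_b = p_GS·k_ex).
Observed profiles are reported as
(R₂ + R_ex) = (R1ρ − R₁cos²θ)/sin²θ with θ the effective-field tilt.
Titrations follow the Henderson–Hasselbalch form with weighted-CSP
reduction Δδ_obs = √((0.341·Δδ₁₃C)² + (0.154·Δδ₁₅N)²), and the flux
model composes serial (harmonic) and parallel (additive) pathway fluxes
p_i·k_ij at the exchange equilibrium, giving the anionic share
f_A = 100·F_A/(F_T + F_A).  Details and all conventions are in the
vignette (`vignettes/relaxation-dispersion-flux.Rmd`).

## Worked example

Simulate a noisy dispersion dataset from the dT·rG ground truth and refit
it globally:

```r
library(rdflux)
truth <- duplex_model("dT.rG", 7.4)
ds <- simulate_rd_dataset(truth, seed = 11)
fit <- bmfit(ds, nstates = 2)
fit
#> 2-state Bloch-McConnell fit (G-N1, T-N3)
#>   chi2 = 117.79 on 130 observations, 8 parameters; converged
#>   AIC = 3.2, BIC = 26.1 (4 starts)
#>   parameters:
#>     p_ES1              0.00080254
#>     kex_GS_ES1             6782.4
#>     dw_ES1_G-N1            35.015
#>     dw_ES1_T-N3            25.276
#>     r1_G-N1                2.0352
#>     r1_T-N3                2.0045
#>     r2_G-N1                14.268
#>     r2_T-N3                14.333
```

The generating values (p_ES = 8.3×10⁻⁴, k_ex = 7200 s⁻¹, Δω = 34.9/25.7
ppm) are recovered within the Monte-Carlo uncertainties
(`monte_carlo_uncertainty(fit)`).  Feeding fitted parameters into the
flux model:

```r
sc <- scheme_from_model(duplex_model("dG.rU", 7.4), k2 = 100)
relative_flux(sc)
#> Misincorporation flux at k2 = 100 1/s
#>   f_A = 39.0% (anionic), f_T = 61.0% (tautomeric)
#>   F_T = 0.366 1/s, F_A = 0.234 1/s
#>   equilibrium populations: GS = 0.9969, ES1 = 0.0019, ES2 = 0.0012, MIS = 0
```

i.e. at a polymerase-like closure rate, roughly 40% of dG·rU
misincorporation flux is carried by the anionic Watson–Crick-like state.

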