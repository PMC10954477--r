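---
title: "From spin-lock decays to misincorporation flux: the models behind rdflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spin-lock decays to misincorporation flux: the models behind rdflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(rdflux)
```

rdflux models the chemistry of G·T/U mismatches in nucleic-acid duplexes:
the dominant wobble geometry (the ground state, GS) exchanges on the
microsecond–millisecond timescale with two sparsely populated
Watson–Crick-like excited states — a pair of rapidly interconverting enol
tautomers (ES1) and an anionic, N3-deprotonated species (ES2).  The package
covers the full quantitative chain used to characterise these dynamics and
their consequences: forward simulation and global fitting of off-resonance
¹⁵N R1ρ relaxation-dispersion data, pKa determination, pH extrapolation of
the anionic state, and an equilibrium kinetic-flux model that asks what
fraction of misincorporation events proceeds through each excited state.

## The spin-dynamics forward model

Under an off-resonance spin lock of amplitude $\omega_1$ applied at carrier
offset $\Omega$ from the observed ground-state resonance, the magnetization
of each exchanging state evolves under a Bloch–McConnell generator: per
state, precession about $z$ at the state's offset, nutation about $x$ at
$\omega_1$, transverse relaxation $R_2$ and longitudinal relaxation $R_1$;
states are coupled by first-order exchange acting identically on all three
magnetization components.  All states share one $R_1$ and one $R_2$, the
convention under which the published exchange parameters are defined.

Conventions that matter:

* **Shift differences.** $\Delta\omega$ is the excited-state resonance
  position relative to the GS ($\omega_{GS} = 0$), in ppm, converted to
  rad/s via the ¹⁵N Larmor frequency (default 70.95 MHz, a 700 MHz
  spectrometer).  With this sign convention a state at $+\Delta\omega$
  produces its dispersion maximum at carrier offset $-\Delta\omega$, which
  the test suite verifies numerically.
* **Microscopic rates.** Fits are parameterised by populations and edge
  exchange rates $k_{ex} = k_f + k_b$; microscopic rates follow from
  detailed balance on each edge, $k_{i \to j} = k_{ex,ij}\,p_j/(p_i+p_j)$,
  which reduces to $k_f = p_{ES} k_{ex}$ in the 2-state limit.
* **Relaxation model.** The generator is homogeneous (decay toward zero,
  no thermal-recovery term).  Over spin-lock periods of at most 120 ms and
  with $R_1$ a free parameter this is the standard treatment.
* **Initial magnetization.** The experiment's equilibration element is
  modeled by distributing magnetization across states according to their
  equilibrium populations along a common axis: the GS effective field in
  slow exchange, the population-average effective field in fast exchange.
  The switch is controlled by $k_{ex}/|\Delta\omega|$ of the major excited
  state with a default threshold of 5 (`alignment_threshold`), a
  configurable choice because the conventional cutoff is not numerically
  standardised.  For all duplex fixtures in this package the ratio is
  below 0.7, so the GS-field branch is the one exercised.
* **R1ρ extraction.** Simulated R1ρ is defined operationally, exactly as
  for measured data: propagate the magnetization to the experiment's delay
  grid (matrix exponential via eigendecomposition; a compiled
  RcppArmadillo path reproduces the reference R implementation to
  machine precision and is used inside fits) and fit a mono-exponential
  to the projected intensities.  This keeps the forward model and the
  data-reduction step consistent, so the no-noise round trip is exact.
  The mono-exponential fitter is a log-linear initialisation plus
  Gauss–Newton refinement; its uncertainty comes from Monte-Carlo
  resampling of the intensities at the curve's noise level (default 500
  resamples).

A closed-form oracle, the fast-exchange limit
$R_{ex} = p_{GS} p_{ES} \Delta\omega^2 k_{ex}/(k_{ex}^2+\omega_{eff}^2)$,
and an adaptive-step ODE integration of the same generator serve as
independent checks in the test suite; they are never used in fitting.

```{r profile, fig.alt = "Dispersion profiles of the dG.rU model"}
m <- duplex_model("dG.rU", 7.4)
offs <- seq(-7000, 7000, length.out = 121)
plot(offs / 1000, r2eff_transform(
  r1rho_profile(m, "U-N3", rep(2000, 121), offs), 2,
  tilt_angle(rep(2000, 121), offs)), type = "l",
  xlab = "offset (kHz)", ylab = expression(R[2] + R[ex] ~ (s^-1)),
  main = "U-N3, 2000 Hz spin lock")
abline(v = -c(36, 58) * 70.95 / 1000, lty = 3)
```

The two dotted lines mark $-\Delta\omega$ of the tautomeric (36 ppm) and
anionic (58 ppm) excited states; both produce resolved dispersion maxima.

## Global fitting and its conditioning

`bmfit()` fits observed R1ρ values for one or several nuclei by weighted
least squares, sharing populations and exchange rates across nuclei while
fitting per-nucleus $\Delta\omega$, $R_1$ and $R_2$.  Populations and
rates are optimised on a log10 scale inside box bounds
($10^{-6} \le p_{ES} \le 0.1$, $10^2 \le k_{ex} \le 10^6$ s⁻¹,
$|\Delta\omega| \le 100$ ppm, chosen generously around the physically
plausible range); optimisation is Levenberg–Marquardt from multiple
starts.  Starts are built from the data: $\Delta\omega$ from the position
of the dispersion maximum, $R_1$/$R_2$ from the profile floor, and a
coarse grid over populations and rates.  For 3-state fits the tautomer is
seeded from a 2-state pre-fit and the second state is scanned over a
coarse $\Delta\omega$ grid (±60 ppm in 15 ppm steps, plus the strongest
residual-dispersion peaks).  Because an unrefined extra dispersion peak
usually *raises* the residual sum before optimisation, candidates are not
pruned on their initial residuals alone: for every distinct candidate
shift of every nucleus the best-scoring combination is kept, a short
Levenberg–Marquardt stage refines this diverse pool, and full
optimisation runs from the best refined candidates.  Ties are broken
toward the smaller ground-state exchange rate, for reproducibility.

Parameter uncertainties use the standard Monte-Carlo scheme: each observed
R1ρ is resampled from a normal distribution centred on its fitted value
with the observed standard deviation, and the fit is repeated from the
best-fit parameters.  Because the triangular 3-state model is symmetric
under relabelling of its excited states, each Monte-Carlo draw is aligned
to the point estimate by whichever label assignment is closer in
$\Delta\omega$ space before uncertainties are computed.

Two properties of the 3-state problem deserve emphasis, because they are
intrinsic to the science rather than artifacts of this implementation:

* **Label symmetry.** Nothing in the likelihood distinguishes "ES1" from
  "ES2".  Physical identity comes from the chemical-shift signature:
  deprotonation at T/U-N3 barely perturbs the guanine imino nitrogen,
  while tautomerization perturbs both nuclei strongly.  `anion_state()`
  encodes exactly this assignment rule.
* **Weak identifiability of the population split.** With minor (ES1:ES2)
  exchange present, the data tightly constrain the combined excited-state
  population and the products $p \cdot \Delta\omega^2$, but the split
  between the two states is soft: statistically near-equivalent optima
  can place noticeably different populations (and shift differences) on
  the anionic state, mirroring the ~±50% population uncertainties
  reported for such fits.  Recovery tests are therefore phrased in units
  of the combined uncertainty rather than as tight relative errors, and
  single-dataset point estimates should be read with their Monte-Carlo
  uncertainties.

Model choice between 2-state and 3-state fits uses information-criterion
weights computed from the weighted residual sum:
$AIC = N\ln(\chi^2/N) + 2K$, $BIC = N\ln(\chi^2/N) + K\ln N$,
$w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$ (`model_weights()`).  The
Gaussian-likelihood variant with known per-point errors differs only by a
data-independent constant within a comparison on the same dataset, so the
residual-variance form is used.

## pKa determination

Titration series are reduced to a combined chemical-shift perturbation
$\Delta\delta_{obs} = \sqrt{(0.341\,\Delta\delta_{13C})^2 +
(0.154\,\Delta\delta_{15N})^2}$ relative to the lowest-pH (protonated)
point and fitted to a single-site Henderson–Hasselbalch transition with
the pKa and the two endpoint shifts free (`hhfit()`).  Endpoints are
fitted rather than pinned to the observed extremes because the highest pH
sampled need not be fully deprotonated.  No Hill coefficient is included:
the underlying equilibrium is a single deprotonation.  Uncertainties are
taken from the covariance matrix of the nonlinear fit.

The complementary route goes through dispersion-derived populations: at a
single pH the apparent pKa of the anionic transition is
$pK_a^{app} = pH - \log_{10}\!\big(p_{anion}/(p_{wobble}+p_{tautomer})\big)$
(`apparent_pka()`), and conversely the anionic population at any pH is
$p_{ES2} = 10^{pH-pK_a^{app}}/(1+10^{pH-pK_a^{app}})$
(`anion_population()`).

## pH extrapolation

pH-series dispersion measurements established two empirical regularities
which this module adopts as assumptions: tautomer kinetics are pH
independent, and for the anion it is the forward rate that carries the pH
dependence while the backward rate is constant (a late, anion-like
transition state).  `model_at_ph()` therefore retargets a characterised
model to another pH either (i) from the apparent pKa with the backward
rate held fixed, or (ii) by scaling the forward rate with the ln-linear
relation $\ln k = a\,pH + b$.  The default slope $a = \ln 10$ corresponds
to hydroxide-mediated deprotonation and is consistent with the observed
~2.5-fold rise of the dG·rU anionic forward rate over 0.4 pH units; the
slope is configurable because the reference value was fitted on an
external dataset not reproduced here.  The two routes agree on all flux
conclusions (tested to within 5 percentage points of $f_A$); extrapolation
is intended for the pH 6–9 neighbourhood of the measurements.

## The equilibrium flux model

Misincorporation is modeled as binding (optional), wobble/Watson–Crick-like
exchange, and a downstream step $k_2$ (polymerase conformational closure)
acting equally on both Watson–Crick-like states, with reverse rate
$k_{-2}$ (default equal to $k_2$; because the partition is evaluated at
the pre-catalytic exchange equilibrium, $k_{-2}$ does not enter it).  Four routes lead
into the misincorporated state: GS→ES1→MIS, GS→ES2→ES1→MIS, GS→ES2→MIS
and GS→ES1→ES2→MIS.  Each serial route's flux is the harmonic sum of its
step fluxes $p_i k_{i\to j}$, parallel routes add, and the anionic share
is $f_A = 100\,F_A/(F_T+F_A)$.

The step fluxes use the equilibrium populations of the exchange network
itself (obtained by integrating the scheme with $k_2 = k_{-2} = 0$; a
stiff solver integrates to 10 s, far beyond the ~5 ms relaxation time, and
the derivative norm is checked).  These are the populations the NMR
experiment measures, and with them the partition interpolates exactly
between its two limits: the thermodynamic limit
$f_A \to p_{ES2}/(p_{ES1}+p_{ES2})$ as $k_2 \to 0$ and, without minor
exchange, the kinetic limit
$f_A \to k_{GS\to ES2}/(k_{GS\to ES1}+k_{GS\to ES2})$ as
$k_2 \to \infty$.  Solving the full system including a fast catalytic
step instead would distort the stationary populations (the ES1→MIS→ES2
cycle violates detailed balance) and break both limit laws, so rdflux
deliberately separates the pre-catalytic equilibrium from the flux
algebra.  Against an exact stochastic first-passage simulation of the
same network (see the test helpers) the serial/parallel composition
agrees to well under 2 percentage points for $k_2$ up to a few hundred
s⁻¹ — the range of polymerase conformational-closure rates — and drifts
slowly above that, a known cost of composing near-equilibrium step
fluxes.

```{r sweep, fig.alt = "Flux partition versus k2 for both hybrids"}
sw_gu <- k2_sweep(scheme_from_model(duplex_model("dG.rU", 7.4)))
m74 <- model_at_ph(duplex_model("dT.rG", 7.8), 7.4, pka_app = 11.5)
sw_tg <- k2_sweep(scheme_from_model(m74))
plot(sw_gu$k2, sw_gu$f_A, log = "x", type = "l", ylim = c(0, 60),
     col = "forestgreen", lwd = 2, xlab = expression(k[2] ~ (s^-1)),
     ylab = expression(f[A] ~ "(%)"))
lines(sw_tg$k2, sw_tg$f_A, col = "purple", lwd = 2)
legend("topleft", c("dG.rU pH 7.4", "dT.rG pH 7.4 (extrapolated)"),
       col = c("forestgreen", "purple"), lwd = 2, bty = "n")
```

## What the synthetic data do and do not emulate

`simulate_rd_dataset()` reproduces the full measurement chain on the
acquisition design of the real experiment: spin-lock powers 400–2000 Hz,
offsets spanning ±3.5 times each power (13 per power by default), delays
{0, 40, 80, 120} ms, Gaussian intensity noise of 1.5% of the initial
intensity added to every point, mono-exponential reduction and
Monte-Carlo per-point errors.  Ground-truth models for the two hybrid
duplexes (`duplex_model()`) carry the central published parameter values;
$R_1 = 2$ s⁻¹ and $R_2 = 14$ s⁻¹ are typical imino-¹⁵N values at this
field and temperature, chosen once since the measured values appear only
in supplementary material.  The anionic ¹⁵N shifts of dT·rG were never
determined experimentally; its pH 7.8 fixture reuses the dG·rU anion
shifts as a synthetic stand-in (no downstream calculation consumes them).

Not emulated: per-resonance optimisation of the offset/delay lists,
radiofrequency field inhomogeneity, spectrometer drift and phase noise,
and any ¹³C dispersion.  Passing round-trip tests therefore demonstrates
correctness and statistical calibration of the estimation chain under an
idealized but realistic noise model — not instrument-level fidelity.

Problem sizes throughout the tests are chosen for desk-scale runtimes:
reduced grids (two powers, 7–9 offsets) for the heavier fitting studies,
the full default grid for the headline round trips, 40–200 Monte-Carlo
iterations depending on the role of the uncertainty in the test.

## Numerical choices and degenerate inputs

* Matrix exponentials use eigendecomposition with a scaling-and-squaring
  fallback for (numerically) defective generators.
* A zero step flux anywhere in a serial chain yields zero pathway flux by
  continuity, never an error; a total flux of zero makes the partition
  undefined and raises one.
* Mono-exponential fits require at least two distinct delays and positive
  intensities; the low-population regime simulated here keeps late-delay
  intensities far above the noise floor.
* Titration fits warn when the fitted transition lies outside the sampled
  pH range (non-identifiable design), and species populations outside
  [0, 1] from noise are clamped with a warning.
* All stochastic routines (noise injection, Monte-Carlo resampling,
  simulation of fitted models) take explicit seeds and restore the
  caller's RNG state.

## Known limitations

* Exchange topologies beyond the triangular 3-state model, ¹H/¹³C
  dispersion, and temperature dependence are out of scope.
* The flux algebra is a near-equilibrium approximation (quantified
  above); for $k_2$ far above the exchange rates the stochastic
  first-passage simulation in the test helpers is the more faithful tool.
* The population split between tautomer and anion is weakly identified at
  realistic noise (see above); single-dataset point estimates of
  $p_{ES2}$ should always be read together with their Monte-Carlo
  uncertainties.
* pH extrapolation inherits the assumption of a pH-independent anionic
  backward rate (observed variations < 1.2-fold over the measured range);
  extrapolating far outside pH 6–9 is not advised.
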