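---
title: "Connecting AMPA-receptor NTD splaying to desensitization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connecting AMPA-receptor NTD splaying to desensitization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntdsplay)
```

# The scientific problem

AMPA-type glutamate receptors are tetramers whose N-terminal domains
(NTDs) form a dimer-of-dimers layer on top of the ligand-binding and
transmembrane layers.  In the desensitized state the two NTD dimers can
separate ("splay"), and the strength of the NTD dimer-of-dimer interface
is thought to control how fast a receptor recovers from desensitization:
a weak interface favours splayed states, which strain the ligand-binding
layer and keep the receptor desensitized longer.

Testing that idea quantitatively requires combining three very different
measurements:

1. **Small-angle neutron scattering (SANS)** of detergent-solubilized
   receptor reports on the *ensemble* of conformations in solution, but a
   measured curve is a population average and often contaminated by a
   small aggregated fraction.
2. **Biased molecular simulations** can enumerate plausible compact and
   splayed conformations, but their populations are unreliable and must
   be re-weighted against the data.
3. **Patch-clamp electrophysiology** measures desensitization entry and
   recovery kinetics directly, via exponential fits to agonist-evoked
   currents and two-pulse recovery protocols.

`ntdsplay` implements the complete analysis chain at desk scale:
aggregate subtraction ("in silico purification"), Bayesian/maximum-
entropy (BME) ensemble reweighting against SANS data, potential-of-mean-
force (PMF) reconstruction by the weighted histogram analysis method
(WHAM) with binding free-energy extraction, exponential kinetics
fitting, and Henderson–Hasselbalch protonation arithmetic.  A seeded
synthetic-data module generates every input with the statistical
structure the analysis assumes, so the full chain is testable without
cluster-scale simulations or raw recordings.

# The forward scattering model

Conformations are coarse bead models.  The scattering intensity is the
exact Debye sum

$$I(q) = \sum_i \sum_j b_i b_j \frac{\sin(q r_{ij})}{q r_{ij}},$$

with $I(0) = (\sum_i b_i)^2$ and self-terms $b_i^2$
(`debye_intensity()`).  An optional distance-histogram evaluation (1 Å
bins with intensity-weighted bin representatives) agrees with the exact
sum to well under 0.5% for $q \le 0.5\,\mathrm{\AA}^{-1}$ and scales to
larger models.  The radius of gyration is the scattering-length-weighted
RMS distance from the weighted centroid.  Coordinates and $q$ are in Å
and Å$^{-1}$ throughout the scattering layer; the collective-variable
and free-energy layer uses nm, with `nm_to_angstrom()` as the single
conversion point.

Hydration-layer contrast is *not* modelled structurally; a scalar scale
and constant background, refit wherever a model curve meets data, absorb
contrast and incoherent level.  Absolute-scale comparison to curves from
hydration-aware profile calculators is therefore out of scope.

# In silico purification

A measured curve with an aggregated fraction is modelled as

$$I_{fit}(q) = c_{tet}\,P_{tet}(q) + c_a\,P_{tet}(q)\,S(q) + b,$$

where $P_{tet}$ is the tetramer form factor and $S(q)$ the Teixeira
mass-fractal structure factor with dimensionality fixed at $D = 2$, for
which $S(q) = 1 + 2(\xi/r_0)^2/(1 + q^2\xi^2)$.  The aggregate's
building block is the tetramer itself, so $r_0$ is fixed to the sphere
radius equivalent to the form factor's Guinier $R_g$
($r_0 = \sqrt{5/3}\,R_g$).  Only the correlation length $\xi$ is
nonlinear; it is profiled by 1-D minimization with the three amplitudes
solved in closed form at each step, which makes the fit deterministic
and immune to multi-start issues.  Negative amplitudes are clipped to
zero with a warning.

The filtered curve subtracts **only** the fitted aggregate term:
$I_{filtered} = I_{original} - I_{agg,fit}$.  The constant background
stays in the data (it is part of every later fit), and the error bars
are copied unchanged — the subtracted term is a smooth fitted model,
treated as noise-free.  This is the conservative default; subtracting a
fitted model cannot reduce the measurement's noise.

To know what fit quality a structural model can aim for, the package
estimates a model-free reduced-$\chi^2$ floor by Bayesian indirect
Fourier transformation (`ift_chi2_floor()`): a free-form $p(r)$ on
$[0, D_{max}]$ with a second-difference smoothness prior, the prior
weight chosen by a Laplace-approximation evidence over a 41-point
log-spaced grid ($10^{-2}$–$10^{18}$), $D_{max}$ refined by
golden-section search.  The reduced $\chi^2$ subtracts the effective
number of $p(r)$ parameters, $N_g = \mathrm{tr}(H^{-1}A^TWA)$, from the
degrees of freedom.  A $p(r)$ that piles up mass near $D_{max}$ signals
a too-small $D_{max}$ and is flagged.

# Prior weights and BME reweighting

Metadynamics-style biased sampling leaves each frame with a final bias
energy $V_i$; the prior weight of a frame is the Boltzmann inversion
$w^0_i \propto \exp(+V_i/kT)$ (`bias_to_weights()`).  Note this is the
exponential "inverse of the bias", not the reciprocal $1/V$: it is the
standard final-bias reweighting of a converged bias potential.

BME reweighting then minimizes

$$Q = \chi^2_r - \theta\,S_{rel}, \qquad
  S_{rel} = -\sum_i w_i \ln(w_i / w^0_i) \le 0,$$

so $-\theta S_{rel}$ penalizes divergence from the prior and $\theta$
sets the fit–entropy trade-off.  The problem is solved in the dual
parametrization $w_i \propto w^0_i \exp(-\sum_q \lambda_q I_i(q)/\sigma_q)$
(maximum-entropy form, so weights stay strictly positive) by BFGS with an
analytic gradient.  Two numerical choices matter:

* **Scale and background are refit in closed form inside every
  $\chi^2$ evaluation.**  Freezing them from a prior-calibrated first
  pass was tried and rejected: the frozen calibration biases the target
  and leaves a $\chi^2_r$ floor far above 1 even on self-generated data.
  With per-evaluation refitting (an envelope-theorem gradient keeps the
  optimization cheap), data generated from the prior-weighted average is
  fit exactly at $w = w^0$, as it must be.  $\chi^2_r$ uses $n_q - 2$
  degrees of freedom for these two parameters.
* **The dual gradient-norm tolerance is $10^{-3}$.**  With
  $\sigma$-scaled intensity features of magnitude $\sim 10^2$, the BFGS
  stationarity floor in double precision is around $10^{-4}$; the
  reported weights are converged to machine level long before that.

`theta_scan()` runs a log-spaced $\theta$ grid from large to small with
warm-started multipliers, which makes $\chi^2_r$ non-increasing as
$\theta$ decreases.  `select_theta()` picks the knee of the
$\chi^2_r$-versus-$\phi_{eff}$ L-curve, computed on a *log* $\chi^2_r$
axis: the long prior-dominated tail of the curve otherwise drags the
chord and the linear-axis knee lands one grid point too early (at
$\chi^2_r \approx 3$–4 instead of $\approx 1$ on two-state test
problems).  When an IFT floor is supplied, the smallest $\theta$ reaching
the floor is reported as well — mirroring the practice of choosing
$\theta$ so that $\chi^2_r$ matches a model-free target.  The Kish
effective sample fraction $\phi_{eff} = \exp(S_{rel})$ diagnoses how much
of the ensemble survives reweighting.

# Umbrella sampling and WHAM

`wham()` implements the standard self-consistent iteration over window
free-energy offsets, on a fixed bin grid (default 0.02 nm), until the
maximum offset change is below $10^{-6}\,kT$ (cap $10^5$ iterations).
The NTD binding free energy is read off the profile as

$$\Delta G = G(\text{bound minimum}) - \langle G \rangle_{plateau},$$

with the plateau defaulting to the last 0.5 nm of the sampled range (the
unbound reference at large separation).  Two numerical choices:

* **Bins with fewer than `min_count = 10` total samples report
  `G = NA`.**  A far-tail bin that catches one or two samples where the
  bias weight is astronomically small otherwise produces a spurious
  global minimum (observed: a 1.6 kJ/mol well misreported as 5.2
  kJ/mol).  All samples still enter the iteration; only the report is
  masked.
* Window errors are estimated by **bootstrap** (resampling within
  windows, recomputing WHAM on the same bin grid); samples are assumed
  decorrelated, which the generator's thinned Metropolis chains satisfy
  approximately but real correlated trajectories would not — an
  autocorrelation-time analysis is deliberately out of scope.

A single window with $k = 0$ degenerates to
$G = -kT\ln(\text{histogram})$ exactly, which anchors the unit tests.

# Kinetics fitting

Desensitization entry is fit as $y(t) = \sum_i A_i e^{-t/\tau_i}$ on the
segment from the detected peak (3-point-median-smoothed extremum after
stimulus onset) to the end of the agonist application, with the baseline
fixed to the pre-stimulus mean and the trace normalized to peak = 1
(amplitudes are reported on the original scale).  Fits use
Levenberg–Marquardt on log-$\tau$ with log-linear/tail-peeling starts
plus one bracketing restart.  When the order is not specified, the
second exponential is kept only if it lowers the AIC by more than 10
*and* carries at least 5% of the amplitude *and* is separated from the
first by at least 1.5-fold in $\tau$: plain AIC admits a spurious second
component in roughly 7–13% of truly monoexponential traces, while a
genuine second kinetic component at these sampling rates improves the
AIC by hundreds.  Weighted time constants use amplitude fractions,
$\tau_w = \sum A_i\tau_i/\sum A_i$, the field convention for "weighted
means".

Recovery from desensitization uses two-pulse peak ratios fitted to
$r(\Delta t) = 1 - (1 - r_0)e^{-\Delta t/\tau}$.  The zero-interval
ratio $r_0$ is free by default (bounded below by 0).  When the
conditioning pulse fully desensitizes the receptor — the regime the
generator emulates, with ratios falling to zero at short intervals —
fixing $r_0 = 0$ is physiologically justified and reduces the
estimator's SD from ~10.5% to ~7% at SNR 20; the estimator-calibration
runs therefore fix $r_0 = 0$ and adapt the interpulse intervals to the
expected $\tau$ ($\Delta t = \tau \times \{0.2 \ldots 4.5\}$), as an
experimenter adapts the protocol to the construct.

Protonation occupancies use the Henderson–Hasselbalch closed form
$f = 1/(1 + 10^{pH - pK_a})$; $pK_a$ and burial fractions are consumed
as inputs (structure-based $pK_a$ prediction is out of scope).

# What the synthetic generators emulate — and what they do not

The generator module produces every input the pipeline consumes, all
bit-reproducible under a fixed seed:

* **Toy tetramer** (`gen_toy_tetramer()`): four bead clusters at
  tetrahedron-like vertices — two "NTD dimer" clusters whose
  centre-of-mass separation is a base distance (40 Å) plus a `splay`
  offset, and two fixed anchor clusters.  Only the NTD-pair axis moves,
  isolating the one collective variable the analysis uses.  Defaults (15
  beads per cluster of radius 16 Å) give compact/splayed $R_g$ of
  roughly 31/37 Å — a smaller particle than a real receptor, chosen so
  that exact Debye sums stay fast in tests, with the same two-state
  phenomenology.
* **Ensembles** (`gen_ensemble()`): splay values are Metropolis-sampled
  from $\exp(-(G + V_{bias})/kT)$ along the NTD distance, with the bias
  recorded per frame.  The compiled sampler auto-tunes its step to a
  30–50% acceptance rate during a discarded burn-in (10% of the chain)
  and thins by 10 by default.  Thermal energies default to 2.494 kJ/mol
  (300 K) for the atomistic-analog stages and 2.686 kJ/mol (323 K) for
  the coarse-grained-analog stages, matching the two thermostat settings
  such simulations conventionally use.
* **SANS curves** (`gen_sans_dataset()`): weighted Debye average plus an
  optional fractal-aggregate term plus constant background, with
  Gaussian noise of SD
  $\sigma(q) = \mathrm{rel}\cdot I(q)\cdot(1 + c\,q_{scale}/q)$,
  $q_{scale} = 0.01\,\mathrm{\AA}^{-1}$ — relative errors that inflate
  toward low $q$ as on SANS instruments.  This noise model is an
  emulation; no instrument's error model is reproduced.  Study-condition
  defaults: 60 log-spaced points over 0.005–0.35 Å$^{-1}$, 1% relative
  noise, background 20 (about 0.5% of the forward scattering, comparable
  to the bead models' self-scattering floor — a background far below
  that floor would not be identifiable, and a real incoherent background
  is of the same order as the high-$q$ signal).
* **Umbrella windows** (`gen_umbrella_windows()`): per-window Metropolis
  under $G + \frac{1}{2}k(x - c)^2$, defaults $k = 1000$ kJ/mol/nm²
  and 0.1 nm spacing — standard pull-code restraint settings.
* **Currents and recovery series**: sums of exponentials and
  first-order recovery ratios with additive Gaussian noise, clipped to
  $[0, 1.05]$ for ratios.

Passing tests on these generators show that the *analysis layer*
recovers known truths under the stated statistical assumptions.  They do
not show robustness to what real data add: correlated MD frames,
instrument smearing, imperfect buffer subtraction, solution
polydispersity beyond a single fractal aggregate population, series
resistance and filtering artefacts in recordings.  The paper-scale
simulation numbers (cluster MD binding energies, measured patch
statistics, the measured $R_g$ range of a real receptor) are not desk-
reproducible and are not claimed.

# Problem sizes and test design

The test-suite and acceptance runs use two-state ensembles of 40–100
frames on 30–60 point $q$ grids, umbrella sets of 37 windows × 5000
samples, and 100-replicate kinetics calibrations — sizes chosen so the
entire suite completes in well under a minute while keeping Monte-Carlo
error comfortably inside the asserted tolerances (e.g. WHAM depth errors
~0.5 kJ/mol against a ±2 kJ/mol assertion).  `scripts/acceptance.R`
re-runs the same study conditions from scratch for any seed.

# Known limitations

* The aggregate model assumes a single fractal population built from the
  tetramer itself; mixed or compact aggregates would bias $c_a$ and
  $\xi$.
* $\sigma$ is copied unchanged through aggregate subtraction; the
  (small) uncertainty of the fitted aggregate parameters is not
  propagated into the filtered curve.
* WHAM assumes decorrelated window samples; no autocorrelation or
  statistical-inefficiency correction is applied.
* BME reweights against a single experiment; multi-experiment or
  iterative-refinement variants are out of scope.
* The $\chi^2_r$ denominator uses $n_q - 2$ (scale and background); if a
  reference analysis used plain $n_q$ its $\chi^2_r$ values will differ
  by a factor $n_q/(n_q-2)$.
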