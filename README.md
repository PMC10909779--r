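# ntdsplay

Ensemble, free-energy and kinetic analysis connecting N-terminal-domain
(NTD) splaying of AMPA-type glutamate receptors to desensitization.

AMPA receptors are tetramers whose two NTD dimers can separate ("splay")
in the desensitized state. A weak NTD dimer-of-dimer interface favours
splayed conformations and slows recovery from desensitization. Testing
that link requires three analyses that this package implements end to
end, at desk scale, for structural biologists and channel
physiologists:

1. **"In silico purification" of SANS data** — a measured small-angle
   neutron scattering curve contaminated by aggregates is fit as
   `I(q) = c_tet P_tet(q) + c_a P_tet(q) S(q) + b`, with `S(q)` the
   Teixeira mass-fractal structure factor (dimensionality D = 2, so
   `S(q) = 1 + 2(ξ/r₀)²/(1+q²ξ²)`), and the fitted aggregate term is
   subtracted.
2. **Bayesian/maximum-entropy (BME) ensemble reweighting** — frame
   weights of a biased simulation ensemble (priors
   `w⁰ᵢ ∝ exp(+V_bias/kT)`) are adjusted to fit the filtered curve by
   minimizing `Q = χ²_r − θ S_rel` with
   `S_rel = −Σ wᵢ ln(wᵢ/w⁰ᵢ)`, θ chosen at the knee of the
   χ²_r-vs-φ_eff trade-off, with an indirect-Fourier-transform χ²_r
   floor available as a model-free target. Scattering is computed from
   bead models with the exact Debye sum.
3. **Umbrella sampling → WHAM → ΔG** — the potential of mean force
   along the NTD distance is reconstructed by the weighted histogram
   analysis method and the NTD binding free energy is read as
   `ΔG = G(bound minimum) − ⟨G⟩_plateau`.
4. **Desensitization kinetics** — current decays are fit as
   `y = Σ Aᵢ exp(−t/τᵢ)` (order chosen automatically, weighted
   τ = Σ Aᵢτᵢ/Σ Aᵢ), two-pulse recovery as
   `r(Δt) = 1 − (1−r₀) exp(−Δt/τ)`, plus low-/neutral-pH peak ratios
   and Henderson–Hasselbalch protonation fractions.

A seeded synthetic-data module (`gen_toy_tetramer()`, `gen_ensemble()`,
`gen_sans_dataset()`, `gen_umbrella_windows()`, `gen_current_trace()`,
`gen_recovery_series()`) produces every input with the statistical
structure the analysis assumes, so the whole chain runs and is tested
without MD trajectories or raw recordings. See the vignette
(`vignettes/ntd-splaying-analysis.Rmd`) for the models, assumptions and
design decisions.

## Worked example

The bundled demo pipeline builds a two-state (compact/splayed) toy
tetramer ensemble with a 90/10 prior, simulates an aggregate-
contaminated SANS measurement of a 50/50 population, purifies and
reweights it, reconstructs a −26 kJ/mol binding PMF from umbrella
windows, and fits synthetic desensitization kinetics:

```r
library(ntdsplay)
rep <- run_pipeline(pipeline_config(seed = 11))
```

which yields (printed from the report):

```
prior splayed fraction:     0.100
posterior splayed fraction: 0.512
selected theta:             3.16
chi2r at selected theta:    1.35
mean Rg prior -> posterior: 31.5 -> 33.9 A
WHAM Delta G:               -25.4 kJ/mol (truth -26.0)
tau_entry:                  8.81 ms
tau_recov:                  16.7 ms
low-pH peak ratio:          0.116
```

Reading: BME moved the splayed population from the (wrong) 10% prior to
51% — the generator truth is 50% — at a fit quality χ²_r ≈ 1.3, and the
weighted mean radius of gyration shifted toward the splayed state
accordingly. WHAM recovered the binding free energy within 0.6 kJ/mol,
and the kinetics fits recovered the entry (8.9 ms), recovery (17 ms)
and peak-ratio (0.12) truths within noise.

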