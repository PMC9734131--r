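# cpmgx

Quantitative analysis of two-state micro-to-millisecond conformational
exchange in proteins, for NMR spectroscopists and computational
structural biologists studying transient, lowly populated states —
e.g. a lid segment that occasionally folds over a ligand-binding site.

The package covers the full quantitative chain used in such studies:

- **Forward models.** Effective relaxation rates
  R<sub>2,eff</sub>(ν<sub>cpmg</sub>) for ¹⁵N single-quantum and methyl
  ¹³C–¹H multiple-quantum CPMG experiments under two-site exchange
  A ⇌ B (populations p<sub>A</sub>, p<sub>B</sub>; k<sub>ex</sub> =
  k₁ + k₋₁), by numerical Bloch–McConnell propagation of the coherence
  through the ideal even-pulse echo train (compiled core).
- **Fitting.** `fit_dispersion()`: grid search over (k<sub>ex</sub>,
  p<sub>B</sub>) followed by a global multi-probe fit in which
  k<sub>ex</sub> and p<sub>B</sub> are shared while each probe keeps its
  shift differences |Δω| and per-field exchange-free baselines; 2%
  error floor, R<sub>ex</sub> ≥ 2 s⁻¹ inclusion filter, Monte-Carlo
  uncertainties, leave-one-probe-out jackknife.  Returns a classed model
  object with `print`, `summary`, `coef`, `predict`, `fitted`,
  `residuals`, `plot` and `simulate` methods.
- **Thermo-kinetics.** `kinetic_summary()`: microscopic rates,
  half-lives ln 2/k, ΔG = −RT ln(p_B/p_A), and Eyring barriers
  ΔG‡ = −RT ln(k·h/κk<sub>B</sub>T) with κ = 1.
- **Restraints & ensembles.** NOE distance restraints with methyl
  proton-barycenter pseudo-atoms, intensity-class bounds, satisfaction
  evaluation on multi-model bundles, and two-state partitioning
  (state-A-only / state-B-only / both / neither); Kabsch superposition,
  core-fitted region RMSD, pairwise-RMSD matrices, Ward clustering with
  automatic cluster number, medoids and spreads, RMSF profiles.
- **Trajectory monitoring.** Per-frame violation statistic
  V = (1/N) Σ max(0, d<sub>ij</sub> − d<sub>ij</sub><sup>viol</sup>)
  with thresholds ⟨d⟩ + 2σ from a reference bundle, and
  stable/transitioned/neither classification of trajectories.
- **Synthetic data.** Generators for dispersion datasets with known
  truth, two-conformation toy structures, reference bundles and
  two-state jump trajectories, so the entire pipeline runs and is
  tested without downloads.

Standard formats are read and written as plain text: dispersion CSV,
restraint TSV (plus CYANA-style `.upl` import), multi-model PDB (via
bio3d).  A thin CLI (`inst/cli/cpmgx`, or `cpmgx_cli()` in R) exposes
`simulate`, `fit-cpmg`, `thermo`, `classify-restraints`,
`monitor-violations` and `cluster-ensemble` subcommands.

## Worked example

Simulate a WT-like methyl MQ dataset (21 probes, 700 + 850 MHz, 2%
noise) at the operating point p_B = 0.032, k_ex = 2490 s⁻¹, refit it,
and read off the energy landscape:

```r
library(cpmgx)

ds  <- gen_dispersion_dataset(synthetic_truth(seed = 42))
fit <- fit_dispersion(ds, filter_rex = 2)
fit
#> Global two-state CPMG dispersion fit
#>   curves: 21   points: 672   parameters: 86
#>   k_ex      = 2486.09 s^-1
#>   p_excited = 0.03011
#>   chi2 = 576.31  (reduced 0.9835)

kinetic_summary(fit$exch)
#> Two-state thermo-kinetic summary
#>   T = 293 K, kappa = 1
#>   k_ex = 2486 s^-1, p_excited = 0.03011
#>   k1 (ground->excited)   = 74.86 s^-1   half-life 9.3 ms
#>   k-1 (excited->ground)  = 2411 s^-1   half-life 0.29 ms
#>   dG (excited - ground)  = 8.46 kJ/mol
#>   dG+ (ground -> TS)     = 61.2 kJ/mol
#>   dG+ (excited -> TS)    = 52.7 kJ/mol
```

The fitted exchange rate lands within 0.2% of the generating truth and
the minor-state population within 0.2 percentage points; the summary
converts them into rates (k₁ ≈ 75 s⁻¹ ground→excited), state
half-lives (≈ 9 ms ground, ≈ 0.3 ms excited), the stability gap between
the conformers (≈ 8.5 kJ/mol) and the Eyring barriers seen from either
side (≈ 61 and ≈ 53 kJ/mol).  `monte_carlo_errors(fit, 40, seed = 1)`
adds uncertainties; `jackknife_probes()` verifies all probes report the
same process; `plot(fit)` draws the dispersion curves.

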