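---
title: "Quantifying a transient conformation: two-state CPMG fitting, thermo-kinetics, and restraint-based ensemble analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a transient conformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmgx)
```

Proteins often sample lowly populated conformations — a few percent,
living for fractions of a millisecond — that are invisible to
conventional structure determination but functionally decisive.  A
canonical example is a lid-like segment that can fold over a ligand
binding site: the major ("ground", e.g. lid-open) and minor ("excited",
e.g. lid-closed) conformers interconvert on the micro- to millisecond
time scale.  `cpmgx` implements the quantitative machinery for
characterizing such an exchange from NMR CPMG relaxation-dispersion
data and for confronting structural ensembles and MD trajectories with
the NOE distance restraints that define each state.

## The exchange model

We assume two-site exchange A ⇌ B with forward rate $k_1$, reverse rate
$k_{-1}$, exchange rate $k_{ex} = k_1 + k_{-1}$ and minor-state
population $p_B = k_1/k_{ex} \le 0.5$.  During a constant-time CPMG
element of duration $T_{relax}$ containing an even number $n_\pi$ of
ideal refocusing pulses ($\nu_{cpmg} = n_\pi / 2T_{relax}$), the
transverse coherence of the two sites evolves under the Bloch–McConnell
operator

$$L(\Delta\omega) = \begin{pmatrix} -k_1 & k_{-1} \\ k_1 & -k_{-1} + i\Delta\omega \end{pmatrix},$$

written in the rotating frame of state A; site-independent relaxation
$R_{2,0}$ factors out and is added back as a per-field baseline.  The
package propagates the 2-vector through the explicit
delay–pulse–delay train with closed-form $2\times2$ matrix exponentials
and reports

$$R_{2,\mathrm{eff}} = -\frac{1}{T_{relax}}\,\ln\frac{|M_A(T_{relax})|}{p_A}.$$

For $^{15}$N single-quantum coherences a perfect 180° pulse conjugates
the coherence, which is equivalent to alternating the sign of
$\Delta\omega_N$ between inter-pulse segments.  For methyl
$^{13}$C–$^1$H multiple-quantum coherences the heteronuclear pulses
interconvert double- and zero-quantum frames, so the offset alternates
between $\Delta\omega_H + \Delta\omega_C$ and $\Delta\omega_H -
\Delta\omega_C$; the reported rate is the average over both coherence
pathways.  This numerical-propagation formulation is exact for ideal
pulses and avoids the branch ambiguities of closed-form
multiple-quantum expressions; the test suite checks it element-by-element
against a brute-force segment-by-segment matrix-exponential oracle and,
in the fast-exchange limit, against the Luz–Meiboom closed form.
Pulses are treated as instantaneous and on-resonance; off-resonance and
finite-power effects are out of scope.

Shift differences are supplied in ppm and converted per field with
fixed gyromagnetic-ratio magnitudes ($\gamma_N/\gamma_H = 0.10136$,
$\gamma_C/\gamma_H = 0.25144$).  Only $|\Delta\omega|$ enters the
single-quantum model; for multiple-quantum probes the *relative* sign
of $\Delta\omega_H$ against $\Delta\omega_C$ matters and is exposed as
`relative_sign` (default $+1$), since typical datasets only determine
absolute values.

## Fitting strategy

`fit_dispersion()` performs the standard two-stage analysis:

1. **Grid search** (`grid_search()`): $k_{ex}$ and $p_B$ are fixed at
   each node of a grid — by default 25 log-spaced $k_{ex}$ nodes over
   100–10000 s$^{-1}$ and 20 linear $p_B$ nodes over 0.005–0.20 — while
   every probe's shift differences and per-field baselines are freely
   optimized.  The baselines have a closed-form weighted least-squares
   solution because exchange enters additively, so each node reduces to
   a 1–2 parameter optimization per probe, solved by a bounded simplex
   in compiled code, warm-started along a snake-order sweep.
2. **Global fit**: starting at the grid arg-min, $(\log k_{ex},
   \mathrm{logit}\,2p_B)$ are refined by Nelder–Mead (relative χ²
   tolerance $10^{-8}$, at most 2000 iterations) with the per-probe
   parameters re-optimized (L-BFGS-B) at every step — a
   variable-projection decomposition.  The refined χ² never exceeds the
   best grid node's.

Uncertainties follow from parametric Monte-Carlo resampling
(`monte_carlo_errors()`, 40 repeats by default): each $R_{2,\mathrm{eff}}$
is redrawn from $\mathcal N(\hat y, \sigma)$ and refit; per-parameter
standard deviations over the repeats are reported.  Resampling is
parametric rather than residual-based, matching the error model used to
assign $\sigma$ in the first place.  `jackknife_probes()` refits with
each probe left out to confirm that all probes sense a single global
process; a probe is flagged when its removal moves $k_{ex}$ by more
than 3 Monte-Carlo standard deviations (our criterion — the procedure's
purpose is standard, the numeric threshold is not).

Data handling mirrors common practice: uncertainties are floored at 2%
of the rate (`apply_error_floor()`), and only curves with an exchange
contribution $R_{ex} \ge 2$ s$^{-1}$ (low-minus-high frequency
difference, maximum over fields) enter the global fit
(`filter_curves()`).  Unidentifiable datasets are flagged by the grid:
a surface with no structure ("flat", e.g. no shift differences) or a
near-minimum region spanning most of the population axis ("ridge", the
fast-exchange $p\,\Delta\omega^2$ degeneracy, under which populations
cannot be extracted reliably).

## From exchange parameters to an energy landscape

`kinetic_summary()` composes the thermo-kinetic chain with
$k_1 = p_B\,k_{ex}$, $k_{-1} = (1-p_B)\,k_{ex}$, half-lives $\ln 2/k$,
$\Delta G = -RT\ln(p_B/p_A)$, and Eyring activation free energies
$\Delta G^\ddagger = -RT\,\ln\!\big(k\,h/(\kappa\,k_B T)\big)$ with
transmission coefficient $\kappa = 1$.  The identity $\Delta G =
\Delta G^\ddagger_{fwd} - \Delta G^\ddagger_{rev}$ holds algebraically
and is tested numerically.  Temperatures are used as given in kelvin
(e.g. 293 K, not 293.15); energies are carried in J mol$^{-1}$ and
reported in kJ mol$^{-1}$.

```{r thermo}
kinetic_summary(exchange_params(p_excited = 0.032, k_ex = 2490,
                                temperature = 293))
```

## Restraints, ensembles, and the violation statistic

NOE cross-peaks are converted to distance bounds by qualitative
intensity classes (`derive_bounds()`): 2–4 Å and 4–6 Å for strong and
weak short-mixing-time peaks, 4–8 Å for peaks seen only at long mixing
time, 2–6 Å for amide–amide peaks, 2–8 Å for single-dataset intermethyl
peaks, and hydrogen-bond donor limits of 2 Å (H) and 3 Å (N).  The
donor pairing of the 2/3 Å limits follows the geometry (H–acceptor
shorter than N–acceptor); the source description is ambiguous on this
point.  Methyl groups are represented by the unweighted barycenter of
the three protons; $\langle r^{-6}\rangle^{-1/6}$ averaging is
available as an option for sensitivity analysis but is not the default,
because the violation statistic below is defined on barycenter
geometry.

Satisfaction on a bundle (`evaluate_on_ensemble()`) is judged on the
representative (medoid) member by default, with a fraction-of-members
rule as an option; how "satisfied by a state" should be decided across
a 20-member bundle is genuinely open, and the medoid is the least
arbitrary single-structure proxy.  Violations are upper-bound events
(lower bounds are reported but not enforced by default), with a slack
tolerance of 0.5 Å.  `partition_two_states()` classifies each restraint
as satisfied only in state A, only in state B, in both, or in neither —
the state-specificity analysis that separates restraints characteristic
of each conformation.

For trajectories, `build_violation_spec()` turns a reference bundle
into per-pair thresholds $d^{viol}_{ij} = \langle d_{ij}\rangle +
2\sigma(d_{ij})$ (population standard deviation — the bundle is the
complete reference set, not a sample), and `violation_series()` scores
each frame with

$$V = \frac{1}{N}\sum_{ij}\max(0,\; d_{ij} - d^{viol}_{ij}).$$

`classify_trajectory()` labels a run *stable* (smoothed home-state $V$
below 0.5 Å throughout), *transitioned* (over the final 20% of frames
the other state's smoothed $V$ is below 0.5 Å while the home state's
exceeds 1.0 Å), or *neither*.  The qualitative three-way behaviour is
from the underlying analysis; the numeric thresholds, 10-frame moving
average and 20% tail are this package's defaults and are all
configurable.

## Ensemble geometry

Superposition is closed-form Kabsch with a determinant guard against
reflections.  `region_rmsd()` fits on one selection and measures on
another (e.g. fit on the rigid core, residues 40–97 + 137–220, measure
on the mobile lid, residues 98–136 — the defaults mirror that usage and
are configurable).  `pairwise_rmsd_matrix()` feeds
`ward_cluster()`: Ward-linkage hierarchical clustering with the number
of clusters chosen automatically by maximal mean silhouette width over
$k = 2..10$ (ties toward smaller $k$) — the criterion behind the
"automatic" choice is unspecified in the tools this mirrors, and the
silhouette is the standard model-free choice.  Each cluster reports its
medoid (member minimizing summed RMSD to co-members) and spread (mean
member-to-medoid RMSD).  `rmsf_profile()` superposes on the mean
structure (one refinement pass) and reports per-residue fluctuations.

## Synthetic data: what it emulates, and what it does not

Every stage runs without external data through the generators:

- `gen_dispersion_dataset()` simulates multi-field dispersion profiles
  from the forward models with multiplicative Gaussian noise
  (default 2% of $R_{2,\mathrm{eff}}$, matching the error-floor
  convention).  The default conditions are the WT-like study design: 21
  methyl MQ probes, 700 and 850 MHz, 16 frequencies between 66 and
  2000 Hz in a 30 ms period, truth $p_B = 0.032$, $k_{ex} = 2490$
  s$^{-1}$ at 293 K.  Probe shift differences (0.75–2.2 ppm $^{13}$C,
  0.02–0.25 ppm $^1$H) are chosen so that every curve clears the
  $R_{ex} \ge 2$ s$^{-1}$ filter by design, as the 21 analysed
  experimental curves did.
- `gen_toy_system()` builds a two-conformation toy protein: a rigid
  helical core and a mobile strand whose state-B position is the
  state-A position rigidly displaced (default 20 Å, the order of a full
  lid rearrangement), carrying ILE-style methyl triplets so pseudo-atom
  handling exercises real naming conventions.
- `gen_reference_ensemble()` and `gen_jump_trajectory()` add isotropic
  coordinate noise around a state and a latent A/B telegraph process,
  respectively.

These synthetic data validate the *estimators*: that the fit recovers
known exchange parameters at realistic noise, that the violation
statistic and classifier recover constructed behaviours, that
clustering recovers constructed clouds.  They do not emulate spectral
artefacts (peak overlap, $t_1$ noise), correlated coordinate noise,
force-field physics, or three-state exchange, so passing tests say
nothing about those failure modes on real data.

## Numerical choices and limitations

- CPMG frequencies must correspond to an even pulse count in
  $T_{relax}$ (tolerance $10^{-3}$ relative); others are rejected
  rather than rounded silently.
- Grid-node optimizations use a bounded Nelder–Mead on
  $\Delta\omega \in [0, 10]$ ppm ($^{1}$H: $[0, 3]$ ppm) with
  multi-start at the first node only; the global stage re-polishes with
  L-BFGS-B.  Baselines are clamped at zero.
- Monte-Carlo and jackknife refits are warm-started from the optimum;
  repeats that fail to converge are dropped and counted, with a warning
  beyond 25%.
- All stochastic steps take explicit seeds and restore the caller's
  RNG state.
- Problem sizes used by the shipped checks: recovery experiments use 10
  regenerated 21-probe datasets; geometry and trajectory checks use
  30–38-residue toy systems with 10–20-member bundles and 100-frame
  trajectories — small enough to be regenerated from code on any
  machine, large enough for the statistics they test.
- Deposited-data comparisons (experimental open/closed bundles,
  archived MD snapshots) require downloads and are therefore kept
  outside the default desk-scale workflow; the geometry operations
  support them directly once files are available locally.
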