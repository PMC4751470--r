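---
title: "Modelling voltage- and flux-dependent pore block in inward rectifier K+ channels"
author: "kirblock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling voltage- and flux-dependent pore block in inward rectifier K+ channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirblock)
```

## The biological problem

Inward rectifier K⁺ channels such as Kir2.1 pass inward K⁺ current far
more readily than outward current. The rectification is not intrinsic
gating: it is produced by intracellular cations — Mg²⁺ at millimolar and
polyamines such as spermine (SPM) at micromolar concentrations — that
enter the pore from the cytoplasmic side and plug it whenever the
electrochemical gradient drives K⁺ outward. Two features make this block
richer than a textbook Woodhull blocker:

* **Flux coupling.** The apparent affinity changes most steeply around the
  K⁺ reversal potential `E_K`, not around 0 mV absolute, because the
  permeant ions themselves drag the blocker along the pore axis. Outward
  K⁺ flow pushes the blocker to the outer end of a flux-coupling segment
  (the bundle-crossing region of the inner helix) and holds it there.
* **Punch-through.** A long polyamine can, at strong depolarization,
  escape *outward* through the selectivity filter, relieving its own
  block. Mg²⁺, a compact divalent, cannot. A resident Mg²⁺ behind a bound
  SPM therefore occludes SPM's only escape route at depolarized
  potentials — the mechanistic basis of the two blockers' synergy.

`kirblock` packages a minimal kinetic model with these ingredients, a
generator of synthetic voltage-clamp experiments, and the estimators used
on real recordings of this kind.

## The kinetic scheme

States are `O` (open, conducting) plus one state per bound blocker and,
with two blockers, the doubly-occupied state. For blockers M (Mg²⁺) and S
(SPM):

```
O  ⇌  M        O  ⇌  S        M  ⇌  MS        S  ⇌  MS
```

Only `O` conducts. Transition rates at membrane voltage `V` (mV), with
thermal voltage `vt`:

* binding: `kon0 · [B] · exp(z·δ_on·V/vt)` — a Woodhull entry over a
  barrier at electrical distance `δ_on` from the inside, for an effective
  valence `z` (2 for Mg²⁺, 4 for SPM);
* unbinding to the inside:
  `koff0 · exp(−Zδ_off·V/vt) · exp(−θ·(1 + tanh((V − E_K)/vs)))`;
* punch-through (from a singly-occupied state only):
  `kexit0 · exp(zδ_exit·V/vt)`; identically zero for Mg²⁺.

The doubly-occupied state is reached by either binding order, inherits
each blocker's singly-bound unbinding rates, and has **no** punch-through:
that single structural assumption (occlusion of the outward exit)
generates the steady-state synergy, while the parallel entry paths
generate additive onset rates. No further interaction parameters are
introduced.

### The flux-coupling factor

The data motivating this model demonstrate flux dependence but contain no
equation for it, so its functional form is a design decision of this
package. We multiply the unbinding-to-inside rate by
`exp(−θ·(1 + tanh((V − E_K)/vs)))`: a saturating, `E_K`-centred factor
that equals 1 in the inward-flux limit and `exp(−2θ)` in the outward-flux
limit. Two choices deserve comment.

* **Normalization to the inward-flux limit.** Off rates are measured from
  slow-tail decays at −20 to −100 mV, where inward flux is preponderant
  and, as such measurements are usually interpreted, essentially devoid of
  flux coupling. Anchoring the factor at 1 in that limit makes the
  Woodhull parameters printed by the pipeline (`off rate(0)`, `Zδ`)
  coincide exactly with the generator constants `koff0`, `Zδ_off`; an
  `E_K`-anchored normalization would fold a constant `e^{−θ}` into every
  measured intercept and a small slope bias into `Zδ`.
* **Saturation scale `vs` = 4 mV.** A sharp kink around `E_K` keeps the
  −20…−100 mV measurement window clean (the tanh is saturated to within
  10⁻⁴ beyond ±20 mV of `E_K`) while still producing the characteristic
  steep change of apparent Kd around the reversal potential. Voltage
  protocols in this field step in 10 mV increments, so sharper structure
  would not be resolved anyway.

With this law the IR index (`Kd(−30)/Kd(+30)` in symmetric K⁺) factorizes
as `exp((Zδ_off + z·δ_on)·60/vt) · exp(2θ·tanh(30/vs))`, so `θ` is the
single knob controlling how much rectification exceeds the pure Woodhull
contribution.

### Thermal voltage

`vt` is fixed at 25 mV exactly — the convention used in every printed
rate equation in this literature — rather than RT/F ≈ 25.7 mV at room
temperature. All electrical distances reported by the package are relative
to that convention.

## Presets and their calibration

`kir_presets()` ships one versioned JSON file with the default blocker
kinetics and genotype multiplier sets.

* Mg²⁺/WT: `kon0 = 5×10⁶ M⁻¹s⁻¹`, `δ_on = 0.08`, `koff0 = 4300 s⁻¹`,
  `Zδ_off = 0.48`, no punch-through. SPM/WT: `kon0 = 10⁷ M⁻¹s⁻¹`,
  `δ_on = 0.06`, `koff0 = 50 s⁻¹`, `Zδ_off = 2.32`,
  `kexit0 = 0.002 s⁻¹` with `zδ_exit = 1`.
* The flux-coupling strengths were calibrated once, by one-dimensional
  root finding on the closed-form IR index in symmetric 100 mM K⁺, to the
  published rectification magnitudes of the two blockers (≈95 for Mg²⁺,
  ≈1.02×10⁵ for SPM): `θ_Mg = 1.5089`, `θ_SPM = 3.0123`. These two numbers
  are frozen in the preset file; they are calibration constants, not
  measurements, and the package's rectification checks are accordingly
  model-adequacy checks.
* Genotypes are multiplier sets on `kon0`, `koff0`, `Zδ_off` and `θ`
  only — barrier heights and flux coupling, never barrier positions in any
  structural sense. E224/E299 mutants slow binding and unbinding jointly
  (reproducing the strong correlation between blocking and unblocking
  kinetics across that mutant panel) and suppress `θ` (their Kd–voltage
  curves lose the kink at `E_K`). Bundle-crossing mutants reduce affinity
  and `θ` moderately. Double mutants at the segment boundaries
  (E224G/D172N, E224G/A184Q) are exact products of their singles, so their
  coupling coefficient is exactly 1; doubles inside the segment
  (E224G/G177N, E224G/M183N) carry an additional interaction factor on
  `koff0` producing a strongly negative-cooperative Ω (≈0.1–0.17 at
  +40 mV). The interaction factors are qualitative: the underlying
  published Kd values exist only in graphical form, so the presets make no
  claim to reproduce particular Ω values.

## Synthetic experiments

`simulate_sweep()` composes the model's relaxation solutions segment by
segment: the occupancy starts at the stationary distribution of the
holding level and propagates continuously across voltage steps; the
recorded current is `N · P_open(t) · i_open(V)` plus i.i.d. Gaussian
noise. The open-channel current uses the GHK constant-field form purely to
give sweeps realistic inward/outward asymmetry under asymmetric K⁺
(inward negative). Defaults: 100 channels, a permeability scale giving
±2 nA at ±100 mV in symmetric 100 mM K⁺, 0.1 ms sampling (10 kHz, the
usual digitization rate for such recordings).

What is deliberately **not** emulated: capacitive transients and leak
(analyses here concern steady states and relaxations), filter rise time,
series-resistance error, single-channel stochasticity (currents are
ensemble means — Gillespie ensembles appear only as test oracles), and
rundown/drift between sweeps. Passing the recovery tests therefore shows
the estimators are correct and noise-robust, not that they survive every
artefact of real patches.

Protocol presets follow the standard designs: a step family (hold 0 mV →
−100 mV for 20 ms → 150 ms test pulses from −150 to +100 mV in 10 mV
increments) and a two-pulse protocol (pre-pulse −100 mV → +100 mV
depolarization of variable length → negative tail pulse). Two-pulse
designs intended for off-rate (Woodhull) measurements default to 200 kHz
sampling with short 10 ms pulses: wild-type unblocking at −100 mV runs at
~3×10⁴ s⁻¹ (τ ≈ 34 µs) and simply cannot be digitized at 10 kHz. Segment
durations are constrained to integer multiples of the sample interval so
that boundaries land exactly on samples, and all window arithmetic in the
fitting code is done in integer sample counts — with 10⁵-sample grids,
accumulated binary round-off in floating-point times is otherwise enough
to shift a window boundary by one sample between sweeps.

## Estimators

* **Relaxation fits** (`fit_relaxation()`): least squares of
  `baseline + Σ aᵢ·exp(−t/τᵢ)` over one segment, after a blank of 10
  sample intervals that skips the settling instant and any very fast
  occupancy redistribution at the step. Initialization is a deterministic
  multistart: a log-spaced grid of time constants spanning (5 samples,
  half the window), scored by variable projection (amplitudes and baseline
  solved linearly), the best start polished by Levenberg–Marquardt in
  log-τ. One versus two components is decided by BIC; the published
  analyses this mirrors do not state their criterion, and BIC errs on the
  side of one component, which is the correct behaviour for the 2-state
  relaxations that dominate here. If the polish step fails (degenerate
  windows, e.g. zero amplitude), the best grid point is returned and
  flagged.
* **Hill fits** (`fit_hill()`): relative current `f = 1/(1 + [B]/Kd)`
  fitted in log-Kd with unweighted residuals on `f`; the Hill coefficient
  is fixed at 1 (one-to-one binding), with a free-slope option kept
  off-pipeline as a diagnostic. A dose series that never crosses
  `f = 0.5` warns; one showing essentially no or complete block is
  unidentifiable and errors. Standard errors come from the Jacobian by the
  delta method.
* **Kd–voltage curves** (`kd_curve()`): per-voltage Hill fits restricted
  to the window where the one-to-one fit is meaningful (more positive
  than −60 mV in symmetric K⁺, −100 mV in 20/100 asymmetric K⁺);
  voltages near the reversal potential, where the control current
  vanishes, are skipped with a recorded reason. The IR index interpolates
  log-Kd linearly if ±30 mV are not grid points and flags that it did.
  `kd_shift()` finds the displacement minimizing the summed squared
  log-Kd difference over the overlapping support, by golden-section
  refinement of a 0.1 mV grid scan; negative shifts mean the second curve
  is displaced toward negative voltages.
* **Rate analyses** (`rate_vs_conc()`, `fit_rate_voltage()`,
  `woodhull_table()`): `1/τ = kon·[B] + koff` gives on-rate constants as
  OLS slopes and off rates as intercepts. Rate–voltage fits offer two
  estimators: log-linear regression of `ln(rate)` on `V` (default; exact
  on noise-free data and standard for Woodhull analyses) and a direct
  nonlinear exponential fit on the rate scale. The distinction matters
  when the input rates are few and rounded: fitting the five published
  on-rate constants (+70…+110 mV), only the nonlinear estimator
  reproduces the published prefactor, exponent coefficient and electrical
  distance at their printed precision, which is why the acceptance script
  uses it for that computation — it is evidently the estimator behind the
  published figure. `woodhull_table()` removes the `kon·[B]` contribution
  from measured tail rates via the concentration-series intercept whenever
  a voltage carries ≥3 concentrations, mirroring the intercept logic of
  the rate-versus-concentration analysis; with fewer concentrations it
  falls back to the raw `1/τ` and inherits its small positive bias.
* **Cycle and synergy analyses**: Ω is the ratio of the product of
  single-mutant Kd fold-changes to the double mutant's fold-change,
  invariant to Kd units and mutation order, with an "additive" verdict
  band of [0.5, 2] by default. For two-blocker steady states the package
  reports **two** null models — independent sites (`f_A·f_B`) and
  mutually exclusive competition (`1/(1 + (1/f_A − 1) + (1/f_B − 1))`) —
  and flags synergy only when the measured `f_both` falls below both,
  beyond the propagated error; asserting synergy against a single
  unstated null would be ambiguous, and the two standard nulls bracket
  it. Onset-rate additivity compares `1/τ` of the both-blockers decay
  with the sum of the single-blocker values at a default 20% tolerance
  (the roughness with which such additivity is typically claimed);
  exactly, it is the initial decay slope of the open state that is
  additive, so the fitted-rate comparison holds whenever unbinding
  contributes little over the fitted window.

## Numerical choices

* Occupancy relaxations are solved by eigendecomposition of the 2–4 state
  generator, with a matrix-exponential stepping fallback for defective
  generators. Steady states solve `πQ = 0` with the normalization row
  appended, erroring on rank deficiency (reducible schemes).
* The steady-state current of a segment is the mean of its final 10% — the
  published analyses do not define their window, and with segments at
  least five relaxation times long the choice is immaterial.
* Test oracles are independent of these paths: a classical Runge–Kutta
  micro-step integrator (1 µs steps) for trajectories, vectorized
  Gillespie ensembles of 10⁵ channels for occupancies, hand-solved balance
  equations for stationary distributions, bisection on the occupancy for
  apparent Kd, and normal-equation solutions for the regressions.
* Problem sizes in the test suite (chosen as the smallest that exercise
  the estimators at realistic signal-to-noise): 100-seed Monte-Carlo
  batches for noise-robustness claims; the end-to-end Woodhull recovery
  uses 2 genotypes × 5 tail voltages × 3 concentrations × 5 replicate
  sweeps per cell — 5 replicates matching the typical per-point n of 4–7
  patches in published figures of this kind — at 5% amplitude noise.

## Known limitations

* The flux-coupling law is phenomenological; θ and vs are calibration
  constants with no microscopic interpretation, and the model deliberately
  omits multi-ion single-file permeation, so it cannot predict how the IR
  index varies with symmetric K⁺ concentration from first principles
  (the presets encode the 100 mM condition).
* The very fast initial phase of repolarization tails is excluded by the
  blank window rather than modelled; only the slow (deep-site) unblocking
  phase carries information here.
* Apparent Kd is defined per blocker; two-blocker experiments are analysed
  through relative currents and rates, not a joint Kd.
* Mutant presets are parameter multipliers. They express the documented
  qualitative patterns (joint kinetic scaling, loss of flux coupling,
  negative-cooperative doubles) but individual preset values for mutants
  other than those with printed Woodhull parameters are plausible
  inventions, not measurements.
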