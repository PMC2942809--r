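---
title: "The serotonergic terminal model: equations, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The serotonergic terminal model: equations, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seroterm)
```

## The model and its assumptions

`seroterm` models one serotonergic nerve terminal as a well-mixed,
constant-volume system of nine concentrations (μM) evolving in hours:
BH2 and BH4 (the biopterin cofactor pair), free tryptophan and an
exchangeable intracellular tryptophan pool, 5-HTP, cytosolic, vesicular
and extracellular 5-HT, and 5-HIAA.  The structural assumptions matter as
much as the rate laws:

* **Well-mixed compartments.** No spatial gradients; the extracellular
  compartment is the share of extracellular space belonging to this
  terminal (volume transmission, not a single synapse).
* **Equal vesicular and cytosolic volumes.** Since the cytosol is
  well-mixed and vesicle trafficking is not modeled, only the product
  of volume and concentration matters; no volume scaling appears anywhere.
* **The soma is implicit.** Somatodendritic 5-HT1A effects enter only
  through the firing-rate driver `fire(t)`.
* **Out of scope by design:** vesicle trafficking and recycling, SERT leak
  of cytosolic 5-HT, autoreceptor modulation of reuptake, receptor
  desensitization dynamics, and multi-amino-acid competition at the
  L-transporter.

Release is `release(e5ht)·fire(t)·v5ht`.  At tonic firing (1/hr) the
vesicular pool turns over once per hour.  The two autoreceptor factors —
the smooth synthesis factor `1.5 − e²/(e*² + e²)` and the piecewise-linear
release factor (1.5 at 0, 1.0 at `e* = 0.768` nM, 0.4 at 2.3 nM and
beyond) — both equal 1 at the baseline extracellular concentration, so
switching the feedback off (`autoreceptor_config(FALSE, FALSE)`, the
5-HT1B-knockout configuration) leaves the baseline steady state unchanged
while changing every response to perturbation.

## Parameters that matter

All parameters live in `kinetic_parameters()` with per-entry provenance
tags.  The ones a user will most often touch:

| parameter | default | unit | meaning |
|---|---|---|---|
| `sert_vmax` | 4700 | μM/hr | SERT density; varies ~5-fold across projection regions |
| `tph_vmax` | 400 | μM/hr | TPH activity; polymorphisms span 0.19–1.0 of normal |
| `k_rem` | 400 | /hr | removal of extracellular 5-HT by glia/blood/diffusion |
| `nadph`, `nadp` | 300 | μM | fixed cofactor levels for the reductase |

Where the tabulated and narrative parameter values disagree in the source
literature, the narrative values are used (`sert_vmax` 4700 not 8000;
tryptophan uptake Km/Vmax 330/700 not 64/400), because only those
reproduce the printed uptake flux (~158 μM/hr), reuptake flux
(21.1 μM/hr), and the ~1 s pulse-clearance timescale.

NADPH and NADP are fixed parameters rather than states; only their Km
values are constrained by the source, so their level (300 μM) is an
assumption.  Changing it rescales only the calibrated BH2 level — every
other calibrated constant and the whole steady state are invariant to the
choice (asserted by a test).

## Calibration

Three constants are under-determined and are pinned by closed-form flux
balance at the target operating point (free tryptophan 20.6 μM, a 10×
pool, synthesis flux 5.57 μM/hr, extracellular 5-HT 0.768 nM, fire 1/hr):

1. **Biopterin** (`calibrate_biopterin`): BH4 solves the TPH law equal to
   the synthesis flux (root-bracketed in (0, 10³] μM), BH2 solves the
   reductase balance; their sum is the conserved biopterin total
   (≈1.005 μM).
2. **Vesicular leak** (`calibrate_mat`): at steady state the net packaging
   flux must equal the release flux, which equals the vesicular
   concentration itself at tonic firing; with the cytosolic level forced
   by the catabolism balance (0.502 μM), `k_out ≈ 116`/hr.  The tabulated
   `k_out = 40` is consistent only with `mat_vmax ≈ 1226`, an alternative
   pair the calibrator also supports; 3500/116 is the default because the
   transporter Vmax is the author-chosen constant and Km = 0.198 μM is
   literature-anchored.
3. **Tryptophan pool** (`calibrate_trp_pool`): the pool must dispose of
   the uptake flux not consumed by synthesis, giving
   `k_catab = (157.7 − 5.57)/206 ≈ 0.739`/hr and `k1 ≈ 13.4`/hr.  The
   originally tabulated triple (k1 = 6, k−1 = 0.6, k_catab = 0.2) is
   *provably infeasible*: disposal of ≈152 μM/hr is required but
   `k1·trp = 6 × 20.6 = 123.6` μM/hr is the most the exchange can carry.
   `check_printed_pool_constants()` performs this arithmetic and raises a
   warning carrying it (once per session during calibration) rather than
   silently patching.  These constants are treated as first-order rate
   constants (/hr); the tabulated μM/hr label is dimensionally
   inconsistent with a linear exchange and a fixed 10:1 pool ratio.

Calibration is idempotent and leaves the literature-anchored Km values
untouched.  The steady-state report echoes the relative error against
every target; free tryptophan is targeted at the narrative 20.6 μM, ~2%
above the tabulated 20.1 μM, and that delta is reported, not hidden.

## Numerics

* **Stiff integration** via `deSolve::lsoda`, default `rtol 1e-8`,
  `atol 1e-10`.  The solver is hard-restarted at every declared driver
  breakpoint (pulse edges, dose time, meal knots) so sub-second events do
  not depend on step-size heuristics; the pulse experiment additionally
  caps the step inside the 0.2-s window.
* **Steady states** are found by a damped Newton iteration with a
  finite-difference Jacobian, seeded from the calibrated baseline (with
  continuation seeding along sweeps).  Because `bh2 + bh4` is conserved,
  the raw Jacobian is singular; the redundant biopterin equation is
  replaced by the conservation constraint.  The convergence tolerance
  (1e-8 μM/hr on the ∞-norm of the right-hand side) sits far below the
  smallest flux of interest (extracellular catabolism, ≈0.008 μM/hr).
  A long integration (400 h) cross-checks the root to 0.1% per variable.
  One Jacobian eigenvalue is exactly zero (the conserved direction); the
  other eight have negative real part at baseline, which is what makes the
  long-integration route valid.
* **Half-life** of a post-pulse decay is defined on the *elevation above
  baseline*, not the absolute concentration, because saturated reuptake
  makes the decay near-linear rather than exponential; it is computed by
  bracketed root finding on an interpolant of the dense solution.
* **Negative round-off**: rates are evaluated on concentrations clipped at
  0, but the stored state is never clipped, so conservation checks stay
  honest.
* Everything is deterministic; no random numbers are used anywhere.

## Design choices where the design was open

* **SSRI firing suppression.** After an SSRI dose, raphe SERT blockade
  raises raphe 5-HT, stimulates somatodendritic 5-HT1A autoreceptors, and
  suppresses firing toward a region-specific floor (58% hippocampus/MRN,
  20% frontal cortex/DRN).  The time course of that suppression is not
  constrained by the source experiments.  Tying it to the drug's own 37-h
  washout makes frontal-cortex extracellular 5-HT *never* rise above
  baseline — the firing deficit always outweighs the local blockade —
  contradicting the observed post-dose increases in both regions.  The
  default therefore lets firing recover with its own 5-h constant
  (occupancy-shaped onset, faster recovery, consistent with partial
  desensitization of the somatodendritic autoreceptors), which preserves
  the robust orderings (hippocampus > frontal cortex; 5-HT1B knockout >
  wild type) while the absolute peak percentages remain soft and are
  flagged as such in the result metadata.  `fire_washout` is a first-class
  argument.
* **Agonist occupancy** uses the same dosing shape with a 2-h washout — a
  short-acting agonist — since no agonist pharmacokinetics are specified.
* **Meal shape**: raised-cosine bumps, 3 h rise, back to baseline 6 h
  after meal start, default peak factor 2.0 (plasma amino acids typically
  vary 2–4-fold over a day); `peak_factor` is a config knob.  Meals drive
  serum tryptophan only.
* **5-HT1B knockout** turns off both terminal feedbacks; the two flags are
  independently settable for finer experiments.
* **Config format** is YAML; results are CSV/JSON with fixed formatting so
  repeated runs are byte-identical and diffable.

## What the experiments show — and what they do not

The scripted experiments use desk-scale problem sizes chosen for clean
convergence: steady-state sweeps of ~20 grid points, a 72-h dosing span
sampled at 0.02 h, a 40-s pulse follow-up at 5-ms resolution, and a 3-day
meal simulation at 0.05-h resolution.

The model reproduces, without per-experiment retuning: the baseline
steady state (all nine concentrations and every flux), the SERT-fraction
ladder from wild type to knockout (extracellular 5-HT up ~8-fold,
vesicular store down ~70%), a ~2 μM pulse peak with near-linear decay and
a doubled half-life under 50% SERT block, the autoreceptor damping of
firing-rate and polymorphism effects (halving TPH lowers extracellular
5-HT by only ~13%), and the regional/knockout orderings of SSRI responses.

Two honest caveats.  First, the computed pulse half-lives (0.76 s
unblocked, 1.39 s half-blocked) sit ~25–30% below the nominal 1 s / 2 s
read-offs: with SERT Vmax 4700 μM/hr and `k_rem` 400/hr, clearance near a
2 μM peak runs at ≈1.4 μM/s, and halving a ~2 μM elevation simply cannot
take a full second — a 1-s half-life would require a ~2.8 μM peak,
inconsistent with the 2 μM peak the model does reproduce.  The *ratio* of
blocked to unblocked half-lives (1.84×) matches the reported doubling.
Second, the absolute SSRI peak percentages depend on the unconstrained
firing-suppression time course and should be read as orderings, not
point predictions.

More broadly, this is a model of "a" terminal, not "the" terminal: SERT
density and autoreceptor expression vary several-fold across projection
regions, and all tests certify internal consistency against the published
operating point — not transferability to any particular tissue.
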