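# seroterm

A deterministic kinetic model of serotonin (5-HT) synthesis, release, and
reuptake in a single serotonergic nerve terminal, for computational
neuroscientists and systems biologists studying serotonergic homeostasis,
SERT pharmacology, and autoreceptor function.

## The model

Nine ordinary differential equations track, in μM: the biopterin cofactor
pair (BH2, BH4), free intracellular tryptophan and an exchangeable
tryptophan pool, 5-HTP, cytosolic / vesicular / extracellular 5-HT, and
5-HIAA.  Enzymes and transporters follow Michaelis–Menten kinetics:
tryptophan uptake across the blood–brain barrier (effective L-transporter
kinetics, Km 330 μM), tryptophan hydroxylase (TPH) with weak substrate
inhibition,

```
V_TPH = Vmax · trp · bh4 / [(K_trp + trp + trp²/K_i)(K_bh4 + bh4)]
          · (1.5 − e5ht² / (e*² + e5ht²))
```

aromatic amino acid decarboxylase, dihydropteridine reductase (against
fixed NADPH/NADP levels), the vesicular monoamine transporter with a linear
leak `k_out·v5ht`, the serotonin transporter SERT (Km 0.17 μM, Vmax
4700 μM/hr), combined MAO/ALDH catabolism to 5-HIAA, and first-order
removal of extracellular 5-HT (`k_rem = 400`/hr).

Release is `release(e5ht) · fire(t) · v5ht`: at tonic firing (`fire` =
1/hr) the vesicular pool turns over once per hour.  Terminal 5-HT1B
autoreceptors provide end-product feedback through two factors of
extracellular 5-HT — the synthesis factor above (1.5 at zero 5-HT, 1 at the
0.768 nM baseline, →0.5 at high 5-HT) and a piecewise-linear release factor
(1.5 → 1.0 → 0.4, constant beyond 2.3 nM).  Both equal 1 at baseline, so
the normal steady state is the same with and without feedback.

Three exogenous drivers — firing rate `fire(t)`, unblocked-SERT fraction
`fluox(t)` (an SSRI dose profile with ~37 h washout), and serum tryptophan
`btrp(t)` (meal profiles) — turn the model into in-silico versions of
classic experiments: stimulation-pulse voltammetry, SERT knockouts and
dose ladders, meal-driven synthesis swings, autoreceptor homeostasis, and
SSRI / 5-HT1A-agonist dosing with region-specific raphe firing suppression.

Three under-determined constants (the biopterin pool, the vesicular leak,
and the tryptophan-pool turnover) are calibrated so the baseline steady
state reproduces the published concentrations and fluxes; the calibration
arithmetic is closed-form and documented in the methods vignette, which
also explains why the originally tabulated trp-pool constants cannot
balance the fluxes.

## Worked example

```r
library(seroterm)
p <- kinetic_parameters()        # calibrated baseline parameter set
find_steady_state(p, cross_check = TRUE)
#> <seroterm_steady> (converged)
#>   e5ht 0.768 nM | c5ht 0.5018 uM | v5ht 21.45 uM | trp 20.6 uM
#>   residual norm 2.03e-13 uM/hr | route disagreement 8.89e-15
```

Extracellular 5-HT sits at 0.768 nM, cytosolic 5-HT at 0.50 μM, vesicular
5-HT at 21.45 μM (the store released each hour at tonic firing); the damped
Newton root and a 400-hour stiff integration agree to machine precision.

```r
table4_sweep(p)$tables$sweep[, c("f", "v5ht", "e5ht_nM", "v_tph")]
#>      f   v5ht e5ht_nM v_tph
#> 1 1.00 21.453   0.768 5.570
#> 2 0.50 19.888   1.180 4.584
#> 3 0.20 17.964   1.809 3.838
#> 4 0.10 16.868   2.252 3.581
#> 5 0.05 14.536   3.291 3.298
#> 6 0.00  6.351   6.188 3.098
```

As SERTs are progressively blocked (wild type `f = 1` to knockout
`f = 0`), extracellular 5-HT rises ~8-fold while the vesicular store drains
to 30% and synthesis is throttled by the autoreceptors.

```r
pulse_release(p)$summary[c("peak_e5ht_uM", "half_life_s")]
#> $peak_e5ht_uM [1] 2.026276
#> $half_life_s  [1] 0.7565305
```

A 0.2-s firing burst (1 → 5000/hr) dumps ~10% of the vesicular store,
extracellular 5-HT peaks near 2 μM, and saturated SERTs clear it in a
near-linear ramp.

A command-line shell wraps the same functions:

```sh
Rscript inst/cli/seroterm.R experiment table4 --out results/
Rscript inst/cli/seroterm.R steady --fluox 0 --out results/
```

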