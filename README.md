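# pocenmr

Quantification of position-specific ¹³C isotopic enrichment of brain
metabolites from proton-observed carbon-edited (POCE) NMR, with
FDR-controlled Spearman correlation networks across metabolites and brain
regions, group-level depletion statistics, and a fully synthetic cohort
generator with known ground truth so the entire chain is testable without
any experimental data.

## Who this is for

POCE experiments acquire two scans per tissue extract: a **reference** scan
recording total metabolite signal (¹²C + ¹³C bound protons) and an
**edited** scan isolating the ¹³C-bound protons after infusion of a labeled
substrate such as [3-¹³C]glucose. For each metabolite, integrating both
scans over a fixed chemical-shift window gives the fractional enrichment

```
enrichment (%) = 100 × [¹³C] / ([¹³C] + [¹²C])
               = 100 × ∫window edited / ∫window reference
```

This package implements that pipeline end to end for a two-group
(control vs cerebral ischemia), six-region mouse study design — frontal,
occipital and temporal cortex, striatum, hippocampus, thalamus — and the
downstream analyses such studies report: per-metabolite percent depletion
with bootstrap intervals, tracer-equilibration QC against the TMSP internal
standard, and metabolite/region Spearman networks retained at |ρ| > 0.8
with Benjamini–Hochberg q < 0.01. Utilities for the accompanying behavioral
and electrophysiological endpoints (discrimination index, corner-test turn
ratios, 60 s beam-time censoring, Welch band power, JC-1 ΔΨm index) are
included.

## What is inside

| Stage | Functions |
| --- | --- |
| Synthetic data | `cohort_design()`, `simulate_cohort()`, `simulate_spectrum_pair()`, `render_cohort()`, `write_cohort()` |
| Spectral processing | `phase_correct()`, `baseline_correct()`, `calibrate_ppm()`, `find_apex()` |
| Quantification | `load_windows()`, `integrate_window()`, `enrichment_ratio()`, `quantify_pair()`, `quantify_cohort()`, `normalize_to_tmsp()` |
| Networks | `metabolite_network()`, `regional_network()`, `hub_scores()`, `write_graphml()` |
| Group statistics | `percent_reduction()`, `depletion_summary()`, `normality_screen()`, `anova_tukey()` |
| Other endpoints | `discrimination_index()`, `turn_ratio()`, `censor_beam_time()`, `band_power()`, `mito_potential_index()` |
| End to end | `run_demo()` |

Spectra are simulated directly in the frequency domain as closed-form
Lorentzians, so an analytic arctan window integral is available as an
oracle for every numerical step. Cohorts draw per-sample enrichments
through a Gaussian copula (latent metabolite and region coupling) with
mean-preserving lognormal noise; the defaults encode the study structure
the package targets: ~50% GABA/glutamate depletion under ischemia, a spared
highly-correlated three-carbon pool (lactate, alanine, aspartate, NAA), and
a TMSP steady-state factor of 1.10 ± 0.03. See the methods vignette
(`vignettes/poce-enrichment-methods.Rmd`) for the models, defaults, and
numerical choices.

## Worked example

Simulate one cohort sample, quantify its scan pair, then run the group
comparison and the control-group network on the full cohort:

```r
library(pocenmr)

windows <- default_windows()
design  <- cohort_design(seed = 1)          # 8 mice/group x 6 regions
cohort  <- simulate_cohort(design)

pair <- simulate_spectrum_pair(cohort$samples[[1]], windows,
                               acquisition_params(noise_sd = 0.6), seed = 2)
quantify_pair(pair$reference, pair$edited, windows)[1:6, ]
#>   metabolite ref_integral edit_integral enrichment_pct
#> 1       TMSP        0.939         1.016          108.1
#> 2    Lactate        0.804         0.335           41.6
#> 3      GABA3        0.887         0.145           16.4
#> 4      GABA4        0.869         0.251           28.9
#> 5        NAA        0.975         0.210           21.6
#> 6       NAAG        0.804         0.185           23.1
```

The TMSP row is the internal standard: its enrichment column is the
steady-state ratio × 100 (near 110), not a metabolite enrichment. Now the
whole cohort:

```r
rendered <- render_cohort(cohort, windows,
                          acquisition_params(noise_sd = 0.6), seed = 1)
enr <- normalize_to_tmsp(quantify_cohort(rendered, windows))

percent_reduction(enr, "GABA4", "all", seed = 1)
#>   metabolite n_control mean_control mean_ischemia pct_reduction ci_lo ci_hi
#> 1      GABA4        48        25.34         13.56         46.47 44.07 48.77

edges <- metabolite_network(enr, "control")
edges[edges$retained, c("item_a", "item_b", "rho", "q_fdr")]
#>   item_a  item_b   rho    q_fdr
#> 9    Ala Lactate 0.857 1.11e-12

qc <- tmsp_qc(enr)
mean(qc$steady_ratio)
#> [1] 1.138
```

The generator planted a 50% GABA depletion (estimated 46.5%, CI
44.1–48.8), a latent 0.9 coupling inside the spared pool (the Lactate–Ala
edge survives both the |ρ| > 0.8 and q < 0.01 gates at n = 48), and a TMSP
steady state of 1.10 (QC mean 1.14 at this noise level; see the vignette's
note on baseline bias at high spectral noise).

`run_demo(outdir, seed)` chains all of the above and writes the ground
truth, enrichment table, QC table, edge lists (CSV + GraphML), hub scores,
and a depletion summary, plus a config snapshot — byte-reproducible from
(config, seed).

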