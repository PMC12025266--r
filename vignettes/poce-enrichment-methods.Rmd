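---
title: "Quantifying 13C isotopic enrichment from POCE NMR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 13C isotopic enrichment from POCE NMR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocenmr)
```

## The measurement

Proton-observed carbon-edited (POCE) NMR measures position-specific
\eqn{^{13}}C isotopic enrichment of metabolites after infusion of a labeled
substrate such as [3-\eqn{^{13}}C]glucose. Two scans are acquired per sample:
a *reference* scan recording protons bound to both \eqn{^{12}}C and
\eqn{^{13}}C (the total pool), and an *edited* scan isolating protons bound
to \eqn{^{13}}C. For a metabolite resonance integrated over a fixed
chemical-shift window, the fractional enrichment is

$$\mathrm{enrichment} \;=\;
  \frac{[^{13}\mathrm{C}]}{[^{13}\mathrm{C}]+[^{12}\mathrm{C}]}\times 100\%
  \;=\; 100 \times \frac{\int_{\mathrm{window}} S_{\mathrm{edited}}}
                        {\int_{\mathrm{window}} S_{\mathrm{reference}}}.$$

Because it is a ratio of two integrals over the same window of two scans of
the same sample, the statistic is invariant to any common rescaling of both
scans — receiver gain, sample loading, and (to first order) small phase
errors all cancel. That robustness is the reason windowed sum-integration,
rather than lineshape fitting, is the standard workhorse for this assay, and
it is what this package implements.

The packaged window table carries the 18 curated brain-metabolite
chemical-shift ranges used throughout (TMSP, lactate, GABA C3/C4, NAA, NAAG,
Glu C3/C4, Gln C4, Glx C2/C3, succinate, Asp C3, myo-inositol ×3, taurine,
alanine). Several rows of the source table list their bounds in descending
order; `load_windows()` canonicalizes them and warns about any overlapping
pairs.

## The synthetic-data generator

No spectra are deposited with the study this package operationalizes, so
every stage is validated against a simulator with known ground truth.

**Spectra.** Simulation happens directly in the frequency domain: each
metabolite contributes a closed-form absorption Lorentzian at its window
center with area proportional to amount (reference) or amount × enrichment
(edited); TMSP appears in both scans with an edited/reference area ratio
equal to the sample's steady-state factor. A zero-order phase error mixes in
the dispersion lineshape as \eqn{\cos\phi_0 \cdot A + \sin\phi_0 \cdot D}, a
polynomial baseline is added, and i.i.d. Gaussian noise is drawn per scan.
There is no FID/FFT path: the study's own analysis only ever handles
processed spectra, and the frequency-domain form keeps an analytic oracle —
the window integral of a unit Lorentzian is
\eqn{\frac{1}{\pi}[\arctan\frac{b-x_0}{\gamma}-\arctan\frac{a-x_0}{\gamma}]}
— available for every test. The edited scan is simulated as the
post-subtraction \eqn{^{13}}C-only spectrum; the two-subscan subtraction
arithmetic is not modeled. One-bond \eqn{^1}H–\eqn{^{13}}C satellite
doublets (two half-area peaks at ±J/2) are available behind a flag and off
by default, since the integration windows are wide relative to J.

Acquisition defaults: 20 ppm sweep, 16384 points (desk scale; 65536 matches
a 64k acquisition), Lorentzian half-width γ = 0.005 ppm, noise
`noise_sd = 0` unless requested. The grid keeps γ ≥ 2 grid steps so
trapezoidal window integrals track the analytic form within 0.5%.

**Cohorts.** `cohort_design()` describes a two-group (control vs ischemia),
six-region study with `n_per_group = 8` mice. Per-sample enrichments are
drawn through a Gaussian copula — latent correlations `copula_corr` between
metabolites within a sample, plus optional per-metabolite region coupling
within a mouse — with marginal multiplicative lognormal noise of coefficient
of variation `noise_cv = 0.1` and mean preserved
(\eqn{e^{\sigma z - \sigma^2/2}}, \eqn{\sigma^2=\log(1+\mathrm{CV}^2)}).
Ischemia group means are baseline × depletion factor. The TMSP steady-state
factor is drawn per sample from Normal(1.10, 0.03), emulating tracer
equilibration at isotopic steady state. Cohort generation is a pure function
of (design, seed).

**Defaults and what they emulate.** The depletion factors place the spared
three-carbon pool (lactate, alanine, Asp C3, NAA) at 1.0, GABA and
glutamate near 0.5 (the ~50% transmitter depletion), and the remaining
metabolites at 0.55–0.65, so recovered reductions land in the reported
30–50% band as an emergent summary rather than a parameter. The default
copula couples the spared pool at 0.9, reproducing the retained
high rank-correlations among three-carbon units. Baseline enrichment
fractions are not printed anywhere and are the package's own choice: they
are set to plausible [3-\eqn{^{13}}C]glucose values with the added rule that
chemically adjacent resonances (the NAA/NAAG/Glu3/Glx3 cluster at
2.0–2.2 ppm, the GABA4/Glu4/Suc/Gln4 cluster at 2.27–2.46 ppm) carry
similar fractions. That rule is metabolically sensible — these pools
exchange label — and it bounds the effect of fixed-window cross-talk between
neighboring Lorentzian tails, keeping noise-free end-to-end recovery within
0.5 percentage points for all 17 metabolites. Spectral noise defaults target
a signal-to-noise ratio near 100 for a unit-amount peak (`noise_sd = 0.6`
at γ = 0.005; 0.3 at the desk-scale γ = 0.01). Neither the noise level nor
the inter-animal CV is reported by the study; both are configurable.

**What the simulator does not emulate.** Isotopomer-resolved label
propagation, J-coupling multiplet structure (beyond the optional
satellites), T1/T2 relaxation and NOE effects, field drift, solvent
artifacts, and any region-specific mean differences. Passing tests
demonstrate that the pipeline recovers known ground truth under this noise
model; they cannot certify behavior under artifacts the generator does not
produce.

## Spectral processing

**Phase.** `phase_correct()` rotates the spectrum in the complex plane,
reconstructing the imaginary channel with a discrete Hilbert transform.
Automatic phasing minimizes the sum of squared negative intensities over a
0.5° grid on \eqn{[-\pi,\pi)} followed by golden-section refinement to
0.01°. The criterion is evaluated on quadratically detrended copies of the
two channels: an additive smooth baseline otherwise biases the negative-area
criterion by tens of milliradians, which matters because a residual phase
error leaks neighboring peaks' dispersion tails into wide integration
windows. Detrending is linear, so it is precomputed once on the spectrum and
its Hilbert transform; the output spectrum itself is only rotated, never
detrended. Recovery of injected errors is accurate to < 0.01 rad in all
tested scenarios, and the procedure is idempotent at its fixed point.
First-order (frequency-linear) phase is available via `phi1` but off by
default — the simulator injects only zero-order errors, and the vendor
processing this step stands in for is not further specified.

**Baseline.** `baseline_correct()` uses asymmetric least squares (second
difference penalty λ, asymmetry `p_asym = 0.001`, 10 reweighting
iterations), with two departures from the textbook recipe, both adopted
after measuring their effect on the enrichment statistic:

1. *Signal masking and re-centering.* A second pass refits the baseline
   with detected signal points (residual > 3·MAD above the first fit, plus a
   small absolute guard) excluded outright, and then re-centers the fitted
   curve on the median of the retained residuals. Plain ALS fits the *lower
   envelope* of the noise and is pulled upward by peak mass; both effects
   are differential between the reference and edited scans (whose total
   signal mass differs several-fold) and together biased the TMSP
   steady-state QC ratio by up to +0.05 before masking. On a signal-free or
   noise-free spectrum both corrections are exact no-ops.
2. *Stiffness.* λ defaults to 1e13 expressed on the reference grid and is
   rescaled internally by the fourth power of the actual grid spacing, so it
   corresponds to a fixed smoothing length of a couple of ppm regardless of
   digitization. Softer baselines (λ ≤ 1e9) absorb the genuine summed-tail
   plateau inside crowded peak regions and shave several percent off wide
   windows; at the default, isolated peak areas on polynomial baselines are
   restored to 0.1–0.2% and the full chain recovers every noise-free window
   integral within 2%.

**Calibration.** `calibrate_ppm()` shifts the axis so the TMSP apex (maximum
within its window, refined by 3-point parabolic interpolation for sub-grid
precision) sits at its catalogued position, 0.004 ppm. The table's 0.004 —
rather than the conventional 0.000 — is followed literally; whether it
reflects a window-center convention in the source table is unknowable, and a
uniform axis shift is immaterial to every downstream statistic. Shifts
beyond 0.05 ppm succeed with a warning, implementing the stated tolerance
around known chemical shifts as a drift alarm, not as window widening.
Intensities are untouched (axis-only transform).

**Chain order.** `quantify_pair()` applies phase → baseline → calibrate to
both scans, integrates all windows by the trapezoidal rule (partial end bins
linearly interpolated, sign preserved), and forms enrichment ratios.
Enrichments outside [0, 100] are flagged, never clipped — clipping would
bias cohort means. A non-positive reference integral produces an explicit
missing value with a diagnostic.

## Correlation networks

`metabolite_network()` computes Spearman rank correlations for every
unordered metabolite pair over a group's observations — by default one
observation per (mouse × region) sample, up to n = 48; mouse-level pooling
is available behind the `observation` flag since the study's "within
identical samples" phrasing admits both readings. Two-sided p-values use the
exact permutation distribution for n ≤ 9 without ties and the
t-approximation otherwise; ties get mid-ranks. Benjamini–Hochberg adjustment
runs over all pairs jointly, and an edge is retained only when *both*
|ρ| > 0.8 *and* q < 0.01 (strict inequalities, conjunctive rule). Spearman
is the primary method, matching the stated nonparametric analysis; Pearson
is exposed as an option without presuming intent. `regional_network()`
applies the same machinery across mice for one metabolite's six regions
(15 pairs), and `hub_scores()` ranks nodes by retained-edge degree and
summed |ρ| strength.

A granularity note: at n = 8 mice the exact permutation null's smallest
attainable p-values are coarse enough that BH at q < 0.01 over 15 region
pairs rarely retains even a perfectly planted coupling. The package's
planted-structure recovery tests therefore state their own problem sizes
(n = 20–24 mice) and use valid positive semi-definite planted structures;
at the study's n = 8, regional claims rest on the correlation magnitudes
rather than the retention flag.

## Group statistics

`percent_reduction()` reports \eqn{100\,(1-\bar e_{\mathrm{ischemia}}/\bar
e_{\mathrm{control}})} with a 95% bias-corrected bootstrap interval
(group-stratified resampling, 2000 draws, seeded) and the two-group ANOVA of
the same records. `normality_screen()` is the Kolmogorov–Smirnov test with
the Lilliefors correction — the plain KS null is wrong when mean and sd are
estimated, and the correction is the standard reading of a KS screen at
α = 0.05. `anova_tukey()` wraps one-way ANOVA with Tukey's HSD; both are
always computed, and `tukey_reported` records whether the omnibus test
reached p < 0.05 under the convention of reporting the post hoc only then.
`depletion_summary()` runs the reduction estimate per metabolite and adds BH
adjustment within the family (the multiplicity treatment across the
metabolite × region grid is otherwise unspecified; raw and adjusted p are
reported side by side).

## Behavioral and electrophysiological endpoints

The package also implements the study's defined non-NMR formulas:
discrimination index \eqn{(T_{novel}-T_{familiar})/(T_{novel}+T_{familiar})}
with the < 10 s total-exploration exclusion; corner-test left/right
percentages over valid trials; beam-traversal censoring at 60 s with the
censoring flag retained; band power as a Hann-windowed Welch periodogram
(2 s segments, 50% overlap — the PSD estimator is otherwise unspecified, and
these are conventional ECoG parameters) integrated by trapezoid over Delta
(0.5–4), Theta (4–8), Alpha (8–13), Beta (13–30), Gamma (30–100 Hz), with a
shared band edge contributing half weight to each side so partitions are
additive; and the JC-1 aggregate/monomer membrane-potential index. Corner
trial validity beyond the >90° rotation rule is caller-declared.

## Numerical choices and degenerate inputs

* Trapezoidal integration requires ≥ 3 grid points of window overlap and
  errors otherwise; partial end bins are linearly interpolated.
* Automatic phasing refuses spectra with no region above 5× the noise sd
  (estimated robustly as MAD of first differences / √2); calibration
  refuses windows without a detectable apex by the same criterion.
* Constant series yield missing correlations with a diagnostic; empty
  networks yield all-zero hub scores with a warning.
* Non-PSD copulas are rejected with a pointer to the nearest-correlation
  repair flag (`repair_copula = TRUE`, Higham projection).
* Out-of-range enrichments and censored trials carry flags downstream;
  missing values propagate explicitly and are excluded pairwise.
* Tie-breaks: hub rankings sort by strength, then node name.

## Problem sizes used in the test suite

Cohort-level property tests run on ground-truth tables (no spectral
rendering), which makes 100–200-seed Monte-Carlo sweeps cheap; the
full-pipeline recovery checks render one 96-sample cohort at the default
16384-point grid and a second at the desk scale (4096 points, γ = 0.01,
same SNR ≈ 100). These sizes were chosen as the smallest at which the
statistical claims under test are stable across seed sets.

## Known limitations

* Fixed-window sum integration cannot apportion overlapping resonances; the
  windows are integrated as catalogued, cross-talk between neighboring
  tails included. Deconvolution of the Glx multiplets is out of scope.
* Absolute concentrations (mM) are not computed; TMSP serves as a loading
  and axis reference only.
* At high spectral noise (σ ≈ 0.6 on the fine grid) the baseline step still
  biases the TMSP steady-state ratio by ~+0.03: distinguishing a
  0.2-intensity Lorentzian tail plateau from baseline under that noise is
  locally ill-posed. Ratio-of-group-means statistics are insensitive to
  this; per-sample QC ratios are best taken at the desk-scale acquisition.
* The copula reproduces rank correlations, not mechanistic label exchange;
  region labels differ only through the coupling structure, never through
  mean effects.
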