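# fscvsync

Analysis of dopamine terminal function measured with ex vivo fast-scan
cyclic voltammetry (FSCV) together with midbrain gene expression — and the
statistic that links them: the rank-pooled transcript-by-function
**synchrony** correlation with a subject-level permutation test.

The scientific setting is the hypodopaminergic state left by chronic
alcohol exposure: accumbens dopamine terminals clear dopamine faster,
release less per stimulus and are more sensitive to kappa opioid receptor
(KOR) inhibition, while individual-gene expression in the VTA shows no
differential expression at all. What changes is the *coordination* between
somatic transcript levels and terminal function, which this package
quantifies. It is aimed at slice electrophysiologists and computational
biologists who want the full chain — trace kinetics to pooled rank
statistics — reproducible and testable without animal data.

## What it computes

**Kinetic deconvolution.** Stimulated dopamine traces are modelled as

    dC/dt = [DA]p * sum_i delta(t - t_i)  -  Vmax * C / (Km + C)

with the Michaelis constant fixed at Km = 0.160 uM. `fit_kinetics()`
estimates per-pulse release `[DA]p` and maximal uptake rate `Vmax` by
bounded Levenberg-Marquardt least squares (RK4 forward model in compiled
code); `simulate_trace()` is the matching generator.

**Terminal metrics.** `fit_io_sigmoid()` fits the input-output curve
`y = bottom + (top - bottom) / (1 + exp((EA50 - I)/steepness))` over
stimulation amperage (EA50 = half-maximal excitatory amperage; span = top −
bottom). `kor_sensitivity_metrics()` gives percent inhibition at 300 nM
(potency) and 1 uM (efficacy) of cumulative agonist, both against the
original baseline; `auc_frequency()` and `disinhibition_auc_change()`
quantify the frequency-response curve before/after KOR blockade.

**Expression stage.** `filter_low_expression()` (count ≥ 5 in ≥ 3 samples),
median-of-ratios `size_factors()`, `normalize_log()`, a Welch-t +
Benjamini-Hochberg `de_screen()`, and `pca_scores()`.

**Synchrony.** Within each group, every panel gene is correlated with every
functional measure; subjects are ranked 1..n per variable within group and
all gene x measure pairs are pooled into one rank-rank plane (4 genes x 2
measures x 8 subjects = 64 pairs per group). `pooled_spearman()` is the
pooled correlation; `subject_permutation_test()` supplies a
dependence-aware p-value by permuting subject labels of the function table
(p = (1 + #{|r_perm| ≥ |r_obs|}) / (B + 1)); `synchrony()` runs both groups
and contrasts them (bootstrap CIs, slope-set t-tests, sign-reversal flag).

**Synthetic cohorts.** `cohort_config()` / `generate_cohort()` produce a
seeded cohort (defaults: 17 drinkers, 11 controls, 8 + 8 with voltammetry)
with known ground truth; `generate_expression()` couples panel genes to
functional truth at a target Spearman rho via a Gaussian copula
(r = 2 sin(pi rho / 6)); `generate_counts()`, `generate_drinking()` and
`generate_fscv_session()` complete the data types. `run_pipeline()` chains
everything and writes versioned, seeded outputs.

## A worked example

```r
library(fscvsync)

# --- kinetics: simulate a single-pulse trace and recover its parameters
tr  <- simulate_trace(stim_protocol(), dap = 0.8, vmax = 2.5)
fit <- fit_kinetics(tr)
fit
#> Michaelis-Menten kinetic fit
#>   [DA]p = 0.8 uM/pulse, Vmax = 2.5 uM/s (Km fixed at 0.16 uM)
#>   RSS = 2.887e-32, converged: TRUE

# --- synchrony: a cohort whose drinkers couple the a priori dopamine panel
#     (DRD2, OPRK1, SLC6A3, SLC18A2) to release/Vmax at rho = 0.8 and whose
#     controls do not (the default configuration)
coh  <- generate_cohort(cohort_config(seed = 7))
expr <- generate_expression(coh, gene_panel("a_priori_dopamine"))
ft   <- truth_function_table(coh)
synchrony(ft, expr, "a_priori_dopamine", B = 1000, n_boot = 1000, seed = 1)
#> Transcript-function synchrony contrast
#>   control: pooled r = 0.333 [-0.171, 0.692], permutation p = 0.247
#>   drinker: pooled r = 0.643 [0.269, 0.842], permutation p = 0.004
#>   difference (drinker - control) = 0.310; sign reversal: FALSE
#>   slope sets: two-sample t(14) = 1.940, p = 0.0728
```

Each group pools 64 rank pairs (4 genes x 2 measures x 8 subjects). Here
the drinkers' pooled correlation (0.64) is individually significant under
the subject permutation test while the controls' (0.33) is not — the
generator's configured pattern. The slope-set comparison uses the
pooled-variance t with df = 14 (8 + 8 slopes).

The full pipeline at fixture scale (4 + 4 subjects, 50 genes, 112 traces)
runs in about a second:

```r
rep <- run_pipeline(fscvsync:::fixture_config(3))
rep
#> Pipeline run (seed 3, config 25ab48ec)
#>   8 subjects, 50 genes simulated (36 retained), 112 traces
#>   DE screen: 0 gene(s) BH-significant
#>   synchrony [a_priori_dopamine]: control r = -0.075, drinker r = 0.900, reversal FALSE
```

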