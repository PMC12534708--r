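---
title: "Methods: ternary-code methylation analysis on paired 5modC/5hmC arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ternary-code methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and numerical
choices: what each stage assumes, which tunable parameters matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open. No empirical claim is made here that the test suite or
`scripts/acceptance.R` does not itself compute.

## The ternary decomposition

A bisulfite-converted array measures total modification per CpG,
β(5modC) = 5mC + 5hmC, because both marks resist conversion. A matched
experiment that further deaminates 5mC with APOBEC3A (while
bisulfite-protected 5hmC resists) measures β(5hmC) directly on the same
sample. `ternary_decompose()` recovers the third component by subtraction:

* 5mC = max(0, β(5modC) − β(5hmC))
* C = 1 − 5mC − 5hmC

Both measurements are noisy, so a small fraction of cells has
β(5modC) < β(5hmC). Three treatments were on the table: renormalize the
pair, trust the subtraction and report a negative 5mC, or clamp. We clamp
5mC at zero, keep the 5hmC measurement untouched, and record the cell in a
`clamped_mask`. Rationale: renormalizing silently redistributes error into
the component that was measured directly, while a negative fraction is not
interpretable; clamping is the least-information-destroying option and the
mask keeps the violation auditable. The closure 5mC + 5hmC + C = 1 then
holds for every non-NA cell by construction (to ~1e-16), which the tests
assert at 1e-9. NA in either input blanks all three components: a
half-observed cell has no defined decomposition.

The `ratio_by_hmc_bin()` summary (mean 5mC/(5mC + C) across 5hmC bins,
left-closed/right-open, last bin closed) is a composition diagnostic: if
5hmC is deposited on methylated substrate, high-5hmC bins contain almost
no unmethylated sites and the ratio rises. Note this rise is driven by
which sites populate a bin; within a fully methylated site the ratio
(m − h)/(1 − h) actually falls slightly with h. The tests therefore assert
the composition effect (lowest bin far below the rest, upward trend), not
cell-wise monotonicity, which would be wrong.

## Marker discovery

`one_vs_rest_markers()` tests each CpG with a two-sided Wilcoxon rank-sum
statistic using midranks. The exact null (via the `pwilcox` distribution)
is used when both sides have ≤ 10 usable samples and no ties — the regime
of sorted-cell reference panels, where a normal approximation is at its
worst — and a tie-corrected normal approximation with continuity
correction otherwise. AUC is U/(n₁n₂); orientation is "target higher" >
0.5, and selection uses distance from 0.5 so hypomethylated markers
qualify symmetrically (whether the original screening was one-sided with
separate hypo handling is not documented anywhere we could rely on; the
symmetric rule is declared here and used consistently).

Defaults follow the headline screen: AUC ≥ 0.8, |Δβ| ≥ 0.2, and the NA
rules that drop a CpG with missingness > 10% of the target group or > 50%
of the rest. Δβ is a difference of group means (not medians). A design-mode
variant (AUC = 1, Δβ ≥ 0.3, cap = 80 per contrast) reproduces the stricter
probe-selection screen; under a cap, candidates are ranked by
(AUC distance from 0.5, |Δβ|, probe ID) and drawn alternately from the
hyper- and hypomethylated lists while both are non-empty, so the two
directions stay balanced and reruns are bit-identical.

The same machinery runs on arbitrary numeric feature tables
(`tissue_specific_features()`, default |Δ| ≥ 1 on the table's own scale,
e.g. TPM), including single-column groups where each group contributes one
observation.

## Deconvolution

"Robust partial correlations" is implemented as iteratively reweighted
least squares with Huber weights (tuning constant 1.345 ≈ 95% Gaussian
efficiency; `MASS::rlm` is the engine), no intercept, followed by
truncation of negative coefficients and renormalization to a probability
vector. No intercept because betas already share the [0,1] scale and the
reference profiles span the mixture space; an intercept would absorb
genuine proportion mass. The exact iteration settings of the published
implementations vary and are rarely documented; ours are stated here
(max 50 iterations, tolerance 1e-6) and exposed as arguments. On
(near-)exact fits the MAD scale estimate degenerates, so the solver falls
back to OLS when the residual RMS is below 1e-8. `nnls_deconvolve()`
(non-negative least squares, then renormalization) is kept as an
independent cross-check; the tests require agreement within 0.02 per
component on Gaussian-noise mixtures and exact recovery (1e-9) on
noiseless ones. Markers NA in a sample are dropped pairwise for that
sample only.

## Cross-platform imputation

`build_neighbor_map()` finds, for every query (legacy-only) site, the
retained site with the smallest Euclidean distance across the
reference-sample vectors. The original construction used a k-NN descent
graph (k = 50) plus a global lowest-distance pass and kept the overall
minimum; we implement the exhaustive-equivalent semantics directly (the
graph is an optimization for millions of sites, not a different
definition), and the interface retains `k` for compatibility. NA cells are
mean-imputed per probe before distances, because distances require complete
vectors — this NA policy can change neighbors and is therefore stated.
Substitution uses a neighbor only when Pearson r strictly exceeds
`r_min = 0.5`; distance ties break by higher r, then probe ID, and a query
literally present in the retained list is a pass-through, not an
imputation.

## EWAS, clocks, sex score

`fit_linear_ewas()` fits per-CpG OLS of β on age, sex and tissue (dummy
coding against the first level, no interactions), with two-sided t tests
and BH q-values computed separately within each coefficient family.
Complete rows go through one shared QR decomposition; rows with NAs are
re-fit on complete cases and require rank(design) + 2 samples. Zero
residual variance (constant betas) yields p = NA, never a spurious 0.
Collinear designs abort naming the aliased columns.

`loocv_clock()` holds out one sample at a time, reruns the EWAS on the
remainder, selects the `n_features = 50` CpGs with the smallest age
p-values (ties broken lexicographically), and trains
`glmnet::cv.glmnet(alpha = 0.5, nfolds = 10)`, predicting at λ.min (the
λ.min-vs-λ.1se choice is not documented by the analyses this mirrors; we
fix λ.min). Covariates enter the feature-selection EWAS only — the elastic
net itself sees CpG betas alone. Feature selection happens strictly inside
each fold; a `select_in_fold = FALSE` switch exists purely so the tests can
demonstrate the optimistic bias of leaking selection, and the acceptance
suite asserts that on permuted ages the leaky variant reports a better
(spurious) MAE than the honest one. Inner-fold assignment is seeded from
(seed, held-out sample ID), making results invariant to sample order.
`sex_score()` is mean(β over male-hyper CpGs) − mean(β over male-hypo
CpGs); a score exactly at the threshold is called female (strict
inequality for male), a documented tie rule.

## Enrichment statistics

`fisher_set_enrichment()` computes the one-sided hypergeometric
over-representation p against a stated universe, with BH across the
annotation family. The odds ratio uses a 0.5 continuity correction only
when a zero cell occurs; a degenerate margin (annotation empty or equal to
the universe) carries no association signal and reports OR = 1. Interval
colocalization expands both sides symmetrically (±5 kb by convention for
GWAS SNP work, clamped at 0) under 0-based half-open semantics via
IRanges.

The ranked-set enrichment statistic is the unweighted KS-style running sum
(+1/|Q| at hits, −1/(N−|Q|) at misses), signed maximum deviation, with a
tie between the positive and negative extremes resolved positive. The
null permutes query membership uniformly; p = (1 + #{|ES*| ≥ |ES|}) /
(n_perm + 1), so p ≥ 1/(n_perm+1) and the test is valid by construction.
The weighted-ES variants used by other tools were deliberately not
adopted: with membership permutation the unweighted statistic is exactly
enumerable on small cases, which the tests exploit.

Dunn's post-hoc test (rank-sum z with tie correction, BH adjustment) is
implemented in the package because no post-hoc package is among the
dependencies; it follows the standard formulation and is exercised against
a closed-form Kruskal–Wallis oracle.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes:
bimodal background betas (modes 0.1/0.9), planted one-vs-rest markers at
exact Δβ, Dirichlet mixtures, linear age effects (default 0.002–0.005
per year over ages 20–95, matching a ~117-sample adult tissue cohort),
sex offsets, imprinted probes fixed at 0.5, replicate probe groups
(additive SD 0.02, the magnitude replicate designs show in practice), a
1% MCAR missingness rate, and a two-platform split with
correlation-calibrated neighbor copies.

Noise is Gaussian on the logit scale: β′ = logistic(logit(β) + ε). This
preserves [0,1] without clamping and reproduces the heteroskedastic error
of array betas (variance shrinking near 0 and 1); exact 0/1 values are
nudged by 1e-6 before the logit. No published noise model exists for this
choice — it is ours, and the default sd of 0.5 was chosen so that planted
Δβ = 0.4 markers are recoverable but not trivially so.

The 5hmC layer is built pre-noise as
5hmC = (1 − proliferation) · fraction(group) · 5modC, with a high-5hmC
probe group (gene-body-like, mean ratio 0.35) and a low group (0.05).
Because 5hmC is not copied at mitosis it dilutes with division, so the
per-tissue proliferation rate enters as 1 − retention; the ground truth
stores both the rate and the retention scale, and the recovered global
5hmC means are anti-correlated with proliferation by construction. The
constraint 5hmC ≤ 5modC is enforced before noise only; post-noise
violations are left in place deliberately so the decomposition's clamping
path is exercised at realistic rates (~0.2–0.3% of cells at sd 0.5).

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: probe-level chemistry artifacts (type I/II
dye bias, background), detection-p missingness structure (our NAs are
MCAR), linkage disequilibrium between neighboring CpGs, copy-number and
SNP artifacts, batch effects, and real biological covariance beyond the
planted block structure. Recovery rates on synthetic data are upper bounds
on real-data behavior.

## Problem sizes and numerical conventions

The default simulated cohort is 5,000 probes × 40 samples — large enough
that every NA rule, replicate group and screen is exercised, small enough
that the full replay (`run_pipeline()`) completes in well under ten
minutes on one core; the acceptance checks use 2,000-query neighbor maps,
2,000-CpG null EWAS panels, 500-replicate slope calibrations and
1,000-query SEA null sweeps at the same scale. Coordinates are 0-based
half-open everywhere (BED convention); 1-based sources must be converted
at the boundary. All multiple-testing corrections are Benjamini–Hochberg.
Every stochastic function takes a mandatory seed, and the pipeline derives
per-stage seeds from one global seed via an FNV-style hash
(`derive_seed()`), so stages rerun in isolation reproduce exactly.

## Known limitations

* Replicate collapsing offers the mean only; selecting the most robust
  replicate by signal intensity requires raw intensities that beta-level
  inputs do not carry.
* The clamping rule biases 5mC upward by ~half the noise magnitude at
  truly-zero-5mC sites (a truncated error distribution); the clamp
  fraction is reported so users can judge severity.
* `rpc_deconvolve` assumes the panel spans the mixture; unmodeled cell
  types project onto their nearest panel columns rather than into a
  residual term.
* The probe-sequence QC covers the extra-CpG and 3'-SNP rules; mapping
  quality and hybridization design scores require external tools and are
  out of scope.
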