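---
title: "Cross-species transcriptome integration and methylation mediation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species transcriptome integration and methylation mediation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(crossmed)
library(dplyr)
```

## The problem

A symptom cluster that can be modelled in animals invites a two-sided
screen: find genes whose peripheral-blood expression tracks symptom
severity in patients, find genes whose brain expression changes when the
corresponding process is triggered in the animal model, and keep the genes
that move in the *same direction* on both sides. `crossmed` implements this
design for the PTSD reexperiencing / fear-memory-retrieval setting: a human
cohort of PTSD patients and healthy controls with blood microarray
expression and an intrusion-subscale symptom score, and a mouse contrast
between animals sampled 30 minutes after fear-memory reactivation
(`React-30`) and non-reactivated controls (`NR`). Downstream of the screen,
a candidate gene (exemplar: *PDE4B*, a cAMP-degrading phosphodiesterase) is
characterized by co-expression, gene-set overrepresentation, and a
CpG-methylation mediation model.

Everything is driven by plain tabular inputs: a features-by-samples
expression matrix per species, a phenotype table, a CpG beta-value matrix,
and an optional GMT gene-set collection.

## Stage by stage

### Normalization

`normalize_microarray()` reproduces the vendor-style preprocessing chain
for one-color arrays: raw signals are floored at 1.0, log2-transformed,
each sample is shifted by its own 75th percentile, and each feature is
centred at its across-sample median. Two conventions are deliberately
explicit because array software rarely documents them:

* **Percentile definition.** Linear interpolation between order statistics
  (`stats::quantile(type = 7)`), configurable via `quantile_type`.
* **Stage-wise invariants.** Immediately after the shift, every sample's
  75th percentile is exactly 0; after the baseline step, every feature's
  median is exactly 0. The baseline step necessarily moves sample
  percentiles off 0 again (any per-feature centring does), which is why
  `keep_stages = TRUE` exposes the intermediate matrix: each invariant is
  checkable at the stage where it holds.

Whether the vendor computes the per-sample percentile over detected probes
only is unknown; the full matrix is used here.

### Human association screen

`correlate_phenotype()` computes per-probe Pearson correlations with a
chosen symptom score (Spearman as a rank-based confirmation, partial
correlation given covariates such as age as an option), two-sided p-values
from the t distribution with `n_used - 2` degrees of freedom. Subjects
with a missing score are dropped pairwise-complete and `n_used` is
recorded — symptom questionnaires do go missing for individual subjects,
and the record keeps the analysis honest about its effective n.
`case_control_tests()` uses the pooled-variance Student t-test (not Welch:
the convention named by the study design this mirrors), two-sided, with an
optional one-way ANCOVA whose group term carries `(1, n - 3)` degrees of
freedom.

### Mouse differential expression

`differential_expression()` applies the same pooled t-test per gene on the
log2-scale matrix and adjusts with Benjamini–Hochberg (`bh_fdr()`, a
validated wrapper of `stats::p.adjust`). A count-model analysis (negative
binomial etc.) is intentionally out of scope: the pipeline follows the
t-test-on-log-expression design it mirrors, and flags raw-count input only
to apply `log2(x + 1)` first. The signed linear fold-change convention is
`fc_linear = sign(log2fc) * 2^|log2fc|`, so a 1.4-fold downregulation
prints as −1.4 and `|fc_linear| >= 1` always.

### Integration gates

`build_integration()` matches features across species by case-insensitive
gene symbol (human `PDE4B` vs mouse `Pde4b`); no ortholog database is
consulted. Direction consistency means the human correlation and the mouse
fold change share a nonzero sign; a zero on either axis is conservatively
inconsistent. Three gates exist explicitly rather than one blended rule:

| gate | human | mouse | consistency | purpose |
|------|-------|-------|-------------|---------|
| `broad` | p < 0.05 | q < 0.05 | not required | concordance characterization; single-pass >10 SD outlier exclusion on the fold-change axis |
| `hybrid` | \|r\| > 0.40 | q < 0.001 | not required | effect-size/FDR joint gate |
| `stringent` | \|r\| > 0.40 | q < 0.001 and \|FC\| > 1.36 | required | the curated overlap |

All inequalities are strict. Notable open choices, resolved as follows:

* **Probe multiplicity.** The human side is probe-level; a gene passes a
  gate if *any* of its probes passes, and each probe keeps its own record.
* **Outlier axis.** The >10 SD exclusion applies to the mouse fold-change
  axis, the axis where a blow-up is plausible; mean and SD are computed
  once, including the candidate outlier (no re-iteration).
* **Thresholds are configurable** (`threshold_spec()`) because the two
  fold-change cutoffs in circulation (log2 0.38 ≈ linear 1.30 for volcano
  classification vs linear 1.36 for the gate) do not coincide; both
  defaults are kept at their respective stages.

`concordance()` z-standardizes both axes before correlating, so the
statistic is comparable across effect-size scales. `curate_candidates()`
adds the third dataset: a gene must differ between patients and controls
(p < 0.05) *and* in the direction its symptom correlation implies — a gene
negatively correlated with severity must be lower in patients.

### Co-expression and overrepresentation

`coexpression_screen()` correlates every probe against the target probe
and keeps |r| > 0.6 (strict). `enrich_hypergeometric()` is a one-sided
upper-tail hypergeometric test, `P(X >= k)` with
`X ~ Hypergeom(N, K, n)`, BH-adjusted across sets. The universe defaults
to all genes measured on the platform after symbol harmonization — the
honest background when the hit list came from that platform — and is
configurable. No GO-graph propagation or rank-based (GSEA-style)
statistics: the engine consumes any GMT file as-is.

### Methylation screen and mediation

`tripartite_screen()` requires, per CpG site, significant correlation with
both symptom severity and target-gene expression (α = 0.05 two-sided,
uncorrected across the candidate gene's sites — a deliberate screening
convention, with `adjust = "BH"` available), plus *sign compatibility*:
`sign(r_meth_expr) * sign(r_expr_symptom) = sign(r_meth_symptom)`, all
three nonzero. Note that a positive methylation-expression correlation is
admissible: gene-body/enhancer methylation can promote expression.

`mediation_analysis()` is the classic product-of-coefficients model:
OLS fits of `m ~ x` (path *a*), `y ~ x + m` (*b* and direct *c′*), and
`y ~ x` (total *c*); indirect effect *ab* with Sobel standard error
`sqrt(a²SE_b² + b²SE_a²)`; nonparametric case-resampling bootstrap CI
(percentile by default, BCa by flag — the choice matters little at these
effect sizes but the default is stated) under a fixed seed. The identity
`c = c′ + ab` holds exactly on complete-case OLS and is tested to 1e-8.

Paths are reported on **both** the raw and the fully standardized scale,
with the standardized indirect as the headline. The reason: raw-scale path
products are unit-bound (a slope per beta-value unit times a slope per
log2-expression unit does not live on the symptom scale), and published
mediation tables frequently mix scales — reporting both removes the
ambiguity. "Complete mediation" is declared when the standardized indirect
is significant (Sobel p < 0.05) while *c′* is not.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it generates the exact
statistical structure every downstream stage assumes, with ground truth.

* **Cohort**: 32 patients, 16 controls; symptom severity on a continuous
  0–40 intrusion-subscale-like scale (patients centred at 20, controls at
  3, residual SD 5, clipped to the scale). The scale itself is irrelevant
  to correlation-based stages and is documented in the truth file.
* **Planted human probes**: `effect_sign * beta * z(symptom) + noise` with
  `beta = noise_sd * r / sqrt(1 - r²)` — closed-form control of the
  population correlation (default magnitude 0.55, negative sign mirroring
  the exemplar's direction). The matrix is emitted on the raw linear scale
  (`2^value` around per-probe baselines) so normalization runs exactly as
  on vendor output.
* **Planted mouse genes**: the same symbols (mouse-cased), shifted by
  log2(1.5) between `React-30` and `NR` with matching sign, 8 animals per
  group.
* **Mediation structure**: one CpG's logistic-Gaussian beta value drives
  target expression (`a`, default 3.86 per beta unit), which drives
  symptom severity (`b`, default −8.54), with a configurable direct path
  (default 0 — complete mediation).
* **Co-expression block**: probes loading at 0.7 on the standardized
  target expression.
* Everything else is independent noise; a fixed seed gives byte-identical
  bundles, and the caller's RNG stream is left untouched.

**Noise calibration.** `mouse_noise_sd` defaults to 0.12 (within-group SD
on the log2 scale). This was fixed by a power simulation run before any
recovery test was written: at the default effect sizes a planted gene
passes the human |r| > 0.40 gate with probability ≈ 0.90 (a property of
r = 0.55 at n = 48, no noise knob involved) and the stringent mouse gate
with probability ≈ 0.98, giving a joint per-gene recovery probability of
about 0.9.

**What the generator does not emulate**: probe chemistry and background
correction, count-level RNA-seq noise, batch structure, cell-type
composition of blood, sex or genotype effects, and correlated null probes.
Passing recovery and calibration tests therefore demonstrates that the
*statistical machinery* is correct and well-calibrated under its stated
model — not that real arrays meet that model. In particular the Gaussian
log-scale noise model is an assumption, not a property of any deposit.

One quirk worth knowing: at large mediation path sizes the symptom-scale
clipping at 0 and 40 attenuates the target gene's human correlation, so
the target is not guaranteed to clear the |r| gate even when the planted
signal genes do. That is a realistic feature (bounded questionnaire
scores), not a bug.

## Numerical and design choices

* Strict inequalities at every threshold.
* Zero-variance features are flagged (`ok = FALSE`), excluded from the BH
  family and from downstream screens, rather than silently producing NaN.
* Identical-group features (difference exactly 0 with zero pooled
  variance) report t = 0, p = 1 — evidence of no difference, not missing
  evidence.
* BH q-values and hypergeometric p-values are computed by `stats::p.adjust`
  and `stats::phyper`; both are verified in the test suite against
  independent brute-force oracles (explicit step-up double loop; exhaustive
  subset enumeration for N ≤ 15).
* Collinear covariates and perfectly collinear mediator/exposure pairs are
  errors with names, not silently dropped terms.
* All randomness flows from explicit integer seeds; the bootstrap and the
  generator restore the caller's RNG state.

## Problem sizes used by the test suite

The calibration tests run at the sizes the defaults encode: 5000 null
probes at n = 48 for the null tail of the human screen; 10 cohorts of
100 planted genes over ~5000 nulls for recovery; 200 cohorts at n = 32
with 1000 bootstrap resamples for CI coverage; 125 null CpG sites over 10
seeds for screen specificity; all hypergeometric configurations up to a
15-gene universe for the enumeration check. These sizes keep each
calibration property measurable with Monte-Carlo error well inside its
tolerance while the whole suite stays quick to run.

## Limitations

* Symbol matching is no substitute for orthology; genes with diverged
  symbols silently drop out of the universe.
* The human screen is probe-level throughout; no probe-to-gene expression
  collapsing is attempted.
* The tripartite screen's two per-site tests are treated as independent in
  its null expectation; when target expression and symptom are themselves
  strongly correlated (the interesting case!), selected-and-compatible
  null counts run above the independence product — the screen is a
  candidate generator, not an error-controlled test.
* The mediation model is three linear regressions: no latent confounders,
  no measurement-error correction, and causal language is only as good as
  the design that produced the data.

## A worked run

```{r pipeline, eval = FALSE}
bundle <- simulate_cohort(sim_config(seed = 1))
run <- run_pipeline(bundle, n_boot = 2000, seed = 1)
run$summary
glance(run$mediation)
plot_concordance(run$broad)
```
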