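---
title: "Models and methods: task-connectome small-worldness, polygenic scoring, and moderation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: task-connectome small-worldness, polygenic scoring, and moderation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmtopo)
```

## The scientific question

Working-memory deficits in schizophrenia are often framed as a problem of
neural inefficiency: the functional connectome of patients appears more
*segregated* (locally clustered) during working-memory load, without a
matching gain in global integration. wmtopo implements the full analysis
chain used to study this in case / unaffected-sibling / control designs:
weighted small-world indices of the 2-back task connectome, normalized
against degree-preserving null graphs and compared across groups; polygenic
risk scores (PRS) for schizophrenia; and moderation models asking whether
symptoms and connectome topology alter the PRS-performance relationship.
Because raw imaging and genotype data of such studies are typically not
depositable, the package pairs every analysis stage with a synthetic-data
generator with known ground truth, so each stage is testable end to end.

## Connectome construction

Per subject, the volumes of all 2-back task blocks are concatenated (the
0-back condition is a vigilance control, not a working-memory probe), mean
ROI time series are correlated (Pearson), and the correlation matrix is
Fisher-z transformed. The linear effects of age, sex, and education are then
removed edgewise across subjects by OLS residualization.

Conventions worth stating explicitly:

* Volume indices are 0-based; block intervals are half-open. One stated
  convention avoids off-by-one drift between files.
* Correlations of exactly ±1 (which arise in degenerate simulated inputs,
  never in realistic data) are clipped to ±(1 − 1e-7) before `atanh`, with a
  warning. This keeps toy pipelines total without affecting realistic runs.
* Residualization re-adds each edge's grand mean, so the corrected weights
  stay on the familiar Fisher-z scale. Proportional thresholding is
  rank-based per subject, so this choice cannot change which edges survive;
  it only keeps curves interpretable. Whether the original analyses kept
  the intercept is not documented anywhere we know of, so this is a package
  choice, flagged as such.
* Sex is coded 0/1; OLS residuals are invariant to any affine recoding.

## Density thresholding and weighted graph metrics

Each corrected matrix is thresholded over the density grid 0.10, 0.12, ...,
0.50 (21 points): at density *d* the strongest
⌊*d*·*n*(*n*−1)/2⌋ edges are retained with their weights. Ties at the cut
are broken by (weight desc, node-pair lexicographic) so results are
bit-reproducible. Negative Fisher-z edges are set to zero before
thresholding by default (`negative_policy = "zero"`); the weighted
clustering and path-length formulas require nonnegative weights, and
published pipelines are typically silent about the sign policy. An
`"abs"` alternative is available.

At each density we compute:

* **Clustering** `C`: the Onnela weighted clustering coefficient. Weights
  are scaled by the network-wide maximum and
  c_i = (1/(k_i(k_i−1))) Σ_{jh} (ŵ_ij ŵ_jh ŵ_hi)^{1/3}, with c_i = 0 for
  degree < 2; `C` is the node mean. The Onnela variant is the default of
  the widely used connectivity toolboxes, which matters for reproducing
  normalized gamma values.
* **Characteristic path length** `L`: mean shortest-path length with edge
  lengths 1/w. At sparse densities graphs can disconnect; disconnected
  pairs are *excluded* from the mean (their count is attached as an
  attribute) rather than imputed, which avoids infinite lambda while
  leaving the exclusion auditable.
* **Null normalization**: 20 null graphs per density (configurable) are
  built by degree-preserving double-edge swaps on the binary topology
  (about 10 attempted swaps per edge), after which the original weight
  multiset is randomly reassigned to the rewired edges. Each null therefore
  preserves node count, edge count, the exact degree sequence, and the
  weight multiset. Whether published pipelines rewired weighted edges
  directly or rewired topology and reassigned weights is ambiguous; we
  chose the latter as the defensible reading that preserves the weight
  distribution exactly. gamma = C/C_null, lambda = L/L_null,
  sigma = gamma/lambda, with C_null, L_null ensemble means. On complete
  graphs no swap can succeed, so nulls degrade to weight-permuted copies
  with a warning.

Curves are collapsed to one scalar per metric per subject by summing values
across densities ("functional" synthesis). On a uniform grid this equals
the Riemann area up to the constant grid step, which cancels in any group
comparison; the synthesis is linear, so any affine reading of the original
"sum of differences" description preserves group ordering. Regional
analysis applies the same synthesis to each node's clustering curve.

## Group statistics

Omnibus group differences use classical one-way ANOVA (raw values) and
Pearson chi-square without continuity correction (categorical tables; the
uncorrected statistic is what published 2×3 sex-by-group tables reproduce).
`anova_from_summary()` reconstructs F from printed per-group
(mean, dispersion, n); the dispersion kind (`"sd"` or `"sem"`) is a
*required* argument because published tables sometimes label standard
errors as SDs — reconstructions of age/education and the network metrics
from such tables are only consistent with an SEM reading, while behavioral
rows are true SDs. A silent default would corrupt one or the other.
Post hoc pairwise comparisons default to Tukey HSD (unadjusted and
Bonferroni t tests available); published reports often leave the procedure
unnamed, so printed post hoc p-values are not treated as reproducible
anchors. Regional (per-node) p-values are corrected by Benjamini-Hochberg
step-up FDR.

## Genetics

QC removes SNPs with call rate < 0.95, MAF < 0.01, or Hardy-Weinberg
equilibrium violation at p < 1e-6. HWE uses a 1-df chi-square
goodness-of-fit of genotype counts against expectations at the sample
allele frequency — oracle-checkable and appropriate at that cutoff regime;
the exact test is a known alternative we did not implement. LD clumping is
greedy: SNPs are visited by ascending GWAS p (ties: lower chromosome, then
position) and retained unless an already-retained SNP within ±500 kb on the
same chromosome has dosage r² ≥ 0.2.

Scores at a threshold *t* are Σ log(OR)·dosage over clumped SNPs with
p ≤ t. Dosages are oriented to the weights' effect allele (reversed as
2 − d on label flips; SNPs matching neither allele are dropped and
counted); missing dosages are imputed as twice the effect-allele frequency,
a standard choice where the original pipelines are silent. The default
threshold grid is three landmarks (5e-8, 5e-5, 5e-3) plus a dense 0.1-to-1
grid in steps of 1e-4 — a dense-grid-plus-landmarks design of several
thousand scores; published threshold lists of this kind are often
typographically garbled, so the grid is configurable and its size logged.
The per-threshold score columns are standardized and the first principal
component, sign-fixed to correlate positively with the mean standardized
score, is the synthesized PRS, reported with its explained variance. On
nested threshold grids the score columns are extremely correlated, so the
first PC routinely explains well over 90% of variance.

## Moderation models

`moderation_model1()` fits Y ~ b0 + bX·X + bW·W + β·XW and
`moderation_model2()` adds a second moderator with its own interaction.
X and the moderators are mean-centered before products are formed (the
convention of the PROCESS macro family; centering affects the simple-effect
coefficients, not β). Inference is by case-resampling bootstrap with both
percentile and bias-corrected (BC, i.e. BCa without the acceleration term)
intervals reported, alongside analytic OLS p-values — reporting all three
makes the inferential route auditable. The default outcome in cohort
analyses is 2-back accuracy; mediation (indirect-effect) models are out of
scope, since the underlying design only identifies interaction effects.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. It emulates:

* **Cohort structure**: three groups sized 27/24/48 by default, with
  demographic, symptom, behavioral, and head-motion summaries aimed at a
  published three-group early-onset schizophrenia working-memory cohort
  (cases ~18.4 y, accuracy under 2-back load 0.70/0.77/0.84 with SDs
  0.14/0.18/0.12, negative-binomial interpolated-volume counts, etc.).
  Symptom scores are truncated-normal emulations — the real scale
  distributions are not published beyond means and SDs, so truncation
  bounds follow the scales' admissible ranges. Between-group mean
  differences scale with `effect_scale`; 0 gives the null configuration.
* **Latent structure**: a subject-level multivariate Gaussian links genetic
  liability, negative/positive symptoms, network coupling, and accuracy
  with a configurable (PD-validated) correlation matrix, so downstream
  correlation and moderation analyses have known ground truth.
* **Time series**: stationary multivariate Gaussian per block. BOLD
  physiology (hemodynamics, autocorrelation, scanner noise, motion) is
  deliberately not modeled: every downstream stage consumes only the
  correlation structure, so the covariance is the complete ground truth.
  The 2-back covariance is I + c_i·S_g, where S_g is a weighted
  Watts-Strogatz network (ring lattice, 6 neighbors per side, rewiring
  probability 0.15 at baseline) scaled so its most negative eigenvalue is
  −1 — this guarantees positive definiteness for any coupling c_i < 1
  while keeping edge correlations as large as the PD constraint allows
  (a nearest-PD projection backstops configuration corner cases). Groups
  with a positive `clustering_effect` get both a more lattice-like network
  (reduced rewiring) and elevated coupling c_i; with the defaults
  (baseline coupling 0.55, EOS effect 0.5) the recovered group-mean sigma
  elevation is about 8-9% over controls, matching the magnitude such
  studies report. The 0-back condition shares a heavily rewired
  (rewiring 0.9, less clustered) network across groups.
* **Genetics**: dosages are drawn by thresholding latent Gaussians at
  Hardy-Weinberg quantiles of per-SNP frequencies (Unif(0.05, 0.5)), with
  block-diagonal LD from a shared latent factor per 10-SNP block
  (latent correlation 0.7; realized dosage r² is somewhat lower because
  thresholding attenuates correlation — the knob is a target regime, not a
  calibrated value). Causal SNPs (50 by default) load on the cohort's
  latent liability with sign matching their log-OR, so the true polygenic
  score correlates positively with liability; GWAS p-values derive from
  z statistics consistent with the weight magnitudes. 1% of calls are
  set missing so QC has work to do. No realistic LD maps, imputation, or
  ancestry structure are modeled.

Passing tests on these simulations show that the pipeline recovers the
structures the generator encodes — covariance topology, HWE marginals,
latent correlations, interaction coefficients. They cannot show robustness
to hemodynamic confounds, motion artifacts, realistic LD, or population
stratification, which the generator deliberately omits.

## Numerical and design choices

* All stochastic steps take explicit integer seeds; identical seed and
  configuration reproduce outputs bit for bit. Internal RNG use saves and
  restores the caller's RNG state.
* Proportional-threshold ties, clumping ties, and PC sign are all resolved
  by stated deterministic rules.
* Graph metrics are validated against brute-force oracles (exhaustive
  triple enumeration for clustering, Floyd-Warshall for path length,
  explicit sorts for thresholding) on a fixture set of graphs with up to 8
  nodes, to 1e-10.
* Desk-scale problem sizes, chosen as the package's own defaults for
  simulation studies: recovery experiments use 60-node networks, 8
  subjects per group, a 5-point density grid (0.15 to 0.45), 5 nulls per
  density, and 50 replicates; the null-calibration study uses 50
  Erdős–Rényi graphs at n = 100, d = 0.3; type-I error uses 500 cohort
  replicates at 10 subjects per group; moderation recovery uses 200
  replicates of n = 200 with 1000 bootstrap draws. The full 264-node,
  21-density, 20-null configuration is the analysis default and remains
  available through the same functions.

## Known limitations

* The characteristic path length excludes disconnected pairs; at very low
  densities with few nodes this can make L non-monotone in density in ways
  an imputation policy would not show.
* The BC bootstrap interval omits the acceleration term of full BCa;
  for the near-symmetric OLS sampling distributions involved the practical
  difference is small, and both percentile and BC intervals are reported.
* Reconstructed F statistics from printed summaries inherit the rounding
  of the printed means and dispersions; for very small F values (near 0.1)
  that rounding alone can move the reconstruction by a few percent.
* The generator's LD and allele-frequency models are schematic; clumping
  behavior on real reference-panel LD is not exercised.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(group_sizes = c(EOS = 8, SB = 8, HC = 8), n_nodes = 60,
                  seed = 7001)
co  <- generate_cohort(cfg)
ts  <- generate_timeseries(co, cfg)
top <- cohort_topology(co, ts, densities = seq(0.15, 0.45, by = 0.075),
                       k_null = 5, seed = 1)
aggregate(sigma_fda ~ group, top, mean)
anova_oneway(top$sigma_fda, top$group)
```
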