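---
title: "Methods: genotype-specific differential (phospho)proteomics with phosdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-specific differential (phospho)proteomics with phosdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

phosdiff analyses label-free intensity matrices from cohorts stratified
into four genotype groups of lung adenocarcinoma — EML4-ALK-rearranged,
EGFR-mutated, KRAS-mutated and triple wild-type — and asks three
questions: which proteins or phosphosites differ between groups, which of
those differences are specific to one genetic alteration, and which
kinases and gene sets move with them.

The data model is deliberately simple. An intensity matrix holds features
(proteins or phosphosites, identified as `GENE;residue+position`) by
samples, with `NA` encoding "not quantified". Zero intensities at read
time are converted to `NA`: in label-free quantification a zero is
censoring, not a measured abundance of zero. All statistics run on log2
intensities; the transformation is applied exactly once and tracked by a
scale flag.

## Filtering

Two filters precede any statistics:

* **Presence.** A feature is kept if observed in at least 50% of the
  samples of the KRAS, EGFR or WT group, or in at least 4 of the 6
  EML4-ALK samples. The EML4-ALK rule is a count, not a fraction: with
  six samples "at least half" would admit features seen three times,
  which is too thin a basis for a group-specific claim.
* **Localization.** Phosphosites need localization probability >= 0.75
  (class I sites); the boundary is kept. Sites below it may have the
  phosphate assigned to the wrong residue, which would corrupt
  site-level conclusions.

## Imputation

Missingness here is left-censored: the probability of dropout grows as
intensity falls. The imputation strategy therefore differs by how much
within-group evidence exists.

For **proteomes**, group-wise hybrid imputation: if a feature was
observed in at least half of a group's samples, missing cells are filled
by feature-kNN — the `k = 10` nearest features by Euclidean distance over
that group's samples (pairwise-complete, distances scaled by
`sqrt(n_total/n_shared)`; this is exactly `stats::dist`'s missing-value
convention) that are observed in the recipient sample contribute the mean
of their values there. Neighbours are features, not samples: with group
sizes from 6 to 31, sample neighbourhoods are ill-defined for the
smallest group while feature neighbourhoods are always well populated.
If the feature was observed in fewer than half, missing cells get the
recipient sample's 5th percentile of observed log2 intensities — a
per-sample low-abundance floor, matching the censoring interpretation.
Percentiles use linear interpolation between order statistics (type 7),
recorded in the run manifest.

For **phosphosites**, condition-specific imputation first: a feature
x group with observed fraction >= 0.5 is filled with draws from
`Normal(group mean, group SD)` (SD of a single observation treated as 0).
Whatever remains is tail-imputed per sample from a down-shifted normal,
`Normal(mean - 1.8 * SD, 0.3 * SD)` of the sample's observed values. The
1.8/0.3 constants are the widely used down-shifted-normal defaults; they
are exposed as `tail_shift`/`tail_scale` in `analysis_params()`. Both
passes are seeded, and a `deterministic = TRUE` mode fills with the
distribution means for exact-value testing. Imputation never modifies an
observed cell — this is asserted property-style in the test suite.

After phospho imputation, samples are median-scaled additively: every
sample is shifted so its median equals the grand median of per-sample
medians. No multiplicative scaling is applied, so within-sample spread is
preserved. Note that the anchor itself moves if a sample is globally
shifted; the operation is therefore invariant to per-sample offsets only
up to one common constant, which is all that difference-based downstream
statistics require. Whether to median-scale the proteomic dataset as well
is left to the caller; the pipeline default scales only the
phosphoproteomic branch.

## The adaptive test cascade

Parametric tests are used when their assumptions show no evidence of
failure, at gate alpha 0.05 (configurable):

* Shapiro-Wilk per group; a group with fewer than 3 values, or constant
  values, cannot be tested and is treated as non-normal.
* Levene's test centred at the median (Brown-Forsythe) for variance
  homogeneity — across all four groups for the omnibus test, and per
  pair for pairwise tests.

The omnibus test across the four groups is then ANOVA (normal,
homoscedastic), Welch-ANOVA (normal, heteroscedastic) or Kruskal-Wallis
(any non-normal group). Only features with omnibus p < 0.05 proceed to
the six pairwise comparisons, which use Student's t, Welch's t or the
Wilcoxon rank-sum test by the same gating (Wilcoxon exact when both
groups have at most 25 values and no ties, else the normal approximation
with continuity correction).

Within each feature, the six pairwise p-values are Benjamini-Hochberg
adjusted — the "FDR controlled separately for every feature" reading. A
cross-feature BH mode is available (`bh_scope = "global"`) for
sensitivity analysis. A comparison is a discovery when `fdr < 0.05` and
`|log2 fold-change| > 1` (fold-change over 2), both strict inequalities.
Fold-changes (`mean(group_a) - mean(group_b)` on log2 intensities, in the
fixed canonical pair order) are computed for every feature, including
those failing the omnibus gate: the kinase analysis consumes fold-changes
of *all* quantified sites, whereas test fields for gated-out features are
reported as undefined.

## Alteration specificity

The signed significance matrix (one entry in {-1, 0, +1} per feature and
comparison) is classified per feature:

* **group-specific**: all three comparisons involving a group are
  discoveries with a consistent orientation once re-expressed as
  (group minus other); the direction is UP or DOWN for that group. A
  feature may carry two group labels — e.g. one group above the middle
  pair which is in turn above a fourth group labels both the top group
  (UP) and the bottom group (DOWN).
* **partition**: features matching no group are tested against the three
  2-vs-2 partitions; all four cross-partition comparisons must be
  discoveries with consistent orientation and both within-side
  comparisons null.
* **mixed** (some discovery, no coherent pattern) or **none**.

Deeper patterns than 2-vs-2 are deliberately out of scope. The classifier
is verified against an independent brute-force evaluator on all 3^6 = 729
sign patterns. Per-group summary counts include doubly labelled features
in both groups; the unique union deduplicates.

Significant phosphosites are additionally compared with their parent
protein's fold-change in the same comparison. A site is flagged as a
protein-driven candidate when the protein moves in the same direction by
at least 75% of the site's log2 fold-change (`protein_driven_ratio`).
The rationale for a ratio rather than a strict `|protein| >= |site|`
rule: a 1.7-fold protein change under a 2.0-fold site change already
makes abundance the more parsimonious explanation, and a strict rule
would miss exactly that case. Sites without a quantified parent protein
keep an undefined protein fold-change and are never flagged.

## Kinase-substrate enrichment (KSEA)

For each comparison, with `s_bar` the mean log2 fold-change of a kinase's
quantified substrates, `p_bar` and `delta` the mean and the sample (n-1)
standard deviation over all quantified sites, and `m` the substrate
count:

    z = (s_bar - p_bar) * sqrt(m) / delta

with a two-sided normal p-value. A kinase is reported significant when
`m >= 3` and `p < 0.05`. Substrates are matched by the exact
`GENE;residue+position` key; no sequence-motif or window matching is
attempted (that belongs to machine-learning kinase predictors, out of
scope here). Signed log2 fold-changes are the input scale. The z-score is
invariant to shifting all fold-changes by a constant and to positive
rescaling — both asserted in the tests.

## Preranked GSEA with Cohen's d

Features are ranked by Cohen's d (pooled-SD standardized mean
difference) between the two groups of a comparison; undefined effects
(pooled SD zero) are dropped with a warning, and ties in the ranking are
broken by feature id for determinism. Enrichment uses the classic
weighted Kolmogorov-Smirnov running sum with weight exponent 1; the null
is `gsea_nperm = 1000` (default) random same-size gene draws per distinct
set size, the p-value is the one-sided same-sign tail frequency with a +1
pseudocount, NES divides the enrichment score by the mean |null ES| of
matching sign, and BH runs across the reported sets. Set size bounds
default to 10-500 after restriction to the ranked universe. A
permutation-based implementation was chosen over adaptive multilevel
algorithms because it is directly verifiable against a brute-force
running-sum oracle; its stochastic error is absorbed by the NES/FDR
scale. Gene-set permutation (not sample permutation) is the only
coherent null for a preranked list. Protein-to-gene mapping is the
caller's responsibility; the module consumes an already-mapped ranking.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
so that every stage is testable offline with known ground truth:

* four groups of 6/23/31/22 samples (the modelled cohort design);
* per-feature baselines `Normal(25, 2)` in log2 units, residual noise
  `Normal(0, 0.5)`;
* group-specific spiked effects (default 2 log2 units, comfortably above
  the fold-change threshold of 1 log2 unit so recovery tests probe the
  pipeline, not the margin), including 2-vs-2 partition effects;
* kinase designs that add a coordinated shift to a substrate set, plus
  decoy kinases with unshifted substrates;
* localization probabilities from `Beta(9, 1)` (mean 0.9, so most sites
  pass the class-I filter);
* MNAR dropout: a cell survives with probability
  `1 - plogis((midpoint - log2 intensity) * slope)`. The defaults
  (midpoint 22.5, slope 0.8) give ~20% overall dropout under the default
  intensity distribution, computed from the model, with the dropout rate
  strictly decreasing in intensity.

Spiked effects default to up-shifts. This matters: a down-shift applied
to a low-abundance feature pushes it below the detection floor in its
target group while the comparison groups sit near the floor themselves,
so after percentile/tail imputation the recoverable fold-change
collapses. That saturation is a property of left-censored data, not of
the pipeline; signed designs (`make_spike_design(signs = c(1, -1))`) are
available precisely to demonstrate it.

What the generator does **not** emulate: peptide-level evidence, batch
effects, correlated features (co-regulated complexes), heavy-tailed
noise, or sample-specific depth differences beyond what MNAR induces.
Passing recovery tests therefore show the pipeline's rules and
arithmetic are right under the assumed model — not that the model captures
every pathology of real FFPE cohorts.

## Numerical and design choices

* Gate alpha 0.05 for Shapiro-Wilk and Levene, omnibus gate at raw
  p < 0.05 — conventional defaults, configurable in `analysis_params()`.
* Constant features produce p = 1 (no evidence) rather than errors.
* Percentile type 7; KSEA delta uses the sample SD; both recorded in the
  run manifest.
* The pipeline's master seed fans out to fixed per-stage child seeds, so
  toggling a stage never changes another stage's random stream; identical
  config + seed reproduces every output byte for byte.
* Problem sizes used by the packaged recovery experiments: 2000 features
  x 82 samples, 40 spiked features, 3 seeds for spike recovery; 500
  sites with one spiked and one decoy kinase (8 substrates each) for
  kinase recovery; 200-feature cohorts x 5 seeds for null calibration.
  These sizes give stable empirical rates while keeping a full run in
  minutes on one CPU.

## Known limitations

* Covariates (sex, stage, smoking, tumour content) are carried in the
  metadata but not adjusted for; the test cascade is strictly group-wise.
* Down-regulation of low-abundance features is intrinsically hard to
  recover under MNAR censoring (see above); sensitivity claims apply to
  effects clear of the detection floor.
* KSEA inherits the incompleteness of the supplied kinase-substrate
  annotation; kinases absent from it are invisible.
* The per-feature BH scope controls FDR within each feature's six
  comparisons, not across the feature dimension; cross-feature FDR is
  available as a sensitivity mode and will generally be more
  conservative.
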