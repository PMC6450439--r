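---
title: "Methods: targeted immune panel analysis with immunopanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted immune panel analysis with immunopanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`immunopanel` analyses targeted immune gene-expression panels measured as
digital probe counts: a few hundred endogenous genes, a set of
housekeeping reference genes, a spiked positive-control concentration
ladder, and negative background probes, hybridised one sample per lane.
This vignette records the models and conventions behind each stage, the
parameters that matter, and the design choices made where the method was
genuinely open.

## The data model

A `panel_experiment` bundles a probes-by-samples count matrix with the
panel annotation (probe class, ladder concentration) and the sample
metadata (treatment arm, dosing regimen, time point, tissue, replicate),
and tracks the processing stage: `raw` integer counts,
`background_subtracted`, or `normalized` floats. Gene identity is the
gene symbol, matched case-sensitively: panel symbols are controlled
vocabularies and silent case-folding hides annotation errors.

Lane files use the sectioned comma-separated RCC text dialect
(`<Header>`, `<Lane_Attributes>`, `<Code_Summary>` with
`CodeClass,Name,Accession,Count` rows, one file per lane). Positive
probes carry their ladder concentration in the conventional
`Name(conc)` suffix so that a written experiment reads back bit-identical.

## Background and exclusion

Negative probes measure non-specific binding. The background model pools
every negative-probe count across all lanes and summarises them by their
mean and sample standard deviation (n−1 denominator; pooling across
lanes, rather than per lane, stabilises the estimate at the cost of
ignoring lane-specific background, which the platform's scalar lane
effects make a reasonable trade). Endogenous and housekeeping counts are
reduced by the mean background and floored at zero. A gene is excluded
from analysis when its mean raw count over an analysis unit's samples is
strictly below `mean + 2·sd`; the analysis unit is the tissue-by-regimen
cell, so each contrast works on a consistent gene universe.

## Normalization

Two multiplicative per-lane factors are applied in order:

1. **Positive-control factor** — the arithmetic mean over lanes of the
   geometric mean of the positive probes, divided by the lane's
   geometric mean. This equalises the spike-in ladder across lanes and
   absorbs scalar lane effects.
2. **Housekeeping factor** — the same construction over the selected
   housekeeping genes, computed after positive-control scaling.

After normalization the per-lane geometric mean of the selected
housekeeping genes is identical across lanes (the suite asserts equality
to 1e−9 relative). Scaling all counts in one lane by a constant `c`
(controls included) leaves the normalized matrix unchanged *up to a
single global constant*: the pooled arithmetic-mean numerator of the
factor is itself moved by the scaled lane, which rescales every lane
equally. All ratio-scale outputs (log2 ratios, t statistics, Z-scores)
are therefore exactly invariant, and that is the form the tests assert.
Zero housekeeping counts are guarded by a +0.5 pseudocount before any
geometric mean or log2, logged when triggered; 0.5 is small against
panel-scale counts while avoiding −∞.

Housekeeping genes are selected with the geNorm stability analysis: the
stability measure `M` of a candidate is the mean, over the other
candidates, of the standard deviation across samples of their pairwise
log2 ratio; the least stable gene is removed iteratively (ties broken by
removing the lexicographically smallest symbol, for determinism) until
two remain. The number of genes kept uses the pairwise variation
`V(k, k+1)` between normalization factors built from the `k` and `k+1`
most stable genes: the smallest `k ≥ 3` with `V < 0.15` (the
conventional cutoff from the geNorm literature), falling back to the
`k` minimising `V`.

## Differential expression

Per-gene ratios are `log2(mean_case / mean_reference)` of normalized
counts, each treated group matched to its dosing-, time- and
tissue-matched vehicle; per-sample ratios against the reference mean
feed heatmap exports. Two per-gene models are available, chosen globally
per run and recorded per gene:

- **log-linear** (default): ordinary least squares of
  `log2(count + 0.5)` on the case indicator — the pooled-variance
  t-test with `n − 2` degrees of freedom. Zero residual variance is
  flagged degenerate.
- **simplified negative binomial**: NB regression of raw counts with a
  log link and a lane offset equal to the log inverse combined
  normalization factor; the gene dispersion comes from the method of
  moments on Poisson residuals (`α = Σ[(y−μ)² − μ]/Σμ²`, floored at
  1e−8, so underdispersed genes collapse to the Poisson limit) and is
  held fixed for the Wald test. Fit failures fall back to the
  log-linear model, recorded in `model_used`.

The mixture model some vendor pipelines use per gene is deliberately not
reproduced — its selection heuristic is unpublished — and the
responder-mixture phenomenon it targets lives in the simulator instead,
where it belongs for testing.

Raw p-values are Benjamini–Hochberg adjusted within each contrast
(matching per-comparison gene lists), and a gene is called when
`q < 0.05` and `|log2 ratio| > 1`, both strict. Sequential
within-treatment contrasts (week 5 vs 1, 9 vs 5, 13 vs 9) reuse the same
machinery with the later time point as case.

## Gene-set scores

For a set of `G` genes with per-gene t-statistics, the **global
significance score** is `sqrt(mean(t²))`: cumulative evidence for
differential expression regardless of direction. The **directed score**
uses the signed mean of signed squares, `s = mean(sign(t)·t²)`, mapped
back to the t scale as `sign(s)·sqrt(|s|)`. This convention was chosen
because it collapses to ±global when all genes move together and to
zero under perfect cancellation — a set full of strongly regulated
genes can still have a near-zero directed score. By construction
`|directed| ≤ global` (tested exhaustively).

The **pathway Z-score** summarises a set's expression per sample: genes
are Z-scaled across samples (making the score invariant to per-gene
affine rescaling), the first principal component of the samples is
taken, its sign is oriented so the mean gene loading is positive
(higher score = higher average pathway expression; PCA signs are
otherwise arbitrary and orientation stabilises regression tests), and
the scores are Z-scaled to mean 0, sd 1. Zero-variance genes are
dropped with a message. Whether Z-scaling precedes or follows the PCA
is ambiguous in common practice; here it is both, each documented.

## Immune cell profiling

A cell type's score in a sample is the mean log2 normalized expression
of its marker genes — a relative abundance proxy, never an absolute
count, and never comparable across cell types (the output layout keeps
one table per type). The packaged marker map covers 13 mouse immune
cell types from pan-leukocyte *Ptprc* through NK markers *Ncr1*/*Xcl1*.

For multi-marker types a **confidence p-value** asks whether the
markers co-vary as a shared abundance signal would force them to: the
statistic is the mean pairwise Pearson correlation across samples, its
null built by independently permuting each marker's values across
samples (10,000 permutations by default, seeded). This permutation form
is a stated convention: the platform's own threshold computation is not
public. All types are reported regardless of confidence, since
low-confidence marker sets can still be useful with prior support.

Group comparisons use the two-sided Wilcoxon rank-sum test: exact for
total `n ≤ 20` (enumeration when ties are present), normal
approximation with continuity correction otherwise.

## Association analyses

Pathway-phenotype screening computes Spearman's ρ (average-rank ties)
between per-sample pathway Z-scores and each phenotype endpoint —
ordinal histopathology scores (0–4) and percent-positive staining —
with a two-sided p from the t approximation
`t = ρ·sqrt((n−2)/(1−ρ²))`. A correlation is significant when
`ρ > 0.5` or `ρ < −0.5` *and* `p < 0.05`; non-significant cells are
masked downstream (blank-cell convention). Hierarchical clustering is
agglomerative with Euclidean distance and average (UPGMA) linkage; PCA
summaries are column-centred, unit-variance-scaled by default (the
choice is configurable since published figures are often ambiguous
about row scaling), with per-group 95% ellipses from the chi-square
quantile of each group's 2-D coordinate covariance. Venn overlaps of DE
gene lists are exact exclusive-region cardinalities for up to 5 sets.

## Network clustering

Interaction edges come from user-supplied lists scored in [0, 1] (the
0–1000 dialect is auto-rescaled when a file's maximum exceeds 1); edges
are kept when the combined score is at least 0.7 (inclusive) and both
endpoints are significant genes. Markov clustering uses the canonical
scheme: self-loops weighted by each node's maximum incident weight,
column-stochastic normalization, then alternating expansion (matrix
squaring) and inflation (entrywise power 1.5, renormalisation) with
per-iteration pruning of entries below 1e−8, until the largest entry
change falls below 1e−6 or 200 iterations. Clusters are the connected
components of the converged matrix's support, which always refine the
input graph's components. The self-loop and pruning conventions are
documented choices; at inflation 1.5, modules coupled by several
above-threshold bridges can genuinely merge — that is a property of the
algorithm, not of this implementation, and the test suite checks
agreement with an independently written reference implementation on
random graphs.

## The synthetic-data generator

Every stage is exercised against generated data with known ground
truth; the generator emulates the study design the pipeline targets and
its defaults are fixed once:

- **Design**: vehicle vs particle-instilled arms; a single-dose cohort
  sampled at day 1, a four-weekly cohort at day 1, and a chronic
  four-weekly cohort at weeks 1, 5, 9, 13 (lung throughout; kidney and
  spleen at week 13), 8 replicates per cell by default.
- **Counts**: negative binomial with variance `μ + αμ²`; baselines are
  log-normal (log2 mean 7, sd 2 — plausible targeted-panel scale),
  dispersions gamma with mean 0.1. Housekeeping genes are higher and
  tighter (log2 mean 9, α = 0.005) with no treatment effect; planted
  unstable housekeeping genes receive extra per-sample log2 noise
  (sd 1). Negative probes are Poisson with mean 10. Positive probes are
  Poisson around `150 counts/fM × ladder × lane scale`, a realistic
  instrument sensitivity that keeps the lowest ladder point (0.125 fM)
  clearly above zero; the ladder is the 4-fold series 128 … 0.125 fM.
  Lane scale factors are log-normal (sdlog 0.1).
- **Effects**: a fraction (default 10%) of endogenous genes carries a
  ±2 log2 effect (80% up, matching the predominance of induction in
  inflammatory exposures). Single-dose treated samples split into
  high responders (default 3 of 8) carrying the full effect and low
  responders carrying 0.25× — the attenuation value is an assumption,
  stated here, not a measured quantity; all four-weekly treated samples
  respond fully.
- **Severity and phenotypes**: a latent severity grows linearly in time
  for treated samples (0 for vehicle); ordinal endpoints are noisy
  discretised monotone transforms clipped to 0–4, percent endpoints are
  logistic transforms on 0–100, with Gaussian latent noise (sd 0.3).
  On the chronic-lung population (2 arms × 4 weeks × 8) this yields
  severity–endpoint rank correlations comfortably above 0.8.
- **Networks**: planted modules are fully connected with scores in
  0.85–0.95; between-module edges appear with probability 0.1 and
  scores in 0.2–0.5, i.e. below the 0.7 confidence cut, matching how
  curated high-confidence edges concentrate within functional modules.

What the generator does *not* emulate: probe-level cross-hybridisation,
positional lane effects beyond a scalar, count-level correlation
between genes (other than planted marker/module structure), or
realistic pathway co-membership of effects. Passing tests therefore
demonstrate the pipeline's statistical behaviour under its own model
assumptions — calibration, recovery, invariants — not performance on
any particular animal dataset.

## Problem sizes and numerical conventions

The test suite and the acceptance script size their simulations to
desk scale as the package's own reproducibility choices: null
calibration uses 20 seeds of 10,000 genes at n = 8 per group;
planted-effect recovery uses 50 seeds of 2,000 genes with 10% DE at
|log2| = 2 (median sensitivity and mean empirical FDR are the reported
operating characteristics); geNorm recovery uses 100 seeds of 7
housekeeping genes with 2 planted unstable; Markov-cluster recovery
uses 50 seeds of 3 planted 6-gene modules. Tie-breaks are deterministic
everywhere (lexicographic in geNorm; hclust's input-order convention in
clustering — on continuous data exact distance ties have probability
zero, so a bespoke tie-break was not layered on top of it). All
stochastic steps take explicit seeds, and a fixed configuration plus
seed reproduces every output byte for byte.

## Known limitations

- The per-gene model choice is global per run; no attempt is made to
  reproduce vendor per-gene model selection.
- The marker-confidence permutation test is a documented stand-in for
  an unpublished platform computation; its p-values are calibrated
  under independence but are not numerically comparable to vendor
  output.
- The directed-score formula is a convention with the right limits, not
  a published formula; directed scores from other software may differ
  numerically while agreeing in sign and ordering.
- Background subtraction with flooring is not scale-equivariant, so
  absolute normalized counts depend weakly on the background estimate;
  ratio-scale outputs do not.
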