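---
title: "Class-conditional screens for gene-property relationships: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-conditional screens for gene-property relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neurocorr)
```

## The problem

Neurons divide into broad classes -- excitatory (glutamatergic) and
inhibitory (GABAergic) -- that differ systematically in both gene expression
and physiology. When gene expression and electrophysiological or
morphological properties are correlated *across* cell types, that
between-class contrast dominates: a gene enriched in inhibitory types will
correlate with every property that also differs between classes, whether or
not the two have anything to do with each other. Conversely, a genuine
within-class relationship can be cancelled by opposing class offsets and
disappear from the pooled correlation (Simpson's paradox). `neurocorr`
implements a screening framework that separates these situations, assesses
whether the adjusted slopes replicate across datasets, and pushes the same
question down to cell-to-cell variation within a type using PatchSeq data.

## The unit of analysis

The screen operates on **cell-type profiles**: per-type means of
log~2~(CPM+1) expression (mean of logs, not log of means) and of transformed
properties. Types are defined by Cre driver line x cortical layer (or layer
group) x class, and enter the electrophysiology analysis only with >= 6
cells in both the RNA-seq and ephys modalities (>= 3 for morphology). Genes
enter only if their type-level mean expression reaches 1 CPM
(log~2~(1+1) = 1) in at least 10 types; we apply this on the type-level
log-scale summary because that is the quantity every downstream model
consumes, and the filter is monotone in both thresholds. Skewed properties
(input resistance, tau, capacitance, rheobase, maximum firing frequency,
AHP amplitude, adaptation ratio, input-output slope, latency, branchiness,
max branch order, total length, total volume) are log~10~-transformed;
non-positive values in that list become missing with a warning rather than
an error, because adaptation ratio and AHP amplitude can legitimately be
<= 0 at the margin. Sag is only comparable when measured at a similar
holding potential, so it is invalidated (closed window) unless
-110 mV <= vm_for_sag <= -90 mV and resting potential >= -80 mV. Missing
property values are excluded pairwise, never imputed.

## The model family

For a gene with type-level log~2~ expression $G$ and a property $P$, with
class coded $C = 0$ (excitatory, reference) / $C = 1$ (inhibitory):

* model 1, class-independent: $P \sim G$
* model 2, class-only: $P \sim C$
* model 3, class-conditional: $P \sim G + C$
* model 4, interaction: $P \sim G + C + G{\times}C$

Model 1's p-value comes from the $t$-test on its slope; the
class-conditional p-value from the nested ANOVA of model 2 vs model 3; the
interaction p-value from model 3 vs model 4. All slopes are per log~2~ unit,
i.e. per 2-fold change in expression. A model-1 fit restricted to
inhibitory types is also run, as a second way of removing cross-class
contrast. Class-aware models are fitted only when the gene is expressed in
both classes (operationalised as nonzero mean log expression in at least
one type of each class -- the source analyses leave this undefined) and each
class contributes at least 2 types; a skipped fit is recorded as
*not tested*, which is distinct from non-significant and excluded from the
FDR family size.

Two identities are worth noting because the tests rely on them: the
interaction parametrisation gives the per-class slopes directly
($\beta_{exc} = \beta_G$, $\beta_{inh} = \beta_G + \beta_{G \times C}$,
provably equal to separate per-class regressions), and the conditional
slope equals the slope of class-demeaned $P$ on class-demeaned $G$
(Frisch--Waugh).

FDR correction uses the explicit Benjamini--Hochberg construction
$q = p \cdot (m/i)$ followed by a cumulative minimum taken from the largest
p-value downward. The family is one property x one model across all tested
genes (the natural analogue of per-property significant-gene counts); on
synthetic panels, where each gene drives its own private property column,
the per-property family would have size 1, so the screen accepts
`fdr_family = "model"` to pool all pairs per model instead. Classification
at FDR 0.1: significant in model 1 only = class-driven; in model 3 only =
non-class-driven but obscured; in both = shared; a significant interaction
is layered on top. Exemplar-gene selection for a property additionally
requires non-significance (q > 0.2) in both the class-independent and
interaction models, with deterministic tie-breaking (smaller conditional q,
then larger |slope|, then gene id) for reproducibility.

## Cross-dataset consistency

Given per-gene slopes from two datasets (here: a two-class panel and a
single-class reference panel restricted to non-projecting types), the
consistency of a model is the Spearman correlation of the paired slope
vectors over the gene intersection. Confidence intervals come from a
percentile bootstrap -- genes resampled with replacement, 100 resamples,
2.5th/97.5th percentiles -- and two models are compared by a *paired*
bootstrap: the same gene resample is used for both models in each
iteration and the percentile interval of the correlation differences is
examined for zero. We keep the default at 100 resamples to match the
procedure this mirrors, while noting that 100 gives coarse (and slightly
under-covering) percentile intervals; `n_boot` is configurable upward. All
resampling is driven by one seeded generator and is bit-reproducible.

## PatchSeq: within-type relationships

PatchSeq cells are normalized per protocol -- UMI datasets to a total of
2000 molecules per cell, read-based datasets to CPM, both then
log~2~(x+1) -- with library size computed over protein-coding genes only,
since dying or contaminated cells vary strongly in mitochondrial and
non-coding content. Transcriptome quality is scored by a deliberately
simple, pluggable surrogate: mean expression of "on" markers minus mean
expression of "off" (contamination) markers, min-max scaled to [0, 1]
within each dataset. Cells are mapped to a reference atlas by Spearman
correlation to cluster centroids over the atlas's highly variable genes,
then rolled up to subclasses (centroid ties are broken by cluster id order
and flagged). Per-type highly variable genes are ranked by excess variance
over a running-median mean-variance trend (window fraction 0.3) -- a
surrogate for published variance-decomposition methods, chosen so the
package has no dependency on their internals. A gene is tested only if
highly variable in >= 1 type in >= 2 datasets, and a (gene, type, dataset)
group contributes only if the gene is detected in >= 33% of its cells and
in >= 5 cells.

The test itself is a linear mixed model fitted by maximum likelihood (ML
rather than REML, because the likelihood-ratio test compares models
differing in a fixed effect): property ~ expression with a random intercept
for every (dataset x cell type) combination -- we read the grouping
`(1|dataset*cell_type)` as the interaction grouping; crossed random effects
are a defensible alternative but add little with 30 groups. Quality scores,
divided by their dataset mean (so each dataset's mean weight is 1), act as
regression weights; a weight of exactly zero (possible after min-max
scaling) would degenerate the objective and is floored at 10^-6. The LRT
statistic against the expression-free model is referred to chi-square with
1 df, and BH-FDR is applied per property over converged fits.

## The synthetic-data generators

The generators are first-class, tested code: they define the conditions
under which every claim about the pipeline is checked.

**Cell-type panel.** 14 excitatory / 34 inhibitory types (48 total,
mirroring the composition of the Cre-line survey this framework targets,
so class power asymmetries are reproducible), with type-level latent
expression $x_t = \mu + \delta 1[inh] + N(0, \sigma_{type})$ and property
$p_t = \alpha + \beta_{class} x_t + \gamma 1[inh] + N(0, \sigma_{noise})$,
then cell-level draws around type means ($\sigma_{cell}$) emitted on the
CPM scale so the log-transform and summarization stages are exercised.
Scenarios: null ($\beta = 0$), class-driven ($\beta = 0$,
$\delta, \gamma \neq 0$), shared ($\beta_{exc} = \beta_{inh} \neq 0$,
$\gamma = 0$), obscured, and interaction
($\beta_{exc} \neq \beta_{inh}$). For the obscured scenario the class
property offset is chosen per gene to cancel the *empirical* marginal
covariance of the type-level values exactly
($\gamma_g = -\beta\,S_{xx}/S_{xC}$): a fixed population-level offset such
as $-\beta\delta$ leaves a residual marginal slope of
$\beta\sigma_{type}^2/(\delta^2 v + \sigma_{type}^2)$, which is strongly
significant on noiseless data and would make the scenario
indistinguishable from "shared"; exact cancellation is what makes the
obscured case the clean Simpson's-paradox construction. Defaults
($\beta = 1$, $\delta = 2$, $\gamma = 2$, $\sigma_{type} = 1$,
$\sigma_{noise} = 0.5$, $\sigma_{cell} = 0.25$, 5 cells per type) give the
conditional model high power at $\beta = 1$ while keeping the noiseless
limit exactly solvable.

**Paired panels.** Per-gene true slopes shared between a two-class panel
and a single-class (inhibitory-only, 19-type) reference panel with a
controlled correlation (second-panel slopes are a blend of the shared and
an independent component). Setting `confound_sd > 0` adds a per-gene class
offset plus an expression class shift to panel A only, corrupting the
marginal slopes but not the conditional ones -- the planted-confounding
condition under which the conditional model should win the paired
comparison.

**PatchSeq bundle.** Five datasets x six subclasses x ten cells, mixed
UMI/read protocols, with per-cell latent expression driving both the
counts (multinomial sampling, quality-tied binomial thinning for dropout,
"on"-marker weights scaled by quality and "off"-marker weights by
1 - quality) and the property. Property measurement noise has variance
proportional to the inverse of the cell's realized normalized quality
weight. This choice matters: the weighted likelihood-ratio test assumes
residual variance inversely proportional to the weights, and with
homoskedastic property noise the weighted LRT is anticonservative under
the null (we measured ~8% of null p-values below 0.05). Tying the planted
noise to the realized weight is the construction under which the weighted
analysis is exactly the right model, so null calibration of the LRT is a
meaningful check rather than an accident. Real PatchSeq data offers no
guarantee of this structure; on real data the weighted test should be read
as a variance-stabilising heuristic, and its calibration there is an open
empirical question.

What the generators deliberately do not emulate: gene-gene correlation
structure, realistic per-gene expression distributions, batch effects
within a dataset, ambient-RNA contamination profiles, or any spatial/layer
structure beyond the type labels. Passing tests therefore certify the
statistical machinery under the stated model, not robustness to every
failure mode of real data.

## Numerical choices and degenerate inputs

* Exact fits (RSS numerically zero, threshold 10^-12 relative to the
  response scale) yield degenerate inference: coefficient p-values are 0
  for nonzero coefficients and 1 otherwise; a nested ANOVA whose full
  model fits exactly gives p = 0 if it improves on the reduced model and
  p = 1 if both fit exactly. This makes noiseless scenario panels exactly
  classifiable.
* Rank-deficient designs are an error naming the collinear columns, never
  a silent drop.
* PCA components are sign-fixed by requiring the largest-magnitude loading
  positive; types with any missing property in a family are excluded from
  that family's PCA rather than imputed.
* Bootstrap percentile intervals use the default quantile interpolation;
  Spearman ties get average ranks everywhere.
* Non-converged mixed-model fits are flagged and excluded from their FDR
  family.

## Problem sizes and reproducibility

The shipped analyses and checks run at deliberately modest scale: panels of
48 types with a few hundred to ~2400 genes, 200-gene paired panels with
200 bootstrap-coverage replicates, PatchSeq bundles of 300 cells, and 1000
null mixed-model fits for calibration; these sizes give stable Monte-Carlo
estimates for every quantity we assert while keeping a full run in the
minutes range. Every stochastic step takes an explicit seed, a global seed
is fanned out to fixed per-stage child seeds, and `run_pipeline()` writes a
manifest (thresholds, seeds, versions, output checksums); identical
configuration and seed reproduce every output byte for byte.

## Known limitations

* Single-gene linear models only: no multi-gene, regularized or nonlinear
  fits, and all outputs are correlational.
* The FDR family definition (per property x model) is a documented choice;
  the source analyses do not state theirs.
* The quality score and HVG trend are intentionally simple surrogates
  behind stable interfaces.
* With 100 bootstrap resamples the percentile CIs are coarse; coverage in
  our checks is ~90% rather than nominal 95%.
* The atlas mapper assumes the query and reference share enough (>= 50) of
  the atlas's HVGs and does not model platform effects beyond rank
  correlation's invariance to monotone distortion.
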