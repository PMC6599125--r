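# neurocorr

Screens for gene-property relationships across neuronal cell types that
account for cell class.

## The problem

Excitatory and inhibitory neurons differ systematically in both gene
expression and electrophysiology/morphology. A gene whose expression is
merely enriched in one class will therefore correlate, across cell types,
with every property that also differs between classes — and a genuine
within-class relationship can be cancelled by opposing class offsets and
vanish from the pooled correlation (Simpson's paradox). `neurocorr` is for
analysts of multimodal cell-type atlases (Cre-line-based surveys, pooled
literature data, PatchSeq) who want correlation screens that distinguish
these situations.

## What it computes

For each gene *G* and property *P*, on cell-type-level profiles, with class
*C* coded excitatory = 0 / inhibitory = 1:

| model | formula | p-value |
|---|---|---|
| class-independent | P ~ G | t-test on the slope |
| class-only | P ~ C | t-test on the class term |
| class-conditional | P ~ G + C | ANOVA vs P ~ C |
| interaction | P ~ G + C + G×C | ANOVA vs P ~ G + C |

Slopes are per log2 unit (per 2-fold expression change). Benjamini–Hochberg
q-values (q = p·m/i with a cumulative minimum from the largest p) are
computed per family, and each pair is classified at FDR 0.1: significant
independently only = class-driven; conditionally only = non-class-driven
but obscured; both = shared; a significant interaction is layered on top.
On top of the screen the package provides property PCA (E_PC1–3 / M_PC1–3),
cross-dataset slope-consistency with paired percentile bootstraps
(100 resamples), and a quality-weighted random-intercept mixed model with a
likelihood-ratio test for within-cell-type relationships in multi-dataset
PatchSeq data. Seeded generators plant each relationship scenario in
synthetic data, so every stage is validated against known truth.

## Worked example

The numbered scripts under `analysis/` run the full workflow on synthetic
data (seed 17). `analysis/02_screen.R` simulates a 48-type panel (14
excitatory / 34 inhibitory; 600 genes: 200 null and 100 each of the
class-driven, shared, obscured and interaction scenarios at noise
sd 0.5), summarizes cells to type profiles, runs the screen and prints:

```
              call
truth          class_driven conditional_and_interaction interaction_only
  class_driven           97                           0                0
  interaction             1                          79               20
  null                    1                           0                2
  obscured                0                           2                0
  shared                  0                           2                0
...
per-scenario recovery:
class_driven     obscured       shared  interaction
        0.97         0.98         0.98         1.00
```

i.e. at realistic noise, 97–100% of planted relationships are recovered in
their planted category. `analysis/03_consistency.R` plants a class confound
and compares models across a paired dataset:

```
independent model: rho = 0.508 [0.396, 0.605]
conditional model: rho = 0.995 [0.992, 0.996]
paired difference (cond - ind): 0.496 [0.390, 0.597], significant: TRUE
```

— the class-conditional slopes replicate across datasets; the marginal ones
are corrupted by the confound. `analysis/04_patchseq.R` runs the PatchSeq
arm (normalization, quality scoring, atlas mapping, HVG gating, weighted
mixed models):

```
atlas mapping: 100.0% of 200 cells assigned to the right subclass
mixed-model screen: 30 pairs tested after gating, 30 with q <= 0.1
mean fitted beta: -0.0452 (planted -0.05)
```

The methods vignette (`vignettes/class-conditional-screens.Rmd`) documents
the models, parameter defaults, generator design and known limitations.

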