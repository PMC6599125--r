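Package: neurocorr
Title: Class-Conditional Screens for Gene-Property Relationships Across Neuronal Cell Types
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for relating gene expression to electrophysiological and
    morphological properties across neuronal cell types while accounting for
    cell class (excitatory versus inhibitory). Implements a class-independent,
    class-conditional and interaction linear-model screen with nested-ANOVA
    tests and Benjamini-Hochberg FDR, cross-dataset slope-consistency
    bootstraps, and a quality-weighted mixed-effects analysis of within-type
    variation in PatchSeq data, together with seeded synthetic-data generators
    that plant known relationship scenarios for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
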