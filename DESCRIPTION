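Package: intsig
Title: Cross-Study Intestinal Meta-Signature Analysis for Barrett's
    Oesophagus and Oesophageal Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving an intestine-enriched reference gene
    signature from normal-tissue expression comparisons, building
    cross-study disease meta-profiles by concordant intersection,
    decomposing a disease profile into intestine-like and non-intestinal
    components, and quantifying maintenance and specificity of the
    signature across disease stages with 2x2 chi-square association
    statistics. Includes Mann-Whitney/fold-change differential
    expression with an annotation-mask harmonization step for
    heterogeneous microarray platforms, hierarchical clustering of
    signature-restricted expression with a label-separation score and
    Newick export, delta-delta-Ct relative quantification for qPCR, and
    Chou-Talalay median-effect/combination-index synergy analysis.
    Seeded synthetic-data generators emulate the multi-study microarray,
    qPCR and dose-response regimes with ground truth attached.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
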