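---
title: "Methods: cross-study intestinal meta-signature analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study intestinal meta-signature analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intsig)
```

## The scientific question

Barrett's oesophagus (BO) is an intestinal-type metaplasia of the lower
oesophagus and the main precursor lesion of oesophageal adenocarcinoma
(OAC). A natural way to quantify how "intestine-like" the metaplastic and
malignant tissues are is to (i) define a reference signature of genes that
distinguish normal intestinal tissues (duodenum, colon) from normal
oesophageal squamous epithelium, (ii) build cross-study meta-profiles of
genes consistently dysregulated in BO and in OAC, and (iii) measure how
much of the disease profiles this intestinal signature accounts for, and
how much of it persists through the metaplasia-to-carcinoma transition.
`intsig` implements that analysis as a reusable, tested pipeline, together
with the two quantitative assays that typically accompany it: relative
expression by the delta-delta-Ct method, and drug-interaction scoring by
the Chou-Talalay median-effect / combination-index framework.

## Differential expression model

Each study is a matrix of nonnegative linear-scale intensities with a
sample-to-group map. Per gene, two-group comparison uses:

* the two-sided **Mann-Whitney** (Wilcoxon rank-sum) test. The statistic
  `U` is the smaller one-sided U. The p-value is exact by enumeration for
  untied groups of at most 8, otherwise a normal approximation with tie
  correction and continuity correction. The exact path is cross-checked in
  the test suite against full enumeration of all rank assignments.
* a linear-scale **fold change**, the ratio of group means. A gene passes
  at `fc_threshold = 1.5` if the ratio is at least 1.5 or at most 1/1.5.

The default gate is `p < 0.001` with `FC >= 1.5`, applied to the raw
p-value: **no multiple-testing correction is performed**, deliberately, so
the per-study gene lists have the conventional meaning of gated
single-test calls feeding a downstream intersection (the strict
cross-study intersection is itself a powerful false-positive filter). Users
needing FDR control should apply it upstream of the set operations.

Fold change is computed on linear-scale means. A median-based or
log-scale variant would change borderline calls; one semantics is kept to
make the gate unambiguous.

## Cross-platform harmonization

Heterogeneous array platforms are reduced to a shared gene universe by an
annotation mask (probe-to-gene map, at most one symbol per probe; probes
absent from the mask are excluded by construction). Multi-probe genes are
collapsed by `max_mean` — the probe row with the highest mean intensity
across samples, the common microarray convention — with a per-sample
`median` rule as the alternative. Collapse of a single-probe gene is the
identity under both rules, and masking an already collapsed study is
rejected rather than silently repeated. Intensities are assumed
normalized upstream; the package performs no normalization.

## Meta-profiles, decomposition, maintenance, specificity

A **meta-profile** is the set of genes called with a concordant direction
across several independent studies of the same condition. The default
rule, `all_concordant`, is the strict intersection: present in every
study with one common direction. `majority_concordant` (present with a
common direction in more than half of the studies and never with the
opposite direction) is provided for sensitivity analysis; the strict
profile is always a subset of the majority profile.

"Similarly altered" is interpreted throughout as **membership plus
direction concordance** — a gene up in one comparison and down in another
is not similar, even though pure membership would count it. A
`require_direction_match = FALSE` flag relaxes this everywhere for
comparison.

`decompose_signature()` partitions a disease profile into a
reference-like component (genes also in the reference signature,
direction-concordant) and the non-reference remainder; the reference-like
share is reported as a percentage to one decimal, rounding halves away
from zero, the convention used in manuscript reporting.
`maintenance_analysis()` counts, per component, the genes still present
(direction-concordant) in a later-stage profile, producing a 2x2 table
tested by Pearson chi-square, df = 1, upper-tail p, **without** Yates
correction (counts in this design are large; the correction is available
as an option). A zero row margin leaves the statistic undefined and is
reported as missing; a zero column margin (everything maintained, or
everything lost) means observed equals expected, reported as chi-square 0.
`specificity_fraction()` asks the converse question — how much of some
other condition's profile lies inside the signature — and can test the
in/out split against a comparator split with the same chi-square.

## Clustering and separation

Sample (or gene) clustering restricted to a signature uses Pearson
correlation distance (1 − r between item profiles) with average linkage —
the long-standing convention for expression heat maps — with Euclidean /
complete linkage as options, and an optional per-gene median-centering
for cross-tissue display. Constant profiles are rejected by id because
their correlations are undefined. The qualitative claim "clustering on
this signature cannot separate the tissue types" is made quantitative by
`separation_score()`: cut the dendrogram into k clusters and report
purity, the weighted majority-label fraction. Perfectly separated classes
give purity 1; label-shuffled data sits near the majority-class baseline.
Average-linkage heights are verified in the tests against a naive O(n^3)
re-computation, and dendrograms export to Newick (branch lengths are
merge-height differences) via `ape`.

## Delta-delta-Ct

Technical replicates are averaged per (sample, gene); dCt is target minus
reference-gene mean Ct; ddCt subtracts the control group's mean dCt; the
per-sample fold change is 2^(−ddCt). Ct values above the non-detect
ceiling (default 40 cycles) are clamped to the ceiling and the sample
flagged, rather than dropped — silently dropping non-detects biases fold
changes upward; a `drop` policy is available where the flagged samples
should be excluded from group summaries. The group summary is the
arithmetic mean of per-sample fold changes (geometric mean available);
group significance uses the Mann-Whitney test on per-sample 2^(−dCt),
which is rank-equivalent to testing −dCt. No amplification-efficiency
correction is applied: the model is plain delta-delta-Ct.

## Median-effect and combination index

Dose-response points (D, fa) are fitted to the median-effect equation
fa/fu = (D/Dm)^m by least squares on the linearized form
log10(fa/fu) = m·log10(D) − m·log10(Dm). Viability readouts convert to
fa = 1 − treated/control, clipped into [1e-4, 1 − 1e-4] so the
linearization is defined; clipped points are flagged and excluded from
fits by default. A non-positive fitted slope flags the fit as
non-monotone instead of failing. The combination index for a combination
point (d1, d2) with observed combined effect fa is the two-term
(mutually-exclusive) form CI = d1/Dx1(fa) + d2/Dx2(fa); CI < 1 is
synergy, with a reporting band of ±0.1 around additivity. The
mutually-nonexclusive third term is deliberately not implemented — the
two-term form is the standard default. Isobologram coordinates are
exported for plotting; normalized combination coordinates summing below 1
fall under the additivity line.

## What the synthetic generator emulates

`generate_multistudy()` produces the whole multi-study regime with ground
truth attached: log-normal intensities (value = 2^(baseline + group
effect + Normal(0, sigma)), gene baselines drawn once at log2 mean 7,
sd 1.5), a planted directional intestinal signature shared by duodenum
and colon, BO profiles overlapping that signature, and OAC profiles in
which each intestine-like gene is retained independently with the planted
maintenance probability — retention is decided once per gene and shared
by all later-stage studies, the minimal mechanism that produces a
set-level maintenance fraction. Platforms overlap partially (planted
genes are present on every platform so that set-level estimates measure
biology, not platform coverage), and a fraction of genes carry a second,
dimmer probe to exercise the collapse rule.

The default configuration mirrors the published scale of this study
design: a 2861-gene intestinal signature; a 989-gene BO profile with 769
intestine-like and 220 BO-specific members; maintenance probability 0.85
for the intestine-like component and 45/220 for the rest; 381
OAC-specific genes (an OAC profile of about 1078 genes); three BO and
three OAC studies on a 10,000-gene universe.

Two generator defaults deserve explanation:

* **Group size is 9 samples, not 3.** The smallest exact two-sided
  Mann-Whitney p attainable with 3 samples per group is 2/20 = 0.1, so a
  p < 0.001 gate can never fire at n = 3 — with triplicate groups the
  printed gate and the printed group size are mathematically
  incompatible, whichever the original analysis software actually did.
  The generator therefore uses n = 9 per group (well inside the 3-17
  range typical of these cohorts), the smallest round size at which the
  gate is comfortably attainable (minimum attainable p ≈ 4e-4).
* **Planted effects are 2-4 log2 units (4- to 16-fold).** With n = 9 and
  log2 noise 0.5, a 2 log2 effect is detected at the gate with
  near-certainty, so the estimated maintenance fraction measures the
  planted Bernoulli retention rather than per-study detection failure. A
  simple power argument drives this: at effect 1.5 log2 the per-study
  detection probability drops to roughly 0.85, and requiring concordant
  detection in three studies would deflate the maintenance estimate by a
  few percent purely through missed detections. Real signatures of this
  kind are dominated by large fold changes, so the stronger effects are
  also the realistic choice.

What the generator does **not** emulate: probe-level hybridization
physics, batch and spatial artifacts, correlated gene-gene noise, and
partial (per-study) retention of a gene's effect. Passing tests therefore
demonstrate correctness of the inference machinery under a clean
log-normal model, not robustness to real-world artifacts.

The qPCR generator draws Ct = base + shift(group) + Normal(0, 0.3) per
technical replicate (three replicates, GAPDH reference at 18 cycles,
17-vs-17 cohorts, a −3-cycle target shift by default). The dose-response
generator draws single-agent curves from the median-effect equation with
Gaussian noise (sd 0.05) on log10(fa/fu), and combination effects under
Loewe additivity with the required doses scaled by an interaction factor
s (default 0.67, a clearly synergistic regime): a noiseless analysis
recovers CI = s exactly at every combination point, which is what makes
the generator a calibration standard for the CI pipeline.

## Numerical choices and degenerate inputs

* Identical multisets in the rank test return p = 1 directly (the
  normal approximation is 0/0 there).
* Zero pooled variance in the t-test: p = 1 for equal means, 0
  otherwise — a documented convention for degenerate viability data.
* A fold-change ratio of exactly 1 is labelled "up" but can never pass
  the gate, so the label is inert.
* Chi-square margins: zero row margin → statistic undefined (reported
  missing); zero column margin → 0 (observed equals expected).
* Percentages are rounded half-away-from-zero to one decimal at the
  reporting boundary only; all internal arithmetic is unrounded.
* Merge ties in `hclust` are resolved deterministically by input order;
  clustering output is therefore reproducible for a fixed input.

## Problem sizes used by the tests

The test suite exercises the full default configuration once (10,000
genes, seven studies; about two minutes) and otherwise scales the
generators down (hundreds of genes, 2 studies per stage) so that each
property is checked in seconds. The rank-test exactness check enumerates
all 2319 rank configurations with up to 6 samples per group; chi-square
agreement uses 1000 random tables; CI calibration uses 100 seeded
replicates at noise 0.05. These sizes were chosen as the smallest at
which the statistical assertions have negligible false-alarm probability.

## Known limitations

* The pipeline treats vendor-normalized intensities as given; no
  background correction, normalization, or batch adjustment is offered.
* Gene identity is by case-sensitive symbol string; no alias resolution.
* The strict meta-profile rule is sensitive to a single discordant
  study; the majority rule trades that for weaker guarantees.
* The specificity statistic compares in/out splits between two profiles;
  it does not model gene-level dependence between profiles.
* The CI machinery implements the two-term mutually-exclusive form only,
  and no dose-reduction-index reporting.
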