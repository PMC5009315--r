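# intsig

Cross-study intestinal meta-signature analysis for Barrett's oesophagus
(BO) and oesophageal adenocarcinoma (OAC).

Barrett's oesophagus is an intestinal-type metaplasia of the lower
oesophagus and the main precursor of oesophageal adenocarcinoma. A
central question about these lesions is how much of their transcriptome
is genuinely "intestine-like", and whether that intestinal character
survives the transition to cancer. `intsig` answers it with a set-based
pipeline for transcriptomics researchers:

1. **Reference signature** — genes concordantly altered in normal
   duodenum and colon versus normal oesophageal squamous tissue
   (two-sided Mann-Whitney test, p < 0.001, fold change ≥ 1.5 or
   ≤ 1/1.5 on linear-scale group means).
2. **Meta-profiles** — genes called with a concordant direction across
   several independent studies of the same condition (strict
   intersection by default), after reducing heterogeneous platforms to
   one gene universe through a probe-to-gene annotation mask.
3. **Decomposition and maintenance** — the disease profile is split into
   an intestine-like component (genes in the reference signature with
   the same direction) and the non-intestinal rest; persistence of each
   component in the later-stage profile forms a 2×2 table tested by
   Pearson chi-square (df = 1, no continuity correction):
   χ² = N(ad − bc)² / (r₁r₂c₁c₂).
4. **Clustering** — hierarchical clustering (Pearson correlation
   distance 1 − r, average linkage) restricted to a signature, with a
   cluster-purity separation score and Newick / ordered-matrix export.
5. **ΔΔCt** — qPCR relative quantification: ΔCt = Ct(target) − Ct(ref),
   ΔΔCt = ΔCt − mean ΔCt(control), FC = 2^(−ΔΔCt), with
   technical-replicate averaging and a Ct > 40 non-detect convention.
6. **Chou-Talalay synergy** — median-effect fits fa/fu = (D/Dm)^m and
   the non-constant-ratio combination index
   CI = d₁/Dx₁ + d₂/Dx₂ (CI < 1 synergy), with isobologram coordinates.

A seeded synthetic-data module generates every input the pipeline
consumes — multi-study expression matrices with planted directional
signatures and a configurable maintenance fraction, Ct tables, and
Loewe-constructed dose-response curves with a known interaction factor —
so every stage can be validated against ground truth.

## Worked example

Generate a small two-study-per-stage data set with a planted maintenance
fraction of 0.85, derive the signature, and measure maintenance:

```r
library(intsig)
sim <- generate_multistudy(multistudy_config(
  n_genes = 1000, signature_size = 300, bo_like = 120, bo_specific = 40,
  oac_specific = 30, n_bo_studies = 2, n_oac_studies = 2), seed = 7)
gl <- function(id) apply_annotation_mask(sim$studies[[id]], sim$mask)

tissue <- gl("TISSUE")
signature <- derive_reference_signature(
  differential_genes(tissue, "DUO", "OES"),
  differential_genes(tissue, "COL", "OES"))
signature
#> <gene_set> 299 genes (151 up, 148 down)

early <- build_meta_profile(list(
  differential_genes(gl("BO1"), "BO", "SQ"),
  differential_genes(gl("BO2"), "BO", "SQ")))
late <- build_meta_profile(list(
  differential_genes(gl("OAC1"), "OAC", "SQ"),
  differential_genes(gl("OAC2"), "OAC", "SQ")))
early
#> <meta_profile> 160 genes across 2 studies (all_concordant)

dec <- decompose_signature(early, signature)
dec
#> <signature_decomposition> 119/160 reference-like (74.4%), 41 non-reference

maintenance_analysis(dec, late)
#> <maintenance_result>
#>                maintained lost
#> reference_like         99   20
#> non_reference          10   31
#>   maintained: reference-like 83.2%, non-reference 24.4%
#>   chi2 = 48.56, p = 3.21e-12
```

Of the 160-gene early-stage profile, 119 genes (74.4%) are
intestine-like; 83.2% of that component persists in the later-stage
profile versus 24.4% of the non-intestinal component — the estimate
matches this draw's realized Bernoulli retention (0.833 of a planted
0.85) — and the 2×2 association is overwhelming (χ² = 48.6,
p ≈ 3×10⁻¹²).

The same analysis at full scale, plus clustering, ΔΔCt and
combination-index stages, is scripted as a numbered workflow under
`analysis/` (run from the repository root in order:
`Rscript analysis/01_simulate.R`, … `06_synergy_ci.R`); each stage
writes its tables under `results/`.

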