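#!/usr/bin/env Rscript
# Stage 2: derive the intestine-enriched reference signature.
#
# Collapses the three-tissue study through the annotation mask, runs
# Mann-Whitney / fold-change differential expression for duodenum and
# colon against normal oesophagus (FC >= 1.5, p < 0.001), and keeps
# the genes altered concordantly in both intestinal tissues.

library(intsig)

res <- run_signature(list(
  tissue = list(matrix = "results/simulated/TISSUE_matrix.tsv",
                groups = "results/simulated/TISSUE_groups.tsv"),
  mask = "results/simulated/mask.tsv",
  out_dir = "results/signature"))

for (cmp in res$summary$comparisons) {
  cat(sprintf("%s vs %s: %d differential genes\n",
              cmp$test, cmp$ref, cmp$n_genes))
}
cat(sprintf("concordant intestinal signature: %d genes\n",
            res$summary$signature_size))

truth <- read_gene_list("results/simulated/truth_signature.tsv")
overlap <- sum(res$signature$entries$gene %in% truth$entries$gene)
cat(sprintf("overlap with planted truth: %d / %d\n",
            overlap, n_genes(truth)))
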