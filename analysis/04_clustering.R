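#!/usr/bin/env Rscript
# Stage 4: hierarchical clustering on the intestine-like signature.
#
# Restricts one OAC study to the intestine-like component of the BO
# profile, clusters samples by Pearson correlation distance with
# average linkage, scores how well the two-cluster cut separates the
# tumour and squamous groups, and exports the dendrogram (Newick) and
# the leaf-ordered matrix for heat-map display.

library(intsig)

mask <- read_annotation_mask("results/simulated/mask.tsv")
study <- read_expression_matrix("results/simulated/OAC1_matrix.tsv",
                                "results/simulated/OAC1_groups.tsv",
                                study_id = "OAC1")
study <- apply_annotation_mask(study, mask)

reference <- read_gene_list("results/signature/reference_signature.tsv")
bo_profile <- read_gene_list("results/meta/early_meta_profile.tsv")
intestine_like <- decompose_signature(bo_profile,
                                      reference)$reference_like

dir.create("results/clustering", showWarnings = FALSE, recursive = TRUE)
dend_samples <- hierarchical_cluster(study, intestine_like,
                                     axis = "samples")
dend_genes <- hierarchical_cluster(study, intestine_like, axis = "genes")

score <- separation_score(dend_samples, sample_groups(study), k = 2)
cat(sprintf("clustered %d samples on %d intestine-like genes\n",
            length(dend_samples$labels), length(dend_genes$labels)))
cat(sprintf("two-cluster purity against tumour/squamous labels: %.3f\n",
            score$purity))

export_newick(dend_samples, "results/clustering/samples.nwk")
sub <- study
sub$values <- sub$values[dend_genes$labels, , drop = FALSE]
export_ordered_matrix(sub, dend_rows = dend_genes,
                      dend_cols = dend_samples,
                      path = "results/clustering/ordered_matrix.tsv")
cat("wrote results/clustering/{samples.nwk,ordered_matrix.tsv}\n")
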