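#!/usr/bin/env Rscript
# Stage 3: disease meta-profiles, decomposition and maintenance.
#
# Builds the strict-concordance BO and OAC meta-profiles from the
# per-study differential calls, decomposes the BO profile into its
# intestine-like and non-intestinal components against the reference
# signature, and quantifies how much of each component persists in the
# OAC meta-profile (2x2 chi-square association).

library(intsig)

paths <- function(ids) {
  out <- lapply(ids, function(id)
    list(matrix = sprintf("results/simulated/%s_matrix.tsv", id),
         groups = sprintf("results/simulated/%s_groups.tsv", id)))
  names(out) <- ids
  out
}

res <- run_meta(list(
  reference = "results/signature/reference_signature.tsv",
  mask = "results/simulated/mask.tsv",
  early_studies = paths(paste0("BO", 1:3)),
  late_studies = paths(paste0("OAC", 1:3)),
  out_dir = "results/meta"))

cat(sprintf("BO meta-profile: %d genes; OAC meta-profile: %d genes\n",
            res$summary$early_profile_size,
            res$summary$late_profile_size))
cat(sprintf("intestine-like component: %d genes (%.1f%% of BO profile)\n",
            res$summary$decomposition$n_reference_like,
            res$summary$decomposition$fraction_reference_like))
print(res$maintenance)
est <- res$maintenance$table["reference_like", "maintained"] /
  sum(res$maintenance$table["reference_like", ])
cat(sprintf("estimated maintenance of the intestine-like component: %.3f\n",
            est))
cat(sprintf("maintained component as %% of OAC profile: %.1f\n",
            res$summary$late_stage_fraction_in_signature))
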