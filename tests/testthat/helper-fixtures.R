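# Small fixtures built in code.

# gene-level study from a matrix of intensities
make_study <- function(values, groups, study_id = "S1",
                       gene_level = TRUE) {
  expression_study(values, groups, study_id = study_id,
                   is_gene_level = gene_level)
}

# a two-group gene-level study with n samples per group where `up` /
# `down` genes carry a clean log2 effect and the rest are null
planted_two_group_study <- function(n_genes = 20, n = 9, up = 1:3,
                                    down = 4:5, effect = 2, sigma = 0,
                                    seed = 42, study_id = "S1",
                                    groups = c("CTRL", "TEST")) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  samples <- c(sprintf("c%02d", 1:n), sprintf("t%02d", 1:n))
  grp <- setNames(rep(groups, each = n), samples)
  base <- rnorm(n_genes, 8, 1)
  eff <- numeric(n_genes)
  eff[up] <- effect
  eff[down] <- -effect
  log2v <- outer(base, numeric(2 * n), `+`) +
    outer(eff, as.numeric(grp == groups[2])) +
    matrix(rnorm(n_genes * 2 * n, 0, sigma), n_genes)
  vals <- 2^log2v
  dimnames(vals) <- list(genes, samples)
  make_study(vals, grp, study_id = study_id)
}

# directional gene sets of prescribed sizes and overlap structure,
# used to replay printed set counts through the set operations
sets_with_counts <- function(n_disease, n_like, reference_extra = 0) {
  disease_genes <- sprintf("D%04d", seq_len(n_disease))
  dirs <- rep(c("up", "down"), length.out = n_disease)
  like <- disease_genes[seq_len(n_like)]
  ref_genes <- c(like, sprintf("R%04d", seq_len(reference_extra)))
  ref_dirs <- c(dirs[seq_len(n_like)],
                rep(c("up", "down"), length.out = reference_extra))
  list(disease = gene_set(disease_genes, dirs),
       reference = gene_set(ref_genes, ref_dirs))
}
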