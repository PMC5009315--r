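# a gene-level study with two sample classes separated by disjoint
# directional blocks of genes
two_class_study <- function(n_genes = 40, n = 5, effect = 3,
                            sigma = 0.2, seed = 2) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  samples <- c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n))
  grp <- setNames(rep(c("A", "B"), each = n), samples)
  base <- rnorm(n_genes, 8, 0.5)
  eff <- rep(c(effect, -effect), length.out = n_genes)
  log2v <- outer(base, numeric(2 * n), `+`) +
    outer(eff, as.numeric(grp == "B")) +
    matrix(rnorm(n_genes * 2 * n, 0, sigma), n_genes)
  vals <- 2^log2v
  dimnames(vals) <- list(genes, samples)
  expression_study(vals, grp, study_id = "CL", is_gene_level = TRUE)
}

test_that("correlation distance puts identical and opposite profiles at 0 and 2", {
  vals <- cbind(s1 = c(1, 2, 3, 4), s2 = c(2, 4, 6, 8),
                s3 = c(4, 3, 2, 1), s4 = c(9, 9, 1, 1))
  rownames(vals) <- sprintf("G%d", 1:4)
  st <- expression_study(vals, setNames(rep("X", 4), colnames(vals)),
                         is_gene_level = TRUE)
  dend <- hierarchical_cluster(st, axis = "samples")
  hc <- dend$hclust
  # s1 and s2 are perfectly correlated: first merge at height 0
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  first <- sort(dend$labels[-hc$merge[1, ]])
  expect_equal(first, c("s1", "s2"))
  # s3 is the exact reversal of s1: their correlation distance is 2
  d <- 1 - cor(vals)
  expect_equal(d["s1", "s3"], 2, tolerance = 1e-12)
})

test_that("average-linkage heights match the naive O(n^3) oracle", {
  set.seed(13)
  vals <- matrix(2^rnorm(8 * 12, 8, 1), nrow = 12,
                 dimnames = list(sprintf("G%02d", 1:12),
                                 sprintf("s%d", 1:8)))
  st <- expression_study(vals, setNames(rep("X", 8), colnames(vals)),
                         is_gene_level = TRUE)
  for (metric in c("correlation", "euclidean")) {
    dend <- hierarchical_cluster(st, metric = metric)
    d <- if (metric == "correlation") as.dist(1 - cor(vals))
         else dist(t(vals))
    expect_equal(sort(dend$hclust$height),
                 naive_average_linkage_heights(d), tolerance = 1e-12)
  }
})

test_that("constant profiles are rejected by id under correlation distance", {
  vals <- cbind(s1 = c(1, 2, 3), s2 = c(5, 5, 5), s3 = c(2, 1, 7))
  rownames(vals) <- sprintf("G%d", 1:3)
  st <- expression_study(vals, setNames(rep("X", 3), colnames(vals)),
                         is_gene_level = TRUE)
  expect_error(hierarchical_cluster(st), "s2")
})

test_that("clustering is invariant to positive affine per-item transforms", {
  st <- two_class_study(seed = 41)
  dend <- hierarchical_cluster(st)
  vals2 <- sweep(sweep(st$values, 2, runif(ncol(st$values), 1, 4), `*`),
                 2, runif(ncol(st$values), 0, 5), `+`)
  st2 <- expression_study(vals2, sample_groups(st), is_gene_level = TRUE)
  dend2 <- hierarchical_cluster(st2)
  expect_equal(dend2$hclust$height, dend$hclust$height,
               tolerance = 1e-12)
  expect_equal(dend2$hclust$merge, dend$hclust$merge)
})

test_that("separation purity is 1 on well-separated classes", {
  st <- two_class_study()
  dend <- hierarchical_cluster(st)
  sc <- separation_score(dend, sample_groups(st), k = 2)
  expect_equal(sc$purity, 1)
  # singleton clusters are trivially pure
  expect_equal(separation_score(dend, sample_groups(st),
                                k = length(dend$labels))$purity, 1)
  expect_error(separation_score(dend, sample_groups(st), k = 99),
               "exceeds")
})

test_that("shuffled labels score near the majority-class baseline", {
  st <- two_class_study(sigma = 0.2, seed = 8)
  dend <- hierarchical_cluster(st)
  set.seed(99)
  purities <- replicate(200, {
    labs <- setNames(sample(sample_groups(st)), names(sample_groups(st)))
    separation_score(dend, labs, k = 2)$purity
  })
  # baseline for balanced classes is 0.5; permuted purity should sit
  # near it, far below the perfect separation of the true labels
  expect_lt(mean(purities), 0.75)
  expect_gte(min(purities), 0.5)
})

test_that("gene-axis clustering and signature restriction work", {
  st <- two_class_study()
  sub <- gene_set(rownames(st$values)[1:10], rep("up", 10))
  dend <- hierarchical_cluster(st, gene_subset = sub, axis = "genes")
  expect_equal(sort(dend$labels), sort(sub$entries$gene))
  expect_error(hierarchical_cluster(st, gene_subset = gene_set("ZZ", "up")),
               "intersect")
})

test_that("newick export and ordered-matrix export are faithful", {
  st <- two_class_study()
  dc <- hierarchical_cluster(st, axis = "samples")
  dr <- hierarchical_cluster(st, axis = "genes")
  nwk <- export_newick(dc)
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), sort(colnames(st$values)))
  expect_equal(length(tree$tip.label), ncol(st$values))

  path <- withr::local_tempfile(fileext = ".tsv")
  export_ordered_matrix(st, dend_rows = dr, dend_cols = dc, path = path)
  gm_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(names(sample_groups(st)), sample_groups(st),
                   sep = "\t"), gm_path)
  re <- read_expression_matrix(path, gm_path)
  expect_setequal(rownames(re$values), rownames(st$values))
  expect_setequal(colnames(re$values), colnames(st$values))
  expect_equal(re$values[rownames(st$values), colnames(st$values)],
               st$values, tolerance = 1e-12)

  # no reordering writes an identical file body
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  export_ordered_matrix(st, path = p1)
  write_expression_matrix(st, p2)
  expect_identical(readLines(p1), readLines(p2))

  st_bad <- two_class_study(n_genes = 10, seed = 77)
  expect_error(export_ordered_matrix(st, dend_rows =
    hierarchical_cluster(st_bad, axis = "genes"), path = p1),
    "do not match")
})
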