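#' Hierarchical clustering of a signature-restricted expression matrix
#'
#' Clusters samples (or genes) of a study restricted to a gene subset,
#' with Pearson correlation distance (1 - r between item profiles) and
#' average linkage by default — the conventional choices for expression
#' heat maps. Euclidean distance and complete linkage are available.
#' Items with constant profiles are rejected by id, since their
#' correlations are undefined.
#'
#' @param study a gene-level `expression_study`.
#' @param gene_subset optional `gene_set` (or character vector of
#'   symbols) restricting the features used; its intersection with the
#'   study features must be non-empty.
#' @param axis cluster `"samples"` (default) or `"genes"`.
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @param center_rows subtract the per-gene median before clustering
#'   (a display convention for cross-tissue panels).
#' @return object of class `signature_dendrogram`: list with the
#'   underlying `hclust` object, `labels` in input order, `leaf_order`,
#'   and the parameters used.
#' @export
hierarchical_cluster <- function(study, gene_subset = NULL,
                                 axis = c("samples", "genes"),
                                 metric = c("correlation", "euclidean"),
                                 linkage = c("average", "complete"),
                                 center_rows = FALSE) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  vals <- study$values
  if (!is.null(gene_subset)) {
    genes <- if (is.character(gene_subset)) gene_subset
             else as_gene_set(gene_subset)$entries$gene
    genes <- intersect(rownames(vals), genes)
    if (!length(genes)) {
      stop("gene subset does not intersect study features", call. = FALSE)
    }
    vals <- vals[genes, , drop = FALSE]
  }
  if (center_rows) vals <- vals - apply(vals, 1L, stats::median)
  m <- if (axis == "samples") t(vals) else vals  # items in rows
  if (nrow(m) < 2) stop("need at least 2 items to cluster", call. = FALSE)
  if (ncol(m) < 2) stop("need at least 2 features per item", call. = FALSE)
  if (metric == "correlation") {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0)) {
      stop("constant profile (zero variance): ",
           paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
    }
    d <- stats::as.dist(1 - stats::cor(t(m)))
  } else {
    d <- stats::dist(m, method = "euclidean")
  }
  hc <- stats::hclust(d, method = linkage)
  structure(
    list(hclust = hc, labels = rownames(m), leaf_order = hc$order,
         axis = axis, metric = metric, linkage = linkage),
    class = "signature_dendrogram"
  )
}

#' @export
print.signature_dendrogram <- function(x, ...) {
  cat(sprintf("<signature_dendrogram> %d %s, %s distance, %s linkage\n",
              length(x$labels), x$axis, x$metric, x$linkage))
  invisible(x)
}

#' Label-separation purity of a dendrogram cut
#'
#' Cuts the tree into `k` clusters (at the k-1 highest merges) and
#' scores how well the clusters separate known class labels: purity is
#' the total count of majority-label items per cluster divided by the
#' number of items. Purity 1 means each cluster is single-class;
#' values near the majority-class frequency mean the clustering carries
#' no label information.
#'
#' @param dend a `signature_dendrogram`.
#' @param labels named vector mapping every leaf to a class label.
#' @param k number of clusters (default 2); must not exceed leaf count.
#' @return list with `k`, `purity`, and the cluster `assignments`.
#' @export
separation_score <- function(dend, labels, k = 2) {
  leaves <- dend$labels
  if (k > length(leaves)) stop("k exceeds leaf count", call. = FALSE)
  missing <- setdiff(leaves, names(labels))
  if (length(missing)) {
    stop("unlabelled leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cl <- stats::cutree(dend$hclust, k = k)
  lab <- as.character(labels[leaves])
  majority <- vapply(split(lab, cl[leaves]),
                     function(v) max(table(v)), numeric(1))
  list(k = k, purity = sum(majority) / length(leaves),
       assignments = cl[leaves])
}

#' Export a matrix reordered by dendrogram leaf orders
#'
#' Writes the study matrix as TSV with rows and/or columns permuted to
#' the dendrogram leaf orders — the substrate for a heat-map display.
#' Leaves must match the corresponding matrix axis exactly.
#'
#' @param study an `expression_study`.
#' @param dend_rows optional `signature_dendrogram` over genes.
#' @param dend_cols optional `signature_dendrogram` over samples.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_ordered_matrix <- function(study, dend_rows = NULL, dend_cols = NULL,
                                  path) {
  vals <- study$values
  if (!is.null(dend_rows)) {
    if (!setequal(dend_rows$labels, rownames(vals))) {
      stop("row dendrogram leaves do not match matrix rows", call. = FALSE)
    }
    vals <- vals[dend_rows$labels[dend_rows$leaf_order], , drop = FALSE]
  }
  if (!is.null(dend_cols)) {
    if (!setequal(dend_cols$labels, colnames(vals))) {
      stop("column dendrogram leaves do not match matrix columns",
           call. = FALSE)
    }
    vals <- vals[, dend_cols$labels[dend_cols$leaf_order], drop = FALSE]
  }
  out <- expression_study(vals, sample_groups(study),
                          study_id = study$study_id,
                          platform_id = study$platform_id,
                          is_gene_level = study$is_gene_level)
  write_expression_matrix(out, path)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are height differences between successive merges.
#' @param dend a `signature_dendrogram`.
#' @param path output path, or `NULL` to only return the string.
#' @return the Newick string, invisibly when writing.
#' @export
export_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  str <- ape::write.tree(phy)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    writeLines(str, con, sep = "\n")
    close(con)
    return(invisible(str))
  }
  str
}
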