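#' Two-group Mann-Whitney test
#'
#' Returns the two-sided Mann-Whitney (Wilcoxon rank-sum) statistic and
#' p-value. `U` is the smaller of the two one-sided U statistics. The
#' p-value is exact by enumeration when both groups have at most 8
#' observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Identical multisets give p = 1.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with elements `U` and `p`.
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (any(!is.finite(c(x, y)))) stop("non-finite values", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = u, p = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && n1 <= 8 && n2 <= 8
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
  list(U = unname(u), p = min(unname(p), 1))
}

#' Linear-scale fold change between two groups
#'
#' Fold change is the ratio of group means on the linear intensity
#' scale (test over reference). Direction is `"up"` when the ratio
#' exceeds 1 and `"down"` when below; a ratio of exactly 1 is labelled
#' `"up"` (it can never pass a fold-change gate, so the label is inert).
#'
#' @param x test-group values.
#' @param y_reference reference-group values; their mean must be > 0.
#' @return list with `fold_change` and `direction`.
#' @export
fold_change <- function(x, y_reference) {
  mref <- mean(y_reference)
  if (!is.finite(mref) || mref <= 0) {
    stop("reference mean must be positive", call. = FALSE)
  }
  fc <- mean(x) / mref
  list(fold_change = fc, direction = if (fc < 1) "down" else "up")
}

#' Per-gene differential expression with fold-change and p gates
#'
#' Applies [mann_whitney_test()] and [fold_change()] to every gene of a
#' gene-level study and keeps genes passing both gates: p below
#' `p_threshold` and fold change at least `fc_threshold` or at most
#' `1/fc_threshold` (the two-sided ratio gate). No multiple-testing
#' correction is applied: the gate is on the raw p-value throughout.
#'
#' @param study gene-level `expression_study`.
#' @param test_group,ref_group group labels, each with >= 2 samples.
#' @param fc_threshold fold-change gate (default 1.5).
#' @param p_threshold p-value gate (default 0.001).
#' @return a `gene_set` of the passing genes with per-gene provenance
#'   (`study_id`, `fold_change`, `p`); the full per-gene table (columns
#'   `gene`, `fold_change`, `direction`, `U`, `p`) is attached as
#'   attribute `"de_table"`.
#' @export
differential_genes <- function(study, test_group, ref_group,
                               fc_threshold = 1.5, p_threshold = 0.001) {
  if (!study$is_gene_level) {
    stop("study must be gene-level (apply the annotation mask first)",
         call. = FALSE)
  }
  grp <- sample_groups(study)
  for (g in c(test_group, ref_group)) {
    if (sum(grp == g) < 2) {
      stop("group '", g, "' missing or has fewer than 2 samples",
           call. = FALSE)
    }
  }
  xm <- study$values[, grp == test_group, drop = FALSE]
  ym <- study$values[, grp == ref_group, drop = FALSE]
  genes <- rownames(study$values)
  n <- length(genes)
  fc <- numeric(n); dir <- character(n); U <- numeric(n); p <- numeric(n)
  for (i in seq_len(n)) {
    f <- fold_change(xm[i, ], ym[i, ])
    mw <- mann_whitney_test(xm[i, ], ym[i, ])
    fc[i] <- f$fold_change; dir[i] <- f$direction
    U[i] <- mw$U; p[i] <- mw$p
  }
  tab <- data.frame(gene = genes, fold_change = fc, direction = dir,
                    U = U, p = p, stringsAsFactors = FALSE)
  keep <- tab$p < p_threshold &
    (tab$fold_change >= fc_threshold | tab$fold_change <= 1 / fc_threshold)
  hits <- tab[keep, , drop = FALSE]
  gs <- gene_set(hits$gene, hits$direction,
                 provenance = data.frame(gene = hits$gene,
                                         study_id = rep(
                                           sprintf("%s:%s_vs_%s",
                                                   study$study_id,
                                                   test_group, ref_group),
                                           nrow(hits)),
                                         fold_change = hits$fold_change,
                                         p = hits$p,
                                         stringsAsFactors = FALSE))
  attr(gs, "de_table") <- tab
  gs
}

#' Write a differential-expression table as TSV
#'
#' Columns `gene`, `fold_change`, `direction`, `U`, `p` in that order.
#' @param x a `gene_set` returned by [differential_genes()] (its
#'   included genes are written) or a data.frame with those columns.
#' @param path output path.
#' @param full if `TRUE` and `x` carries a `"de_table"` attribute, write
#'   the full per-gene table rather than only the passing genes.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(x, path, full = FALSE) {
  if (inherits(x, "gene_set")) {
    tab <- attr(x, "de_table")
    if (is.null(tab)) stop("gene_set carries no DE table", call. = FALSE)
    if (!full) tab <- tab[tab$gene %in% x$entries$gene, , drop = FALSE]
  } else {
    tab <- x
  }
  tab <- tab[, c("gene", "fold_change", "direction", "U", "p")]
  con <- file(path, open = "wb")
  writeLines(c(paste(names(tab), collapse = "\t"),
               do.call(paste, c(lapply(tab, as.character), sep = "\t"))),
             con, sep = "\n")
  close(con)
  invisible(path)
}

#' Two-sample Student t-test (equal variance)
#'
#' Two-sided unpaired t-test p-value for viability-style data. By
#' convention, zero pooled variance with equal means gives p = 1 and
#' zero pooled variance with unequal means gives p = 0.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return the two-sided p-value.
#' @export
student_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = TRUE)$p.value
}
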