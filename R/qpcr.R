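#' qPCR cycle-threshold tables
#'
#' A Ct table holds per-well cycle-threshold records with technical
#' replicates: one row per (sample, gene, replicate). Ct values above
#' the non-detect ceiling (default 40 cycles) represent wells where the
#' transcript was not detected.
#'
#' @param records data.frame with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `Ct`.
#' @param non_detect_ceiling cycles above which a well counts as
#'   non-detect (default 40).
#' @return object of class `ct_table`.
#' @export
ct_table <- function(records, non_detect_ceiling = 40) {
  need <- c("sample_id", "group", "gene", "replicate", "Ct")
  if (!all(need %in% names(records))) {
    stop("Ct records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records$Ct <- as.numeric(records$Ct)
  if (any(!is.finite(records$Ct)) || any(records$Ct <= 0)) {
    stop("Ct values must be positive and finite", call. = FALSE)
  }
  key <- paste(records$sample_id, records$gene, records$replicate)
  if (anyDuplicated(key)) {
    stop("replicate indices must be unique per (sample, gene)",
         call. = FALSE)
  }
  grp_per_sample <- tapply(records$group, records$sample_id,
                           function(g) length(unique(g)))
  if (any(grp_per_sample > 1)) {
    stop("sample(s) with conflicting group labels: ",
         paste(names(grp_per_sample)[grp_per_sample > 1], collapse = ", "),
         call. = FALSE)
  }
  structure(list(records = as.data.frame(records),
                 non_detect_ceiling = non_detect_ceiling),
            class = "ct_table")
}

#' Read a Ct table from TSV
#'
#' Expects a header `sample_id  group  gene  replicate  Ct`.
#' @param path file path.
#' @param non_detect_ceiling passed to [ct_table()].
#' @return a `ct_table`.
#' @export
read_ct_table <- function(path, non_detect_ceiling = 40) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  ct_table(tab, non_detect_ceiling = non_detect_ceiling)
}

#' Write a Ct table as TSV
#' @param table a `ct_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(table, path) {
  r <- table$records
  con <- file(path, open = "wb")
  writeLines(c("sample_id\tgroup\tgene\treplicate\tCt",
               paste(r$sample_id, r$group, r$gene, r$replicate, r$Ct,
                     sep = "\t")),
             con, sep = "\n")
  close(con)
  invisible(path)
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each sample, the technical replicates of each gene are averaged;
#' dCt = mean Ct(target) - mean Ct(reference gene); ddCt subtracts the
#' control group's mean dCt; the per-sample fold change is 2^(-ddCt).
#' Wells with Ct above the non-detect ceiling are clamped to the ceiling
#' and the sample flagged `non_detect` (with `non_detect = "drop"`
#' flagged samples are excluded from the group summary instead).
#'
#' @param table a `ct_table`.
#' @param target_gene gene of interest.
#' @param reference_gene housekeeping denominator (e.g. GAPDH); must be
#'   measured in every sample.
#' @param control_group group whose mean dCt anchors the comparison.
#' @param non_detect `"clamp"` (default) or `"drop"`.
#' @param summary group fold-change aggregation: `"arithmetic"` mean of
#'   per-sample fold changes (default) or `"geometric"`.
#' @return object of class `ddct_result`: `samples` data.frame
#'   (`sample_id`, `group`, `delta_ct`, `ddct`, `fold_change`,
#'   `non_detect`) and `groups` data.frame (`group`, `fold_change`).
#' @export
delta_delta_ct <- function(table, target_gene, reference_gene,
                           control_group,
                           non_detect = c("clamp", "drop"),
                           summary = c("arithmetic", "geometric")) {
  non_detect <- match.arg(non_detect)
  summary <- match.arg(summary)
  tgt <- clamped_means(table, target_gene)
  ref <- clamped_means(table, reference_gene)
  if (!nrow(tgt)) stop("target gene not measured: ", target_gene,
                       call. = FALSE)
  miss <- setdiff(tgt$sample_id, ref$sample_id)
  if (length(miss)) {
    stop("reference gene missing for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- match(tgt$sample_id, ref$sample_id)
  d <- data.frame(sample_id = tgt$sample_id, group = tgt$group,
                  delta_ct = tgt$ct_bar - ref$ct_bar[idx],
                  non_detect = tgt$non_detect | ref$non_detect[idx],
                  stringsAsFactors = FALSE)
  if (!control_group %in% d$group) {
    stop("control group not present: ", control_group, call. = FALSE)
  }
  anchor <- mean(d$delta_ct[d$group == control_group])
  d$ddct <- d$delta_ct - anchor
  d$fold_change <- 2^(-d$ddct)
  d <- d[, c("sample_id", "group", "delta_ct", "ddct", "fold_change",
             "non_detect")]
  use <- if (non_detect == "drop") !d$non_detect else rep(TRUE, nrow(d))
  agg <- vapply(split(d$fold_change[use], d$group[use]), function(v) {
    if (!length(v)) return(NA_real_)
    if (summary == "arithmetic") mean(v) else exp(mean(log(v)))
  }, numeric(1))
  structure(
    list(samples = d,
         groups = data.frame(group = names(agg),
                             fold_change = unname(agg),
                             stringsAsFactors = FALSE),
         target_gene = target_gene, reference_gene = reference_gene,
         control_group = control_group),
    class = "ddct_result"
  )
}

# replicate-averaged, ceiling-clamped Ct per sample for one gene
clamped_means <- function(table, gene) {
  r <- table$records[table$records$gene == gene, , drop = FALSE]
  if (!nrow(r)) {
    return(data.frame(sample_id = character(), group = character(),
                      ct_bar = numeric(), non_detect = logical()))
  }
  nd <- r$Ct > table$non_detect_ceiling
  ct <- ifelse(nd, table$non_detect_ceiling, r$Ct)
  out <- do.call(rbind, lapply(split(seq_len(nrow(r)), r$sample_id),
                               function(i) {
    data.frame(sample_id = r$sample_id[i[1]], group = r$group[i[1]],
               ct_bar = mean(ct[i]), non_detect = any(nd[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result> %s relative to %s, control = %s\n",
              x$target_gene, x$reference_gene, x$control_group))
  print(x$groups)
  invisible(x)
}

#' Mann-Whitney test on qPCR relative quantities between two groups
#'
#' Per-sample relative quantities 2^(-dCt) (target minus reference mean
#' Ct) are compared between the groups with the two-sided Mann-Whitney
#' test. Since the test is rank-based, testing 2^(-dCt) is equivalent
#' to testing -dCt.
#'
#' @param table a `ct_table`.
#' @param target_gene,reference_gene genes as in [delta_delta_ct()].
#' @param group_a,group_b group labels, each with >= 2 samples.
#' @return the two-sided p-value.
#' @export
expression_group_test <- function(table, target_gene, reference_gene,
                                  group_a, group_b) {
  tgt <- clamped_means(table, target_gene)
  ref <- clamped_means(table, reference_gene)
  miss <- setdiff(tgt$sample_id, ref$sample_id)
  if (length(miss)) {
    stop("reference gene missing for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- match(tgt$sample_id, ref$sample_id)
  rq <- 2^(-(tgt$ct_bar - ref$ct_bar[idx]))
  a <- rq[tgt$group == group_a]
  b <- rq[tgt$group == group_b]
  mann_whitney_test(a, b)$p
}

#' Write delta-delta-Ct results
#'
#' Per-sample TSV (`sample_id`, `group`, `fold_change`, `non_detect`)
#' plus an optional JSON summary with group fold changes and a group
#' test p-value.
#' @param result a `ddct_result`.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @param p optional p-value to include in the summary.
#' @return invisibly, the summary list.
#' @export
write_ddct_report <- function(result, tsv_path = NULL, json_path = NULL,
                              p = NULL) {
  if (!is.null(tsv_path)) {
    s <- result$samples
    con <- file(tsv_path, open = "wb")
    writeLines(c("sample_id\tgroup\tfold_change\tnon_detect",
                 paste(s$sample_id, s$group, s$fold_change,
                       tolower(s$non_detect), sep = "\t")),
               con, sep = "\n")
    close(con)
  }
  summary <- list(target_gene = result$target_gene,
                  reference_gene = result$reference_gene,
                  control_group = result$control_group,
                  group_fold_change =
                    stats::setNames(as.list(result$groups$fold_change),
                                    result$groups$group))
  if (!is.null(p)) summary$p <- p
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(summary)
}
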