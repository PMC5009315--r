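#' Expression studies and annotation masks
#'
#' An expression study holds one microarray study's linear-scale
#' intensity matrix (features x samples) together with a sample-to-group
#' map and platform identity. Intensities are assumed normalized and
#' background-corrected upstream; no normalization is performed here.
#'
#' @param values numeric matrix of nonnegative intensities with unique
#'   rownames (feature ids) and colnames (sample ids).
#' @param groups named character vector mapping every sample id to a
#'   group label.
#' @param study_id study identifier.
#' @param platform_id platform identifier (e.g. an array design name).
#' @param is_gene_level logical; `TRUE` once probes have been collapsed
#'   to gene symbols.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(values, groups, study_id = "study",
                             platform_id = NA_character_,
                             is_gene_level = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("intensities must be finite and nonnegative", call. = FALSE)
  }
  samples <- colnames(values)
  missing <- setdiff(samples, names(groups))
  if (length(missing)) {
    stop("sample(s) missing from group map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- groups[samples]
  structure(
    list(study_id = study_id,
         values = values,
         groups = as.character(stats::setNames(groups, samples)),
         platform_id = platform_id,
         is_gene_level = isTRUE(is_gene_level)),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d features x %d samples (%s-level)\n",
              x$study_id, nrow(x$values), ncol(x$values),
              if (x$is_gene_level) "gene" else "probe"))
  tab <- table(sample_groups(x))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Sample-to-group map of a study
#' @param study an `expression_study`.
#' @return named character vector sample id -> group label.
#' @export
sample_groups <- function(study) {
  stats::setNames(study$groups, colnames(study$values))
}

#' Read a tab-delimited expression matrix with its group map
#'
#' The matrix file has a header row (first cell a feature-id column
#' name, then sample ids) and one row per feature. The group map is a
#' two-column TSV `sample_id<TAB>group` without header. Non-numeric
#' cells, duplicate sample ids, and samples absent from the group map
#' are rejected with the offending coordinates/ids named.
#'
#' @param path expression matrix TSV.
#' @param group_map group map TSV path, or a named character vector.
#' @param study_id,platform_id,is_gene_level metadata for the study;
#'   `study_id` defaults to the file name without extension.
#' @return an `expression_study`, feature and sample order as in file.
#' @export
read_expression_matrix <- function(path, group_map,
                                   study_id = NULL,
                                   platform_id = NA_character_,
                                   is_gene_level = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(study_id)) {
    study_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (!ncol(raw) >= 2) stop("matrix must have at least one sample column",
                            call. = FALSE)
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  feature_ids <- trimws(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at feature '%s', sample '%s': '%s'",
                 feature_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(feature_ids, sample_ids)
  if (is.character(group_map) && length(group_map) == 1 && is.null(names(group_map))) {
    group_map <- read_group_map(group_map)
  }
  missing <- setdiff(sample_ids, names(group_map))
  if (length(missing)) {
    stop("sample(s) missing from group map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  expression_study(num, group_map, study_id = study_id,
                   platform_id = platform_id, is_gene_level = is_gene_level)
}

#' Read a two-column sample-to-group TSV
#' @param path file path (no header, `sample_id<TAB>group`).
#' @return named character vector.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("group map must have two columns", call. = FALSE)
  stats::setNames(trimws(tab[[2]]), trimws(tab[[1]]))
}

#' Write an expression matrix (and optionally its group map) as TSV
#'
#' UTF-8, Unix newlines. Round-trips through
#' [read_expression_matrix()] field-by-field when the same metadata is
#' supplied.
#'
#' @param study an `expression_study`.
#' @param path output matrix path.
#' @param group_map_path optional path for the sample-to-group TSV.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(study, path, group_map_path = NULL) {
  con <- file(path, open = "wb")
  header <- paste(c("feature_id", colnames(study$values)), collapse = "\t")
  body <- apply(study$values, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15, scientific = FALSE),
          collapse = "\t"))
  writeLines(c(header, paste(rownames(study$values), body, sep = "\t")),
             con, sep = "\n")
  close(con)
  if (!is.null(group_map_path)) {
    gm <- sample_groups(study)
    con2 <- file(group_map_path, open = "wb")
    writeLines(paste(names(gm), gm, sep = "\t"), con2, sep = "\n")
    close(con2)
  }
  invisible(path)
}

#' Probe-to-gene annotation mask
#'
#' A mask restricts heterogeneous array platforms to a shared gene
#' universe: each probe maps to at most one gene symbol, and probes
#' absent from the map are excluded by construction. A user-supplied
#' mask is treated as authoritative.
#'
#' @param probe_to_gene named character vector probe id -> gene symbol.
#' @param platform_id platform identifier the mask applies to.
#' @return object of class `annotation_mask` with elements
#'   `platform_id`, `probe_to_gene`, `gene_universe`.
#' @export
annotation_mask <- function(probe_to_gene, platform_id = NA_character_) {
  if (is.null(names(probe_to_gene)) || anyDuplicated(names(probe_to_gene))) {
    stop("`probe_to_gene` must have unique probe names", call. = FALSE)
  }
  probe_to_gene <- stats::setNames(trimws(as.character(probe_to_gene)),
                                   trimws(names(probe_to_gene)))
  structure(
    list(platform_id = platform_id,
         probe_to_gene = probe_to_gene,
         gene_universe = sort(unique(unname(probe_to_gene)))),
    class = "annotation_mask"
  )
}

#' Read / write an annotation mask as a two-column TSV
#' @param path file path (`probe_id<TAB>gene_symbol`, no header).
#' @param platform_id platform identifier to attach.
#' @return an `annotation_mask`.
#' @export
read_annotation_mask <- function(path, platform_id = NA_character_) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("mask must have two columns", call. = FALSE)
  annotation_mask(stats::setNames(tab[[2]], tab[[1]]), platform_id)
}

#' @rdname read_annotation_mask
#' @param mask an `annotation_mask` to write.
#' @export
write_annotation_mask <- function(mask, path) {
  con <- file(path, open = "wb")
  writeLines(paste(names(mask$probe_to_gene), mask$probe_to_gene, sep = "\t"),
             con, sep = "\n")
  close(con)
  invisible(path)
}

#' Collapse a probe-level study to gene level through an annotation mask
#'
#' Only probes present in the mask survive; genes with at least one
#' mapped probe in the study become the output features (sorted by
#' symbol so that any platform masked to the same universe yields a
#' comparable feature order). For multi-probe genes the gene row is
#' chosen or derived by `collapse_rule`:
#' \describe{
#'   \item{max_mean}{the probe row with the highest mean intensity
#'     across all samples (the usual microarray convention);}
#'   \item{median}{the per-sample median across probe rows.}
#' }
#'
#' @param study a probe-level `expression_study`.
#' @param mask an `annotation_mask`.
#' @param collapse_rule `"max_mean"` (default) or `"median"`.
#' @return a gene-level `expression_study`.
#' @export
apply_annotation_mask <- function(study, mask,
                                  collapse_rule = c("max_mean", "median")) {
  collapse_rule <- match.arg(collapse_rule)
  if (study$is_gene_level) {
    stop("study is already gene-level", call. = FALSE)
  }
  probes <- intersect(rownames(study$values), names(mask$probe_to_gene))
  if (!length(probes)) {
    stop("no probes of study '", study$study_id, "' are in the mask",
         call. = FALSE)
  }
  genes <- mask$probe_to_gene[probes]
  by_gene <- split(probes, genes)
  gene_ids <- sort(names(by_gene))
  out <- matrix(NA_real_, length(gene_ids), ncol(study$values),
                dimnames = list(gene_ids, colnames(study$values)))
  for (g in gene_ids) {
    rows <- study$values[by_gene[[g]], , drop = FALSE]
    if (nrow(rows) == 1L) {
      out[g, ] <- rows[1L, ]
    } else if (collapse_rule == "max_mean") {
      out[g, ] <- rows[which.max(rowMeans(rows)), ]
    } else {
      out[g, ] <- apply(rows, 2L, stats::median)
    }
  }
  expression_study(out, sample_groups(study), study_id = study$study_id,
                   platform_id = study$platform_id, is_gene_level = TRUE)
}
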