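#' Directional gene sets
#'
#' A directional gene set records, for each gene symbol, whether it is
#' up- or down-regulated in a comparison, optionally with per-study
#' provenance (which study called it, at what fold change and p-value).
#' It is the currency passed between differential expression, reference
#' signature derivation, and the meta-profile operations.
#'
#' @param gene character vector of gene symbols (whitespace is trimmed;
#'   symbols are case-sensitive).
#' @param direction character vector, one of `"up"` or `"down"` per gene.
#' @param provenance optional data.frame with columns `gene`, `study_id`,
#'   `fold_change`, `p` recording which study contributed each call.
#' @return An object of class `gene_set`: a list with elements `entries`
#'   (data.frame `gene`, `direction`) and `provenance`.
#' @examples
#' gs <- gene_set(c("CDX2", "MUC2", "TP63"), c("up", "up", "down"))
#' n_genes(gs)
#' @export
gene_set <- function(gene = character(), direction = character(),
                     provenance = NULL) {
  gene <- trimws(as.character(gene))
  direction <- as.character(direction)
  if (length(gene) != length(direction)) {
    stop("`gene` and `direction` must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(direction), c("up", "down"))
  if (length(bad)) {
    stop("unknown direction token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(gene)) {
    dup <- unique(gene[duplicated(gene)])
    stop("duplicate gene symbol(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(provenance)) {
    need <- c("gene", "study_id", "fold_change", "p")
    if (!all(need %in% names(provenance))) {
      stop("provenance must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    key <- paste(provenance$gene, provenance$study_id)
    if (anyDuplicated(key)) {
      stop("provenance study ids must be unique per gene", call. = FALSE)
    }
    provenance <- provenance[provenance$gene %in% gene, , drop = FALSE]
    rownames(provenance) <- NULL
  }
  structure(
    list(entries = data.frame(gene = gene, direction = direction,
                              stringsAsFactors = FALSE),
         provenance = provenance),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  n_up <- sum(x$entries$direction == "up")
  n_dn <- sum(x$entries$direction == "down")
  cat(sprintf("<gene_set> %d genes (%d up, %d down)\n",
              nrow(x$entries), n_up, n_dn))
  invisible(x)
}

#' Number of genes in a gene set
#' @param x a `gene_set` (or `meta_profile`).
#' @return integer count of member genes.
#' @export
n_genes <- function(x) {
  x <- as_gene_set(x)
  nrow(x$entries)
}

#' Coerce to a gene set
#'
#' Accepts a `gene_set` (returned unchanged), a `meta_profile` (its
#' entries), or a two-column data.frame `gene`, `direction`.
#' @param x object to coerce.
#' @return a `gene_set`.
#' @export
as_gene_set <- function(x) {
  if (inherits(x, "gene_set")) return(x)
  if (inherits(x, "meta_profile")) return(x$entries)
  if (is.data.frame(x) && all(c("gene", "direction") %in% names(x))) {
    return(gene_set(x$gene, x$direction))
  }
  stop("cannot coerce to gene_set", call. = FALSE)
}

#' Directions as a named vector
#' @param x a `gene_set` or coercible object.
#' @return named character vector gene -> "up"/"down".
#' @export
gene_directions <- function(x) {
  x <- as_gene_set(x)
  stats::setNames(x$entries$direction, x$entries$gene)
}

#' Read a directional gene list from a two-column TSV
#'
#' Expects `gene<TAB>direction` with direction `up` or `down`, no header.
#' Duplicate symbols and unknown direction tokens are rejected. An empty
#' file yields an empty set.
#'
#' @param path file path.
#' @return a `gene_set`.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("gene list lines must be gene<TAB>direction: ", path, call. = FALSE)
  }
  gene_set(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
}

#' Write a directional gene list as TSV
#' @param set a `gene_set` or coercible object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(set, path) {
  set <- as_gene_set(set)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(set$entries)) {
    writeLines(paste(set$entries$gene, set$entries$direction, sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}
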