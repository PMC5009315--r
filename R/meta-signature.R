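#' Round half away from zero
#'
#' Percentages in reports are rounded to a fixed number of decimals with
#' halves going away from zero (so 77.65 -> 77.7), matching conventional
#' manuscript reporting rather than R's banker's rounding.
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Pearson chi-square on a 2x2 table
#'
#' Pearson chi-square without continuity correction by default (Yates
#' correction available), df = 1, upper-tail p. A zero row margin
#' leaves the statistic undefined: `chi2` and `p` are `NA`. A zero
#' column margin with positive row margins means observed equals
#' expected in every cell, so `chi2 = 0` and `p = 1`.
#'
#' @param tab 2x2 matrix of counts.
#' @param correct apply the Yates continuity correction.
#' @return list with `chi2` and `p`.
#' @export
chisq_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(rowSums(tab) == 0)) {
    return(list(chi2 = NA_real_, p = NA_real_))
  }
  if (any(colSums(tab) == 0)) {
    return(list(chi2 = 0, p = 1))
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}

#' Derive the reference intestinal signature from two tissue comparisons
#'
#' The reference signature consists of the genes altered in the same
#' direction in both intestinal tissues relative to the common reference
#' tissue (e.g. duodenum-vs-oesophagus and colon-vs-oesophagus).
#' Direction-discordant genes are excluded.
#'
#' @param cmp_a,cmp_b `gene_set`s from the two comparisons.
#' @return the concordant-intersection `gene_set` with merged provenance.
#' @export
derive_reference_signature <- function(cmp_a, cmp_b) {
  cmp_a <- as_gene_set(cmp_a); cmp_b <- as_gene_set(cmp_b)
  da <- gene_directions(cmp_a); db <- gene_directions(cmp_b)
  common <- intersect(names(da), names(db))
  keep <- common[da[common] == db[common]]
  prov <- rbind(cmp_a$provenance, cmp_b$provenance)
  if (!is.null(prov)) prov <- prov[prov$gene %in% keep, , drop = FALSE]
  gene_set(keep, unname(da[keep]), provenance = prov)
}

#' Build a cross-study meta-profile by concordant intersection
#'
#' A meta-profile is the set of genes differentially expressed with a
#' concordant direction across several independent studies of the same
#' condition. Under `all_concordant` (the default, a strict shared
#' profile) a gene must be present in every study set with one common
#' direction. Under `majority_concordant` it must carry a common
#' direction in more than half of the sets and never appear with the
#' opposite direction.
#'
#' @param per_study_sets list of at least two `gene_set`s (one per
#'   study); names, if any, become the member study ids.
#' @param rule `"all_concordant"` or `"majority_concordant"`.
#' @return object of class `meta_profile`: list with `entries`
#'   (a `gene_set` with aggregated provenance), `member_studies`, `rule`.
#' @export
build_meta_profile <- function(per_study_sets,
                               rule = c("all_concordant",
                                        "majority_concordant")) {
  rule <- match.arg(rule)
  if (!is.list(per_study_sets) || length(per_study_sets) == 0) {
    stop("`per_study_sets` must be a non-empty list of gene sets",
         call. = FALSE)
  }
  if (length(per_study_sets) < 2) {
    stop("a meta-profile needs at least 2 study sets", call. = FALSE)
  }
  sets <- lapply(per_study_sets, as_gene_set)
  ids <- names(sets)
  if (is.null(ids)) ids <- paste0("study", seq_along(sets))
  n <- length(sets)
  dirs <- lapply(sets, gene_directions)
  all_genes <- unique(unlist(lapply(dirs, names)))
  n_up <- n_dn <- integer(length(all_genes))
  names(n_up) <- names(n_dn) <- all_genes
  for (d in dirs) {
    n_up[names(d)[d == "up"]] <- n_up[names(d)[d == "up"]] + 1L
    n_dn[names(d)[d == "down"]] <- n_dn[names(d)[d == "down"]] + 1L
  }
  keep <- if (rule == "all_concordant") {
    all_genes[n_up == n | n_dn == n]
  } else {
    all_genes[(n_up > n / 2 & n_dn == 0L) | (n_dn > n / 2 & n_up == 0L)]
  }
  direction <- ifelse(n_up[keep] > 0L, "up", "down")
  prov <- do.call(rbind, lapply(seq_along(sets), function(i) {
    p <- sets[[i]]$provenance
    if (is.null(p)) {
      e <- sets[[i]]$entries
      p <- data.frame(gene = e$gene, study_id = ids[i],
                      fold_change = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    }
    p[p$gene %in% keep, , drop = FALSE]
  }))
  structure(
    list(entries = gene_set(keep, unname(direction), provenance = prov),
         member_studies = ids,
         rule = rule),
    class = "meta_profile"
  )
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("<meta_profile> %d genes across %d studies (%s)\n",
              n_genes(x), length(x$member_studies), x$rule))
  invisible(x)
}

#' Decompose a disease meta-profile against a reference signature
#'
#' Partitions a disease profile into a reference-like component (genes
#' also in the reference signature, direction-concordant by default)
#' and a non-reference component (the rest). The reference-like
#' fraction is reported as a percentage to one decimal.
#'
#' @param disease a `meta_profile` or `gene_set` (non-empty).
#' @param reference the reference `gene_set` (e.g. the intestinal
#'   signature).
#' @param require_direction_match if `TRUE` (default) a disease gene
#'   must carry the same direction as in the reference to count as
#'   reference-like; membership alone suffices otherwise.
#' @return object of class `signature_decomposition`: `reference_like`
#'   and `non_reference` gene sets, counts `n_disease`/`n_reference`,
#'   and `fraction_reference_like` (percent, 1 decimal).
#' @export
decompose_signature <- function(disease, reference,
                                require_direction_match = TRUE) {
  dis <- as_gene_set(disease)
  ref <- as_gene_set(reference)
  if (n_genes(dis) == 0) stop("disease profile is empty", call. = FALSE)
  dd <- gene_directions(dis)
  rd <- gene_directions(ref)
  in_ref <- names(dd) %in% names(rd)
  if (require_direction_match) {
    in_ref <- in_ref & dd == rd[names(dd)]
    in_ref[is.na(in_ref)] <- FALSE
  }
  like <- names(dd)[in_ref]
  rest <- names(dd)[!in_ref]
  structure(
    list(reference_like = gene_set(like, unname(dd[like])),
         non_reference = gene_set(rest, unname(dd[rest])),
         n_disease = length(dd),
         n_reference = length(rd),
         fraction_reference_like =
           round_half_away(100 * length(like) / length(dd), 1)),
    class = "signature_decomposition"
  )
}

#' @export
print.signature_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<signature_decomposition> %d/%d reference-like ",
                     "(%.1f%%), %d non-reference\n"),
              n_genes(x$reference_like), x$n_disease,
              x$fraction_reference_like, n_genes(x$non_reference)))
  invisible(x)
}

#' Maintenance of decomposition components in a later disease stage
#'
#' For each component of an earlier-stage decomposition, counts the
#' genes still present (direction-concordant by default) in the
#' later-stage profile, giving a 2x2 table (component x maintained/lost)
#' with per-row maintenance percentages and a Pearson chi-square
#' association test (df = 1, upper-tail p, no continuity correction by
#' default).
#'
#' @param decomp a `signature_decomposition` from the earlier stage.
#' @param later_stage later-stage `meta_profile` or `gene_set`
#'   (non-empty).
#' @param require_direction_match require direction concordance for a
#'   gene to count as maintained.
#' @param correct Yates continuity correction for the chi-square.
#' @return object of class `maintenance_result`: 2x2 `table`, per-row
#'   `fractions` (percent, 1 decimal), `chi2`, `p`, and a per-gene
#'   `detail` data.frame (`component`, `gene`, `direction`,
#'   `maintained`).
#' @export
maintenance_analysis <- function(decomp, later_stage,
                                 require_direction_match = TRUE,
                                 correct = FALSE) {
  later <- as_gene_set(later_stage)
  if (n_genes(later) == 0) stop("later-stage profile is empty", call. = FALSE)
  ld <- gene_directions(later)
  check <- function(gs) {
    d <- gene_directions(gs)
    m <- names(d) %in% names(ld)
    if (require_direction_match) {
      m <- m & d == ld[names(d)]
      m[is.na(m)] <- FALSE
    }
    m
  }
  m_like <- check(decomp$reference_like)
  m_rest <- check(decomp$non_reference)
  tab <- matrix(c(sum(m_like), sum(!m_like), sum(m_rest), sum(!m_rest)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("reference_like", "non_reference"),
                                c("maintained", "lost")))
  fr <- round_half_away(100 * tab[, "maintained"] / rowSums(tab), 1)
  cs <- chisq_2x2(tab, correct = correct)
  detail <- rbind(
    data.frame(component = "reference_like",
               gene = decomp$reference_like$entries$gene,
               direction = decomp$reference_like$entries$direction,
               maintained = unname(m_like), stringsAsFactors = FALSE),
    data.frame(component = "non_reference",
               gene = decomp$non_reference$entries$gene,
               direction = decomp$non_reference$entries$direction,
               maintained = unname(m_rest), stringsAsFactors = FALSE)
  )
  structure(
    list(table = tab, fractions = fr, chi2 = cs$chi2, p = cs$p,
         detail = detail),
    class = "maintenance_result"
  )
}

#' @export
print.maintenance_result <- function(x, ...) {
  cat("<maintenance_result>\n")
  print(x$table)
  cat(sprintf("  maintained: reference-like %.1f%%, non-reference %.1f%%\n",
              x$fractions[1], x$fractions[2]))
  if (is.na(x$chi2)) {
    cat("  chi-square undefined (zero margin)\n")
  } else {
    cat(sprintf("  chi2 = %.2f, p = %.3g\n", x$chi2, x$p))
  }
  invisible(x)
}

#' Fraction of another disease profile covered by a signature
#'
#' Measures how much of some other condition's meta-profile lies inside
#' a signature (direction-concordant by default), as a percentage of
#' that profile's size — used to ask how specific an intestine-like
#' signature is to the intestinal lineage versus other cancers. A
#' comparator in/out split (e.g. the corresponding split of the disease
#' profile of interest) can be supplied for a 2x2 chi-square comparison.
#'
#' @param signature the reference `gene_set`.
#' @param other_profile `meta_profile` or `gene_set` of the other
#'   condition (non-empty).
#' @param comparator optional length-2 numeric `c(in, out)` counts to
#'   test against, or a `signature_decomposition` (its reference-like /
#'   non-reference sizes are used).
#' @param require_direction_match require direction concordance.
#' @param correct Yates correction for the chi-square.
#' @return list with `fraction` (percent, 1 decimal), `n_in`, `n_total`,
#'   `chi2`, `p` (`NA` when no comparator given).
#' @export
specificity_fraction <- function(signature, other_profile,
                                 comparator = NULL,
                                 require_direction_match = TRUE,
                                 correct = FALSE) {
  other <- as_gene_set(other_profile)
  if (n_genes(other) == 0) stop("other profile is empty", call. = FALSE)
  od <- gene_directions(other)
  sd_ <- gene_directions(signature)
  inside <- names(od) %in% names(sd_)
  if (require_direction_match) {
    inside <- inside & od == sd_[names(od)]
    inside[is.na(inside)] <- FALSE
  }
  n_in <- sum(inside); n_tot <- length(od)
  chi2 <- p <- NA_real_
  if (!is.null(comparator)) {
    if (inherits(comparator, "signature_decomposition")) {
      comparator <- c(n_genes(comparator$reference_like),
                      n_genes(comparator$non_reference))
    }
    stopifnot(length(comparator) == 2)
    tab <- matrix(c(n_in, n_tot - n_in, comparator[1], comparator[2]),
                  nrow = 2, byrow = TRUE)
    cs <- chisq_2x2(tab, correct = correct)
    chi2 <- cs$chi2; p <- cs$p
  }
  list(fraction = round_half_away(100 * n_in / n_tot, 1),
       n_in = n_in, n_total = n_tot, chi2 = chi2, p = p)
}

#' Write a decomposition/maintenance report
#'
#' The TSV has columns `component`, `gene`, `direction`, `maintained`;
#' the JSON summary carries counts, percentages (1 decimal), chi-square
#' and p.
#' @param maint a `maintenance_result`.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the summary list written to JSON.
#' @export
write_maintenance_report <- function(maint, tsv_path = NULL,
                                     json_path = NULL) {
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, open = "wb")
    d <- maint$detail
    writeLines(c("component\tgene\tdirection\tmaintained",
                 paste(d$component, d$gene, d$direction,
                       tolower(d$maintained), sep = "\t")),
               con, sep = "\n")
    close(con)
  }
  summary <- list(
    counts = list(
      reference_like = unname(sum(maint$table["reference_like", ])),
      non_reference = unname(sum(maint$table["non_reference", ])),
      maintained_reference_like = unname(maint$table["reference_like",
                                                     "maintained"]),
      maintained_non_reference = unname(maint$table["non_reference",
                                                    "maintained"])),
    fractions = as.list(maint$fractions),
    chi2 = maint$chi2,
    p = maint$p
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(summary)
}
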