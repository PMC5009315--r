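#' Load a pipeline configuration from YAML
#' @param path YAML file path, or a list (returned unchanged).
#' @return configuration list.
#' @export
load_pipeline_config <- function(path) {
  if (is.list(path)) return(path)
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

# snapshot the config as YAML, log the run, return the config hash
log_run <- function(out_dir, stage, config, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  snap <- file.path(out_dir, paste0(stage, "_config.yaml"))
  yaml::write_yaml(config, snap)
  hash <- unname(tools::md5sum(snap))
  line <- sprintf("%s\t%s\tintsig %s\tconfig=%s%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), stage,
                  as.character(utils::packageVersion("intsig")), hash,
                  if (is.null(seed)) "" else paste0("\tseed=", seed))
  cat(line, "\n", sep = "", file = file.path(out_dir, "pipeline.log"),
      append = TRUE)
  hash
}

stage_stop <- function(stage, e) {
  stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
}

#' Simulate a multi-study data set and write it to disk
#'
#' Runs [generate_multistudy()] and writes per-study expression
#' matrices and group maps, the shared annotation mask, the planted
#' truth gene lists, and a JSON summary.
#'
#' @param config list with optional `generator` (overrides for
#'   [multistudy_config()]) and `out_dir`.
#' @param seed integer RNG seed.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, the generated object with a `paths` element.
#' @export
run_simulate <- function(config = list(), seed = 1, out_dir = NULL) {
  config <- load_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "results/simulated"
  gen_cfg <- do.call(multistudy_config, config$generator %||% list())
  hash <- log_run(out_dir, "simulate", config, seed)
  sim <- generate_multistudy(gen_cfg, seed = seed)
  paths <- list()
  for (id in names(sim$studies)) {
    mp <- file.path(out_dir, paste0(id, "_matrix.tsv"))
    gp <- file.path(out_dir, paste0(id, "_groups.tsv"))
    write_expression_matrix(sim$studies[[id]], mp, group_map_path = gp)
    paths[[id]] <- list(matrix = mp, groups = gp)
  }
  paths$mask <- file.path(out_dir, "mask.tsv")
  write_annotation_mask(sim$mask, paths$mask)
  for (nm in c("signature", "bo_profile", "oac_profile")) {
    paths[[nm]] <- file.path(out_dir, paste0("truth_", nm, ".tsv"))
    write_gene_list(sim$truth[[nm]], paths[[nm]])
  }
  summary <- list(
    config_hash = hash, seed = seed,
    n_studies = length(sim$studies),
    signature_size = n_genes(sim$truth$signature),
    bo_profile_size = n_genes(sim$truth$bo_profile),
    oac_profile_size = n_genes(sim$truth$oac_profile),
    planted_maintenance = gen_cfg$maintenance_fraction,
    realized_maintenance = sim$truth$realized_maintenance
  )
  jsonlite::write_json(summary, file.path(out_dir, "simulate_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sim$paths <- paths
  invisible(sim)
}

# read a (matrix, groups) pair and collapse through the mask
load_gene_level <- function(entry, mask, collapse_rule, study_id) {
  if (!file.exists(entry$matrix)) {
    stop("missing input path: ", entry$matrix, call. = FALSE)
  }
  st <- read_expression_matrix(entry$matrix, entry$groups,
                               study_id = study_id)
  apply_annotation_mask(st, mask, collapse_rule = collapse_rule)
}

#' Derive the reference intestinal signature from a tissue study
#'
#' Reads the three-tissue study, collapses it through the annotation
#' mask, runs differential expression for each intestinal tissue
#' against the reference tissue, intersects the concordant calls, and
#' writes the DE tables, the signature gene list, and a JSON summary.
#'
#' @param config list with elements `tissue` (list `matrix`, `groups`),
#'   `mask` (path), `comparisons` (list of lists `test`, `ref`;
#'   default duodenum and colon vs oesophagus), `fc_threshold`,
#'   `p_threshold`, `collapse_rule`, `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, a list with the signature `gene_set`, per
#'   comparison sets, and the summary.
#' @export
run_signature <- function(config, out_dir = NULL) {
  config <- load_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "results/signature"
  hash <- log_run(out_dir, "signature", config)
  fc_thr <- config$fc_threshold %||% 1.5
  p_thr <- config$p_threshold %||% 0.001
  rule <- config$collapse_rule %||% "max_mean"
  comparisons <- config$comparisons %||%
    list(list(test = "DUO", ref = "OES"), list(test = "COL", ref = "OES"))
  res <- tryCatch({
    if (!file.exists(config$mask)) {
      stop("missing input path: ", config$mask, call. = FALSE)
    }
    mask <- read_annotation_mask(config$mask)
    st <- load_gene_level(config$tissue, mask, rule, "TISSUE")
    sets <- lapply(comparisons, function(cmp) {
      gs <- differential_genes(st, cmp$test, cmp$ref,
                               fc_threshold = fc_thr, p_threshold = p_thr)
      write_de_table(gs, file.path(out_dir,
                                   sprintf("de_%s_vs_%s.tsv", cmp$test,
                                           cmp$ref)))
      gs
    })
    sig <- Reduce(derive_reference_signature, sets)
    write_gene_list(sig, file.path(out_dir, "reference_signature.tsv"))
    summary <- list(
      config_hash = hash,
      comparisons = lapply(seq_along(comparisons), function(i)
        list(test = comparisons[[i]]$test, ref = comparisons[[i]]$ref,
             n_genes = n_genes(sets[[i]]))),
      signature_size = n_genes(sig)
    )
    jsonlite::write_json(summary,
                         file.path(out_dir, "signature_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(signature = sig, comparison_sets = sets, summary = summary)
  }, error = function(e) stage_stop("signature", e))
  invisible(res)
}

#' Meta-profiles, decomposition, maintenance and specificity
#'
#' Reads the reference signature and the per-study disease inputs,
#' builds the earlier- and later-stage meta-profiles by concordant
#' intersection, decomposes the earlier-stage profile against the
#' reference, quantifies maintenance of both components in the later
#' stage, optionally measures specificity of the signature in other
#' disease profiles, and writes the reports and a JSON summary.
#'
#' @param config list with `reference` (gene-list path), `mask` (path),
#'   `early_studies` and `late_studies` (named lists of `matrix`,
#'   `groups`, `test`, `ref` entries; `test`/`ref` default to
#'   `BO`/`SQ` and `OAC`/`SQ`), optional `other_profiles` (same shape)
#'   for specificity, plus `fc_threshold`, `p_threshold`,
#'   `collapse_rule`, `rule` (meta rule), `require_direction_match`,
#'   `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, list with the meta-profiles, decomposition,
#'   maintenance result, specificity list, and summary.
#' @export
run_meta <- function(config, out_dir = NULL) {
  config <- load_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "results/meta"
  hash <- log_run(out_dir, "meta", config)
  fc_thr <- config$fc_threshold %||% 1.5
  p_thr <- config$p_threshold %||% 0.001
  collapse <- config$collapse_rule %||% "max_mean"
  rule <- config$rule %||% "all_concordant"
  dirmatch <- config$require_direction_match %||% TRUE
  res <- tryCatch({
    for (p in c(config$reference, config$mask)) {
      if (!file.exists(p)) stop("missing input path: ", p, call. = FALSE)
    }
    reference <- read_gene_list(config$reference)
    mask <- read_annotation_mask(config$mask)
    de_stage <- function(studies, default_test, default_ref) {
      sets <- lapply(names(studies), function(id) {
        e <- studies[[id]]
        st <- load_gene_level(e, mask, collapse, id)
        differential_genes(st, e$test %||% default_test,
                           e$ref %||% default_ref,
                           fc_threshold = fc_thr, p_threshold = p_thr)
      })
      names(sets) <- names(studies)
      sets
    }
    early_sets <- de_stage(config$early_studies, "BO", "SQ")
    late_sets <- de_stage(config$late_studies, "OAC", "SQ")
    early_profile <- build_meta_profile(early_sets, rule = rule)
    late_profile <- build_meta_profile(late_sets, rule = rule)
    decomp <- decompose_signature(early_profile, reference,
                                  require_direction_match = dirmatch)
    maint <- maintenance_analysis(decomp, late_profile,
                                  require_direction_match = dirmatch)
    write_gene_list(early_profile,
                    file.path(out_dir, "early_meta_profile.tsv"))
    write_gene_list(late_profile,
                    file.path(out_dir, "late_meta_profile.tsv"))
    write_maintenance_report(maint,
                             tsv_path = file.path(out_dir,
                                                  "maintenance.tsv"))
    late_in_sig <- specificity_fraction(reference, late_profile,
                                        require_direction_match = dirmatch)
    spec <- list()
    for (id in names(config$other_profiles %||% list())) {
      e <- config$other_profiles[[id]]
      st <- load_gene_level(e, mask, collapse, id)
      gs <- differential_genes(st, e$test, e$ref,
                               fc_threshold = fc_thr, p_threshold = p_thr)
      spec[[id]] <- specificity_fraction(reference, gs,
                                         comparator = decomp,
                                         require_direction_match = dirmatch)
    }
    summary <- list(
      config_hash = hash,
      early_profile_size = n_genes(early_profile),
      late_profile_size = n_genes(late_profile),
      decomposition = list(
        n_reference_like = n_genes(decomp$reference_like),
        n_non_reference = n_genes(decomp$non_reference),
        fraction_reference_like = decomp$fraction_reference_like),
      maintenance = list(
        table = as.list(as.data.frame(maint$table)),
        fractions = as.list(maint$fractions),
        chi2 = maint$chi2, p = maint$p),
      late_stage_fraction_in_signature = late_in_sig$fraction,
      specificity = spec
    )
    jsonlite::write_json(summary, file.path(out_dir, "meta_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    list(early_profile = early_profile, late_profile = late_profile,
         decomposition = decomp, maintenance = maint,
         specificity = spec, summary = summary)
  }, error = function(e) stage_stop("meta", e))
  invisible(res)
}

#' Relative-expression (delta-delta-Ct) stage
#'
#' @param config list with `ct_table` (TSV path or `ct_table`),
#'   `target_gene`, `reference_gene`, `control_group`, optional
#'   `test_group` (for the Mann-Whitney group test), `non_detect`,
#'   `summary`, `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, list with the `ddct_result`, `p`, and summary.
#' @export
run_ddct <- function(config, out_dir = NULL) {
  config <- load_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "results/ddct"
  hash <- log_run(out_dir, "ddct",
                  config[setdiff(names(config), "ct_table")])
  res <- tryCatch({
    tab <- config$ct_table
    if (is.character(tab)) {
      if (!file.exists(tab)) stop("missing input path: ", tab,
                                  call. = FALSE)
      tab <- read_ct_table(tab)
    }
    dd <- delta_delta_ct(tab, config$target_gene, config$reference_gene,
                         config$control_group,
                         non_detect = config$non_detect %||% "clamp",
                         summary = config$summary %||% "arithmetic")
    p <- NULL
    if (!is.null(config$test_group)) {
      p <- expression_group_test(tab, config$target_gene,
                                 config$reference_gene,
                                 config$control_group, config$test_group)
    }
    summary <- write_ddct_report(
      dd, tsv_path = file.path(out_dir, "ddct_samples.tsv"),
      json_path = file.path(out_dir, "ddct_summary.json"), p = p)
    summary$config_hash <- hash
    list(result = dd, p = p, summary = summary)
  }, error = function(e) stage_stop("ddct", e))
  invisible(res)
}

#' Median-effect fits and combination-index stage
#'
#' @param config list with `single` and `combos` (TSV paths or
#'   data.frames in the dose-response dialects), optional `fa_levels`
#'   for the isobologram, `tolerance`, `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, list with per-agent fits, the CI table,
#'   isobologram coordinates, and summary.
#' @export
run_synergy <- function(config, out_dir = NULL) {
  config <- load_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "results/synergy"
  hash <- log_run(out_dir, "synergy",
                  config[vapply(config, is.character, TRUE) |
                           vapply(config, is.numeric, TRUE)])
  res <- tryCatch({
    get_tab <- function(x) {
      if (is.character(x)) {
        if (!file.exists(x)) stop("missing input path: ", x, call. = FALSE)
        read_dose_response(x)
      } else x
    }
    single <- get_tab(config$single)
    combos <- get_tab(config$combos)
    fits <- lapply(split(single, single$agent), function(d)
      median_effect_fit(d$dose, d$fa))
    if (length(fits) < 2) stop("need two agents", call. = FALSE)
    ci <- combination_index_table(fits[[1]], fits[[2]], combos,
                                  tolerance = config$tolerance %||% 0.1)
    write_dose_response(ci, file.path(out_dir, "combination_index.tsv"))
    iso <- isobologram(fits[[1]], fits[[2]],
                       fa_levels = config$fa_levels %||% c(0.5, 0.75, 0.9),
                       combos = combos)
    write_dose_response(iso$lines, file.path(out_dir, "isobologram.tsv"))
    summary <- list(
      config_hash = hash,
      fits = lapply(fits, function(f)
        list(m = f$m, Dm = f$Dm, r = f$r, flagged = f$flagged)),
      median_CI = stats::median(ci$CI),
      n_synergistic = sum(ci$classification == "synergy")
    )
    jsonlite::write_json(summary,
                         file.path(out_dir, "synergy_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(fits = fits, ci = ci, isobologram = iso, summary = summary)
  }, error = function(e) stage_stop("synergy", e))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
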