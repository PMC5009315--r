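#' Default configuration for the multi-study expression generator
#'
#' The defaults emulate the data regime of a Barrett's oesophagus (BO) /
#' oesophageal adenocarcinoma (OAC) meta-analysis: one three-tissue
#' normal study (oesophagus, duodenum, colon) from which the intestinal
#' reference signature is derived, three independent BO-vs-squamous
#' studies, and three OAC-vs-squamous studies, all on partially
#' overlapping probe universes harmonized by a shared annotation mask.
#' 2861 genes carry a directional intestinal effect; 989 genes are
#' altered in BO, of which 769 are intestine-like (direction-concordant
#' with the intestinal signature) and 220 BO-specific; each
#' intestine-like gene is retained in OAC independently with
#' probability `maintenance_fraction` (0.85) and each BO-specific gene
#' with probability `nonref_maintenance` (45/220); 381 further genes
#' are OAC-specific, giving an OAC profile of about 1078 genes.
#' Group sizes default to 9 samples so the p < 0.001 rank-test gate is
#' attainable; log2 noise defaults to 0.5, a realistic inter-sample
#' variability for normalized arrays, and planted effects are drawn
#' uniformly from 2-4 log2 units (4- to 16-fold), strong enough that
#' detection at the gate is near-certain and set-level maintenance
#' estimates are not confounded by per-study detection failure.
#'
#' @param ... named overrides of any default.
#' @return a configuration list.
#' @export
multistudy_config <- function(...) {
  cfg <- list(
    n_genes = 10000,
    signature_size = 2861,
    bo_like = 769,
    bo_specific = 220,
    oac_specific = 381,
    maintenance_fraction = 0.85,
    nonref_maintenance = 45 / 220,
    tissue_n = 9,
    study_n = 9,
    n_bo_studies = 3,
    n_oac_studies = 3,
    sigma = 0.5,
    effect_range = c(2, 4),
    baseline_mean = 7,
    baseline_sd = 1.5,
    platform_overlap = 0.95,
    duplicate_probe_fraction = 0.1
  )
  utils::modifyList(cfg, list(...))
}

#' Generate a synthetic multi-study expression data set with truth
#'
#' Produces probe-level expression studies, a shared probe-to-gene
#' annotation mask, and the generating truth. Intensities are
#' log-normal: value = 2^(baseline + probe offset + group effect +
#' Normal(0, sigma)), with gene baselines drawn once. Planted genes
#' carry their directional log2 effect in the designated groups;
#' later-stage (OAC) studies retain each intestine-like gene's effect
#' with probability `maintenance_fraction`, decided once per gene and
#' shared by all later-stage studies. Planted genes are present on
#' every platform; other genes are included per platform with
#' probability `platform_overlap`, and a fraction of genes get a second
#' probe to exercise probe collapsing. Fully reproducible per seed.
#'
#' @param config list from [multistudy_config()].
#' @param seed integer RNG seed.
#' @return list with `studies` (named list of probe-level
#'   `expression_study`: `TISSUE`, `BO1`..., `OAC1`...), `mask` (an
#'   `annotation_mask`), and `truth` (see Details).
#' @details `truth` contains the planted `signature`, `bo_profile`,
#'   `oac_profile`, `intestine_like` and `bo_specific` gene sets, the
#'   per-gene retention calls (`maintained_like`,
#'   `maintained_nonref`), the realized maintenance fraction, and the
#'   config/seed used.
#' @export
generate_multistudy <- function(config = multistudy_config(), seed = 1) {
  c_ <- config
  if (c_$signature_size > c_$n_genes) {
    stop("signature larger than gene universe", call. = FALSE)
  }
  if (c_$bo_like > c_$signature_size) {
    stop("intestine-like component larger than signature", call. = FALSE)
  }
  if (c_$maintenance_fraction < 0 || c_$maintenance_fraction > 1) {
    stop("maintenance_fraction must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(c_$n_genes))
  baseline <- stats::setNames(
    stats::rnorm(c_$n_genes, c_$baseline_mean, c_$baseline_sd), genes)

  rand_dir <- function(n) sample(c("up", "down"), n, replace = TRUE)
  rand_mag <- function(n) stats::runif(n, c_$effect_range[1],
                                       c_$effect_range[2])
  signed <- function(dir, mag) ifelse(dir == "up", mag, -mag)

  sig_genes <- sample(genes, c_$signature_size)
  sig_dir <- stats::setNames(rand_dir(c_$signature_size), sig_genes)
  sig_eff <- stats::setNames(signed(sig_dir, rand_mag(c_$signature_size)),
                             sig_genes)

  like_genes <- sample(sig_genes, c_$bo_like)
  spec_pool <- setdiff(genes, sig_genes)
  if (c_$bo_specific + c_$oac_specific > length(spec_pool)) {
    stop("not enough genes outside the signature for the specific sets",
         call. = FALSE)
  }
  bo_spec_genes <- sample(spec_pool, c_$bo_specific)
  bo_spec_dir <- stats::setNames(rand_dir(c_$bo_specific), bo_spec_genes)
  bo_spec_eff <- stats::setNames(
    signed(bo_spec_dir, rand_mag(c_$bo_specific)), bo_spec_genes)

  keep_like <- stats::rbinom(c_$bo_like, 1, c_$maintenance_fraction) == 1
  keep_spec <- stats::rbinom(c_$bo_specific, 1, c_$nonref_maintenance) == 1
  maintained_like <- like_genes[keep_like]
  maintained_nonref <- bo_spec_genes[keep_spec]

  oac_pool <- setdiff(spec_pool, bo_spec_genes)
  oac_spec_genes <- sample(oac_pool, c_$oac_specific)
  oac_spec_dir <- stats::setNames(rand_dir(c_$oac_specific), oac_spec_genes)
  oac_spec_eff <- stats::setNames(
    signed(oac_spec_dir, rand_mag(c_$oac_specific)), oac_spec_genes)

  # per-comparison log2 effect vectors over the whole gene universe
  zero <- stats::setNames(numeric(c_$n_genes), genes)
  eff_intestine <- zero; eff_intestine[sig_genes] <- sig_eff
  eff_bo <- zero
  eff_bo[like_genes] <- sig_eff[like_genes]
  eff_bo[bo_spec_genes] <- bo_spec_eff
  eff_oac <- zero
  eff_oac[maintained_like] <- sig_eff[maintained_like]
  eff_oac[maintained_nonref] <- bo_spec_eff[maintained_nonref]
  eff_oac[oac_spec_genes] <- oac_spec_eff

  planted <- unique(c(sig_genes, bo_spec_genes, oac_spec_genes))

  make_study <- function(study_id, group_sizes, effect_by_group) {
    samples <- unlist(lapply(names(group_sizes), function(g)
      sprintf("%s_%s_%02d", study_id, g, seq_len(group_sizes[[g]]))))
    groups <- stats::setNames(
      rep(names(group_sizes), unlist(group_sizes)), samples)
    present <- genes %in% planted |
      stats::runif(c_$n_genes) < c_$platform_overlap
    g_in <- genes[present]
    dup <- stats::runif(length(g_in)) < c_$duplicate_probe_fraction
    probe_gene <- c(g_in, g_in[dup])
    probe_id <- c(sprintf("%s:%s_a_at", study_id, g_in),
                  sprintf("%s:%s_b_at", study_id, g_in[dup]))
    offset <- c(numeric(length(g_in)),
                stats::rnorm(sum(dup), -0.5, 0.5))
    eff_mat <- vapply(names(group_sizes), function(g) {
      e <- effect_by_group[[g]]
      if (is.null(e)) zero[probe_gene] else e[probe_gene]
    }, numeric(length(probe_gene)))
    log2v <- baseline[probe_gene] + offset +
      eff_mat[, groups, drop = FALSE] +
      stats::rnorm(length(probe_gene) * length(samples), 0, c_$sigma)
    vals <- matrix(2^log2v, nrow = length(probe_gene),
                   dimnames = list(probe_id, samples))
    list(study = expression_study(vals, groups, study_id = study_id,
                                  platform_id = paste0("PLAT_", study_id)),
         probe_to_gene = stats::setNames(probe_gene, probe_id))
  }

  studies <- list()
  probe_maps <- list()
  t_ <- make_study("TISSUE",
                   list(OES = c_$tissue_n, DUO = c_$tissue_n,
                        COL = c_$tissue_n),
                   list(DUO = eff_intestine, COL = eff_intestine))
  studies$TISSUE <- t_$study; probe_maps$TISSUE <- t_$probe_to_gene
  for (i in seq_len(c_$n_bo_studies)) {
    id <- paste0("BO", i)
    s <- make_study(id, list(SQ = c_$study_n, BO = c_$study_n),
                    list(BO = eff_bo))
    studies[[id]] <- s$study; probe_maps[[id]] <- s$probe_to_gene
  }
  for (i in seq_len(c_$n_oac_studies)) {
    id <- paste0("OAC", i)
    s <- make_study(id, list(SQ = c_$study_n, OAC = c_$study_n),
                    list(OAC = eff_oac))
    studies[[id]] <- s$study; probe_maps[[id]] <- s$probe_to_gene
  }
  mask <- annotation_mask(unlist(unname(probe_maps)),
                          platform_id = "SHARED_MASK")

  bo_genes <- c(like_genes, bo_spec_genes)
  bo_dirs <- c(ifelse(sig_eff[like_genes] > 0, "up", "down"),
               unname(bo_spec_dir))
  oac_genes <- c(maintained_like, maintained_nonref, oac_spec_genes)
  oac_dirs <- c(ifelse(sig_eff[maintained_like] > 0, "up", "down"),
                unname(bo_spec_dir[maintained_nonref]),
                unname(oac_spec_dir))
  truth <- list(
    signature = gene_set(sig_genes, unname(sig_dir)),
    intestine_like = gene_set(like_genes,
                              ifelse(sig_eff[like_genes] > 0, "up", "down")),
    bo_specific = gene_set(bo_spec_genes, unname(bo_spec_dir)),
    bo_profile = gene_set(bo_genes, bo_dirs),
    oac_profile = gene_set(oac_genes, oac_dirs),
    maintained_like = maintained_like,
    maintained_nonref = maintained_nonref,
    realized_maintenance = length(maintained_like) / c_$bo_like,
    effects = list(intestine = eff_intestine, bo = eff_bo, oac = eff_oac),
    config = c_,
    seed = seed
  )
  list(studies = studies, mask = mask, truth = truth)
}

#' Default configuration for the synthetic qPCR generator
#'
#' Defaults emulate a 17-vs-17 patient cohort measured in 3 technical
#' replicates with GAPDH as the reference: the target transcript is
#' shifted by -3 cycles in the test group (an 8-fold induction) with
#' replicate noise of 0.3 cycles.
#' @param ... named overrides.
#' @return configuration list.
#' @export
ct_config <- function(...) {
  cfg <- list(
    groups = c("control", "treated"),
    n_per_group = 17,
    reference_gene = "GAPDH",
    reference_ct = 18,
    targets = list(NR5A2 = list(base_ct = 26,
                                shift = c(control = 0, treated = -3))),
    replicate_sigma = 0.3,
    n_replicates = 3,
    non_detect_ceiling = 40
  )
  utils::modifyList(cfg, list(...))
}

#' Generate a synthetic Ct table with truth
#'
#' Ct = base + shift(group, gene) + Normal(0, sigma) per technical
#' replicate; the reference gene has shift 0 everywhere.
#'
#' @param config list from [ct_config()].
#' @param seed integer RNG seed.
#' @return list with `table` (a `ct_table`) and `truth` (the config,
#'   seed, and expected fold change 2^(-shift) per target and group).
#' @export
generate_ct_table <- function(config = ct_config(), seed = 1) {
  c_ <- config
  n <- c_$n_per_group
  if (length(n) == 1) n <- stats::setNames(rep(n, length(c_$groups)),
                                           c_$groups)
  if (any(n < 2)) stop("need at least 2 samples per group", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (g in c_$groups) {
    for (i in seq_len(n[[g]])) {
      sid <- sprintf("%s_%02d", g, i)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, group = g, gene = c_$reference_gene,
        replicate = seq_len(c_$n_replicates),
        Ct = c_$reference_ct +
          stats::rnorm(c_$n_replicates, 0, c_$replicate_sigma),
        stringsAsFactors = FALSE)
      for (tg in names(c_$targets)) {
        spec <- c_$targets[[tg]]
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g, gene = tg,
          replicate = seq_len(c_$n_replicates),
          Ct = spec$base_ct + spec$shift[[g]] +
            stats::rnorm(c_$n_replicates, 0, c_$replicate_sigma),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  truth <- list(
    config = c_, seed = seed,
    expected_fc = lapply(c_$targets, function(spec) {
      ctrl <- c_$groups[1]
      stats::setNames(2^(-(spec$shift - spec$shift[[ctrl]])),
                      names(spec$shift))
    })
  )
  list(table = ct_table(tab, non_detect_ceiling = c_$non_detect_ceiling),
       truth = truth)
}

#' Default configuration for the synthetic dose-response generator
#'
#' Two median-effect agents (m = 2, Dm = 10 and m = 1, Dm = 5 in
#' consistent concentration units), six-point dose grids spanning
#' 1/8x to 4x each Dm, a 3x3 combination grid, an interaction factor of
#' 0.67 (the synergy regime observed for co-silencing experiments) and
#' log-effect noise 0.05.
#' @param ... named overrides.
#' @return configuration list.
#' @export
synergy_config <- function(...) {
  cfg <- list(
    agents = list(A = list(m = 2, Dm = 10), B = list(m = 1, Dm = 5)),
    dose_grid = c(1 / 8, 1 / 4, 1 / 2, 1, 2, 4),
    combo_grid = c(1 / 2, 1, 2),
    interaction = 0.67,
    sigma = 0.05
  )
  utils::modifyList(cfg, list(...))
}

#' Generate synthetic dose-response and combination tables with truth
#'
#' Single-agent curves follow the median-effect equation with Gaussian
#' noise on log10(fa/fu). Combination effects are generated under Loewe
#' additivity with the required doses scaled by the interaction factor
#' `s`: the combined fa solves d1/Dx1(fa) + d2/Dx2(fa) = s, so a
#' noiseless analysis recovers CI = s at every combination point
#' (s = 1 additive, s < 1 synergistic).
#'
#' @param config list from [synergy_config()].
#' @param seed integer RNG seed.
#' @return list with `single` (data.frame `agent`, `dose`, `fa`),
#'   `combos` (data.frame `d1`, `d2`, `fa`) and `truth`.
#' @export
generate_dose_response <- function(config = synergy_config(), seed = 1) {
  c_ <- config
  for (a in c_$agents) {
    if (a$m <= 0 || a$Dm <= 0) {
      stop("agent m and Dm must be positive", call. = FALSE)
    }
  }
  if (c_$interaction <= 0) stop("interaction factor must be positive",
                                call. = FALSE)
  set.seed(seed)
  noisy_fa <- function(t) {
    t <- t + stats::rnorm(length(t), 0, c_$sigma)
    10^t / (1 + 10^t)
  }
  single <- do.call(rbind, lapply(names(c_$agents), function(nm) {
    a <- c_$agents[[nm]]
    d <- a$Dm * c_$dose_grid
    t <- a$m * (log10(d) - log10(a$Dm))
    data.frame(agent = nm, dose = d, fa = noisy_fa(t),
               stringsAsFactors = FALSE)
  }))
  a1 <- c_$agents[[1]]; a2 <- c_$agents[[2]]
  dx <- function(agent, fa) agent$Dm * (fa / (1 - fa))^(1 / agent$m)
  combos <- expand.grid(d1 = a1$Dm * c_$combo_grid,
                        d2 = a2$Dm * c_$combo_grid)
  fa <- vapply(seq_len(nrow(combos)), function(i) {
    d1 <- combos$d1[i]; d2 <- combos$d2[i]
    g <- function(t) {
      f <- 10^t / (1 + 10^t)
      d1 / dx(a1, f) + d2 / dx(a2, f) - c_$interaction
    }
    t <- stats::uniroot(g, c(-12, 12), tol = 1e-12)$root
    t
  }, numeric(1))
  combos$fa <- noisy_fa(fa)
  truth <- list(config = c_, seed = seed,
                agents = c_$agents, interaction = c_$interaction)
  list(single = single, combos = combos, truth = truth)
}
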