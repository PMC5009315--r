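test_that("reference signature is the direction-concordant intersection", {
  a <- gene_set(c("VIL1", "MUC2", "TP63", "CDX1"),
                c("up", "up", "down", "up"))
  b <- gene_set(c("VIL1", "MUC2", "TP63", "KRT5"),
                c("up", "down", "down", "down"))
  sig <- derive_reference_signature(a, b)
  expect_setequal(sig$entries$gene, c("VIL1", "TP63"))  # MUC2 discordant
  expect_equal(unname(gene_directions(sig)["TP63"]), "down")
  empty <- derive_reference_signature(gene_set("A", "up"),
                                      gene_set("B", "up"))
  expect_equal(n_genes(empty), 0)
})

test_that("meta-profile rules behave as strict and majority intersections", {
  s1 <- gene_set(c("A", "B", "C"), c("up", "up", "down"))
  s2 <- gene_set(c("A", "B", "D"), c("up", "down", "down"))
  s3 <- gene_set(c("A", "B", "C"), c("up", "up", "down"))
  mp_all <- build_meta_profile(list(s1, s2, s3))
  expect_equal(as_gene_set(mp_all)$entries$gene, "A")  # B discordant
  mp_maj <- build_meta_profile(list(s1, s2, s3),
                               rule = "majority_concordant")
  # C is down in 2/3 and never opposite; B appears with both directions
  expect_setequal(as_gene_set(mp_maj)$entries$gene, c("A", "C"))
  expect_error(build_meta_profile(list()), "non-empty")
  expect_error(build_meta_profile(list(s1)), "at least 2")
})

test_that("all_concordant profile is contained in majority_concordant", {
  set.seed(17)
  pool <- sprintf("G%02d", 1:30)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) {
      g <- sample(pool, sample(10:20, 1))
      gene_set(g, sample(c("up", "down"), length(g), replace = TRUE))
    })
    g_all <- as_gene_set(build_meta_profile(sets))$entries$gene
    g_maj <- as_gene_set(build_meta_profile(sets,
                                            "majority_concordant"))$entries$gene
    expect_true(all(g_all %in% g_maj))
  }
})

test_that("decomposition replays printed counts and keeps the partition", {
  cnt <- sets_with_counts(n_disease = 989, n_like = 768,
                          reference_extra = 2861 - 768)
  dec <- decompose_signature(cnt$disease, cnt$reference)
  expect_equal(n_genes(dec$reference_like), 768)
  expect_equal(n_genes(dec$non_reference), 221)
  expect_equal(dec$fraction_reference_like, 77.7)
  expect_equal(dec$n_reference, 2861)

  # disjoint and subset extremes
  dis <- gene_set(c("X1", "X2"), c("up", "down"))
  ref <- gene_set(c("Y1", "Y2"), c("up", "down"))
  d0 <- decompose_signature(dis, ref)
  expect_equal(d0$fraction_reference_like, 0)
  expect_equal(d0$non_reference$entries, dis$entries)
  d100 <- decompose_signature(dis, dis)
  expect_equal(d100$fraction_reference_like, 100)
  expect_error(decompose_signature(gene_set(), ref), "empty")
})

test_that("direction matching is enforced unless relaxed", {
  dis <- gene_set(c("A", "B"), c("up", "down"))
  ref <- gene_set(c("A", "B"), c("up", "up"))
  strict <- decompose_signature(dis, ref)
  expect_equal(strict$reference_like$entries$gene, "A")
  loose <- decompose_signature(dis, ref, require_direction_match = FALSE)
  expect_setequal(loose$reference_like$entries$gene, c("A", "B"))
})

test_that("decomposition partition and monotonicity hold on random sets", {
  set.seed(23)
  pool <- sprintf("G%03d", 1:200)
  for (i in 1:15) {
    dg <- sample(pool, 80)
    dis <- gene_set(dg, sample(c("up", "down"), 80, replace = TRUE))
    rg <- sample(pool, 60)
    ref <- gene_set(rg, sample(c("up", "down"), 60, replace = TRUE))
    dec <- decompose_signature(dis, ref)
    expect_equal(n_genes(dec$reference_like) + n_genes(dec$non_reference),
                 n_genes(dis))
    # growing the reference by the disease genes it misses can only help
    add <- dec$non_reference$entries
    add <- add[!add$gene %in% ref$entries$gene, , drop = FALSE]
    ref_plus <- gene_set(c(ref$entries$gene, add$gene),
                         c(ref$entries$direction, add$direction))
    dec_plus <- decompose_signature(dis, ref_plus)
    expect_gte(dec_plus$fraction_reference_like,
               dec$fraction_reference_like)
  }
})

test_that("maintenance analysis replays printed counts with chi-square", {
  cnt <- sets_with_counts(n_disease = 989, n_like = 769)
  dec <- decompose_signature(cnt$disease, cnt$reference)
  like <- dec$reference_like$entries
  non <- dec$non_reference$entries
  later <- gene_set(c(like$gene[1:652], non$gene[1:45]),
                    c(like$direction[1:652], non$direction[1:45]))
  m <- maintenance_analysis(dec, later)
  expect_equal(unname(m$table["reference_like", ]), c(652, 117))
  expect_equal(unname(m$table["non_reference", ]), c(45, 175))
  expect_equal(unname(m$fractions["reference_like"]), 84.8)
  expect_equal(round_half_away(m$fractions["reference_like"], 0),
               c(reference_like = 85))
  expect_lt(m$p, 1e-4)
  expect_equal(m$chi2, chisq_closed_form(m$table), tolerance = 1e-9)
})

test_that("maintenance extremes: full retention and closed-form chi2", {
  dis <- gene_set(sprintf("A%02d", 1:20),
                  rep(c("up", "down"), 10))
  ref <- gene_set(dis$entries$gene[1:10], dis$entries$direction[1:10])
  dec <- decompose_signature(dis, ref)
  m_all <- maintenance_analysis(dec, dis)  # later stage contains all
  expect_equal(unname(m_all$fractions), c(100, 100))
  expect_equal(m_all$chi2, 0)

  # [[10,0],[0,10]] has chi2 = 20 by the closed form
  expect_equal(chisq_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))$chi2,
               20)
  # zero row margin leaves it undefined
  expect_true(is.na(chisq_2x2(matrix(c(0, 0, 3, 4), 2,
                                     byrow = TRUE))$chi2))
})

test_that("2x2 chi-square equals the closed form on random tables", {
  set.seed(29)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    res <- chisq_2x2(tab)
    expect_equal(res$chi2, chisq_closed_form(tab), tolerance = 1e-9)
    expect_equal(res$p, pchisq(res$chi2, 1, lower.tail = FALSE))
  }
})

test_that("specificity fraction is the concordant coverage percentage", {
  prof_genes <- sprintf("P%03d", 1:100)
  dirs <- rep(c("up", "down"), 50)
  prof <- gene_set(prof_genes, dirs)
  sig <- gene_set(prof_genes[1:13], dirs[1:13])
  res <- specificity_fraction(sig, prof)
  expect_equal(res$fraction, 13)
  expect_equal(res$n_in, 13)
  expect_equal(specificity_fraction(prof, prof)$fraction, 100)
  expect_equal(specificity_fraction(gene_set(), prof)$fraction, 0)
  # chi-square against a comparator split matches the closed form
  cmp <- specificity_fraction(sig, prof, comparator = c(769, 220))
  tab <- matrix(c(13, 87, 769, 220), 2, byrow = TRUE)
  expect_equal(cmp$chi2, chisq_closed_form(tab), tolerance = 1e-9)
})

test_that("percent rounding goes half away from zero", {
  expect_equal(round_half_away(77.65, 1), 77.7)
  expect_equal(round_half_away(84.75, 1), 84.8)
  expect_equal(round_half_away(-0.05, 1), -0.1)
  expect_equal(round_half_away(26.85, 1), 26.9)
})
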