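# handcrafted Ct table builder
ct_rows <- function(sample_id, group, gene, cts) {
  data.frame(sample_id = sample_id, group = group, gene = gene,
             replicate = seq_along(cts), Ct = cts,
             stringsAsFactors = FALSE)
}

test_that("flat Ct tables give fold change 1 everywhere", {
  rows <- do.call(rbind, lapply(c("c1", "c2", "t1", "t2"), function(s) {
    g <- if (startsWith(s, "c")) "ctrl" else "trt"
    rbind(ct_rows(s, g, "TGT", c(25, 25, 25)),
          ct_rows(s, g, "GAPDH", c(18, 18, 18)))
  }))
  dd <- delta_delta_ct(ct_table(rows), "TGT", "GAPDH", "ctrl")
  expect_equal(dd$samples$fold_change, rep(1, 4))
  expect_equal(dd$groups$fold_change, c(1, 1))
})

test_that("a -2 cycle target shift gives fold change 4", {
  rows <- do.call(rbind, lapply(1:2, function(i) {
    rbind(ct_rows(paste0("c", i), "ctrl", "TGT", c(25, 25)),
          ct_rows(paste0("c", i), "ctrl", "GAPDH", c(18, 18)),
          ct_rows(paste0("t", i), "trt", "TGT", c(23, 23)),
          ct_rows(paste0("t", i), "trt", "GAPDH", c(18, 18)))
  }))
  dd <- delta_delta_ct(ct_table(rows), "TGT", "GAPDH", "ctrl")
  trt <- dd$samples[dd$samples$group == "trt", ]
  expect_equal(trt$fold_change, c(4, 4))
  expect_equal(dd$groups$fold_change[dd$groups$group == "trt"], 4)
})

test_that("technical replicates are averaged before the deltas", {
  rows <- rbind(ct_rows("c1", "ctrl", "TGT", c(20, 21, 22)),
                ct_rows("c1", "ctrl", "GAPDH", c(18, 18, 18)),
                ct_rows("t1", "trt", "TGT", c(19, 20, 21)),
                ct_rows("t1", "trt", "GAPDH", c(18, 18, 18)))
  dd <- delta_delta_ct(ct_table(rows), "TGT", "GAPDH", "ctrl")
  expect_equal(dd$samples$delta_ct[dd$samples$sample_id == "c1"], 3)  # 21-18
  expect_equal(dd$samples$fold_change[dd$samples$sample_id == "t1"], 2)
})

test_that("per-sample constant Ct offsets cancel in the fold change", {
  rows <- rbind(ct_rows("c1", "ctrl", "TGT", c(25, 25)),
                ct_rows("c1", "ctrl", "GAPDH", c(18, 18)),
                ct_rows("c2", "ctrl", "TGT", c(25, 25) + 1.7),
                ct_rows("c2", "ctrl", "GAPDH", c(18, 18) + 1.7))
  dd <- delta_delta_ct(ct_table(rows), "TGT", "GAPDH", "ctrl")
  expect_equal(dd$samples$fold_change, c(1, 1))
})

test_that("a sample without the reference gene is rejected by name", {
  rows <- rbind(ct_rows("c1", "ctrl", "TGT", c(25, 25)),
                ct_rows("c1", "ctrl", "GAPDH", c(18, 18)),
                ct_rows("c2", "ctrl", "TGT", c(25, 25)))
  expect_error(delta_delta_ct(ct_table(rows), "TGT", "GAPDH", "ctrl"),
               "c2")
})

test_that("non-detects are clamped and flagged, and droppable", {
  rows <- rbind(ct_rows("c1", "ctrl", "TGT", c(30, 30)),
                ct_rows("c1", "ctrl", "GAPDH", c(18, 18)),
                ct_rows("t1", "trt", "TGT", c(45, 45)),  # undetected
                ct_rows("t1", "trt", "GAPDH", c(18, 18)),
                ct_rows("t2", "trt", "TGT", c(30, 30)),
                ct_rows("t2", "trt", "GAPDH", c(18, 18)))
  tab <- ct_table(rows, non_detect_ceiling = 40)
  dd <- delta_delta_ct(tab, "TGT", "GAPDH", "ctrl")
  t1 <- dd$samples[dd$samples$sample_id == "t1", ]
  expect_true(t1$non_detect)
  expect_equal(t1$delta_ct, 40 - 18)  # clamped at the ceiling
  dropped <- delta_delta_ct(tab, "TGT", "GAPDH", "ctrl",
                            non_detect = "drop")
  expect_equal(dropped$groups$fold_change[dropped$groups$group == "trt"],
               1)  # only t2 remains, identical to control
})

test_that("ct_table enforces its invariants", {
  bad <- ct_rows("c1", "ctrl", "TGT", c(25, 25))
  bad$replicate <- c(1, 1)
  expect_error(ct_table(bad), "unique")
  neg <- ct_rows("c1", "ctrl", "TGT", c(-1, 25))
  expect_error(ct_table(neg), "positive")
})

test_that("group test is rank-based on relative quantities", {
  g <- generate_ct_table(ct_config(n_per_group = 6), seed = 5)
  p <- expression_group_test(g$table, "NR5A2", "GAPDH",
                             "control", "treated")
  # compare against a direct Mann-Whitney on -dCt (monotone transform)
  recs <- g$table$records
  mean_ct <- function(gene) {
    v <- tapply(recs$Ct[recs$gene == gene],
                recs$sample_id[recs$gene == gene], mean)
    v
  }
  dct <- mean_ct("NR5A2") - mean_ct("GAPDH")[names(mean_ct("NR5A2"))]
  grp <- tapply(recs$group, recs$sample_id, `[`, 1)[names(dct)]
  p2 <- mann_whitney_test(-dct[grp == "control"],
                          -dct[grp == "treated"])$p
  expect_equal(p, p2)

  flat <- generate_ct_table(
    ct_config(n_per_group = 4, replicate_sigma = 0,
              targets = list(NR5A2 = list(base_ct = 26,
                                          shift = c(control = 0,
                                                    treated = 0)))),
    seed = 1)
  expect_equal(expression_group_test(flat$table, "NR5A2", "GAPDH",
                                     "control", "treated"), 1)
})

test_that("a 3-cycle shift at n=17 is detected in nearly all replicates", {
  hits <- vapply(1:100, function(s) {
    g <- generate_ct_table(ct_config(), seed = s)
    expression_group_test(g$table, "NR5A2", "GAPDH",
                          "control", "treated") < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("ct generator is deterministic and round-trips through TSV", {
  g1 <- generate_ct_table(seed = 11)
  g2 <- generate_ct_table(seed = 11)
  expect_identical(g1$table$records, g2$table$records)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(g1$table, path)
  back <- read_ct_table(path)
  expect_equal(back$records$Ct, g1$table$records$Ct, tolerance = 1e-12)
  expect_error(generate_ct_table(ct_config(n_per_group = 1)), "at least 2")
})
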