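exact_curve <- function(m, Dm, doses) {
  ratio <- (doses / Dm)^m
  ratio / (1 + ratio)
}

test_that("viability signals convert to clipped fraction affected", {
  v <- viability_to_fa(c(1, 0.25, 1.2), c(1, 1, 1))
  expect_equal(v$fa[2], 0.75)
  expect_equal(v$fa[1], 1e-4)   # treated == control clips to epsilon
  expect_equal(v$fa[3], 1e-4)   # negative effect clips too
  expect_equal(v$clipped, c(TRUE, FALSE, TRUE))
  expect_error(viability_to_fa(1, 0), "positive")
})

test_that("median-effect fit recovers a noiseless generating line", {
  doses <- c(1, 3, 10, 30, 100)
  fit <- median_effect_fit(doses, exact_curve(2, 10, doses))
  expect_equal(fit$m, 2, tolerance = 1e-9)
  expect_equal(fit$Dm, 10, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_false(fit$flagged)

  # two points determine the line exactly
  fit2 <- median_effect_fit(c(2, 8), exact_curve(1.3, 4, c(2, 8)))
  expect_equal(fit2$m, 1.3, tolerance = 1e-9)
  expect_equal(fit2$Dm, 4, tolerance = 1e-9)

  expect_error(median_effect_fit(c(5, 5), c(0.2, 0.6)), "distinct")
  down <- median_effect_fit(c(1, 10), c(0.8, 0.2))
  expect_true(down$flagged)
})

test_that("noisy curves recover the slope within 5% median error", {
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    doses <- 10 * 2^seq(-2.5, 2.5, length.out = 6)
    t <- 2 * (log10(doses) - 1) + rnorm(6, 0, 0.05)
    fa <- 10^t / (1 + 10^t)
    abs(median_effect_fit(doses, fa)$m - 2) / 2
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("dose_for_effect inverts the median-effect equation", {
  fit <- median_effect_fit(c(1, 3, 10), exact_curve(2, 10, c(1, 3, 10)))
  expect_equal(dose_for_effect(fit, 0.5), fit$Dm, tolerance = 1e-9)
  fit1 <- list(m = 1, Dm = 1)
  expect_equal(dose_for_effect(fit1, 0.75), 3, tolerance = 1e-12)
  for (fa in c(0.1, 0.37, 0.9)) {
    expect_equal(effect_at_dose(fit, dose_for_effect(fit, fa)), fa,
                 tolerance = 1e-9)
  }
  expect_error(dose_for_effect(fit, 1), "between 0 and 1")
})

test_that("an agent combined with itself is exactly additive", {
  doses <- c(1, 3, 10, 30)
  fit <- median_effect_fit(doses, exact_curve(1.7, 6, doses))
  d1 <- 2; d2 <- 5
  fa <- effect_at_dose(fit, d1 + d2)
  res <- combination_index(fit, fit, d1, d2, fa)
  expect_equal(res$CI, 1, tolerance = 1e-9)
  expect_equal(res$classification, "additive")
})

test_that("combination index matches hand computation and degenerates", {
  fit1 <- list(m = 1, Dm = 1)
  res <- combination_index(fit1, fit1, 1, 1, 0.5)
  expect_equal(res$Dx1, 1); expect_equal(res$Dx2, 1)
  expect_equal(res$CI, 2)
  expect_equal(res$classification, "antagonism")

  solo <- combination_index(fit1, fit1, d1 = 3, d2 = 0, fa_combo = 0.75)
  expect_equal(solo$CI, 3 / dose_for_effect(fit1, 0.75))
  expect_error(combination_index(fit1, fit1, 0, 0, 0.5), "not both zero")
  expect_error(combination_index(fit1, fit1, 1, 1, 1.2), "between 0 and 1")
})

test_that("CI is invariant to a consistent rescaling of one agent's units", {
  doses_a <- c(1, 3, 10, 30); doses_b <- c(0.5, 2, 8)
  fa_a <- exact_curve(2, 10, doses_a); fa_b <- exact_curve(1, 5, doses_b)
  fit_a <- median_effect_fit(doses_a, fa_a)
  fit_b <- median_effect_fit(doses_b, fa_b)
  ci <- combination_index(fit_a, fit_b, 4, 3, 0.6)$CI
  # express agent A in different units (x 1000)
  fit_a2 <- median_effect_fit(doses_a * 1000, fa_a)
  ci2 <- combination_index(fit_a2, fit_b, 4000, 3, 0.6)$CI
  expect_equal(ci2, ci, tolerance = 1e-9)
})

test_that("isobologram coordinates follow the additivity algebra", {
  doses <- c(1, 3, 10, 30)
  fit <- median_effect_fit(doses, exact_curve(2, 8, doses))
  iso <- isobologram(fit, fit, fa_levels = c(0.5, 0.75))
  expect_equal(iso$lines$Dx1, iso$lines$Dx2)          # symmetric fits
  expect_equal(iso$lines$Dx1[1], fit$Dm, tolerance = 1e-9)  # fa = 0.5

  # synergistic combination points fall below the additivity line
  gen <- generate_dose_response(synergy_config(sigma = 0,
                                               interaction = 0.5),
                                seed = 3)
  fits <- lapply(split(gen$single, gen$single$agent),
                 function(d) median_effect_fit(d$dose, d$fa))
  iso2 <- isobologram(fits$A, fits$B, combos = gen$combos)
  expect_true(all(iso2$points$norm1 + iso2$points$norm2 < 1))
})

test_that("generated Loewe data recovers the interaction factor", {
  for (s in c(1, 0.5)) {
    gen <- generate_dose_response(synergy_config(sigma = 0,
                                                 interaction = s),
                                  seed = 7)
    fits <- lapply(split(gen$single, gen$single$agent),
                   function(d) median_effect_fit(d$dose, d$fa))
    ci <- combination_index_table(fits$A, fits$B, gen$combos)
    expect_equal(ci$CI, rep(s, nrow(ci)), tolerance = 1e-9)
  }
  g1 <- generate_dose_response(seed = 4)
  g2 <- generate_dose_response(seed = 4)
  expect_identical(g1, g2)
  expect_error(generate_dose_response(
    synergy_config(agents = list(A = list(m = -1, Dm = 1),
                                 B = list(m = 1, Dm = 1)))),
    "positive")
})
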