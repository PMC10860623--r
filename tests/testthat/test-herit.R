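test_that("phenotype preparation applies the sign convention", {
  neg <- c(a = -23.1, b = -22.9, c = -23.4, d = -22.7)
  pp <- prepare_phenotype(neg)
  expect_equal(pp$transform, "sign_flip")
  expect_equal(unname(pp$values), -unname(neg))
  pos <- c(a = 1.1, b = 0.9, c = 1.0, d = 1.2)
  pp2 <- prepare_phenotype(pos)
  expect_equal(pp2$transform, "none")
  expect_equal(pp2$values, pos)
  expect_warning(prepare_phenotype(c(-2, -1, 1, 2)), "minimum shift")
  expect_error(prepare_phenotype(c(1, 2, NA, NA)), "4 non-missing")
})

test_that("Blom scores match the closed form at n = 5", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(blom_scores(x)[order(x)],
               qnorm(((1:5) - 3 / 8) / (5 + 1 / 4)))
  pp <- prepare_phenotype(x, inverse_normal = TRUE)
  expect_equal(sort(pp$values), sort(blom_scores(x)))
  expect_true("inverse_normal" %in% pp$transform)
})

test_that("heritability estimate is invariant to affine transforms", {
  ped <- make_pedigree(rep(2L, 300L))
  y <- simulate_phenotype(ped, 0.7, seed = 5)
  h0 <- fit_variance_components(y, ped)$h2
  expect_equal(fit_variance_components(10 + 3 * y, ped)$h2, h0,
               tolerance = 1e-6)
  expect_equal(fit_variance_components(-y, ped)$h2, h0, tolerance = 1e-6)
  expect_gte(h0, 0)
  expect_lte(h0, 1)
})

test_that("likelihood fit matches the dense-matrix grid oracle", {
  for (s in 1:4) {
    ped <- make_pedigree(c(2L, 2L, 3L, 2L, 3L))  # 12 subjects
    y <- simulate_phenotype(ped, c(0.2, 0.5, 0.8, 1.0)[s], seed = 100 + s)
    fit <- fit_variance_components(y, ped)
    oracle <- oracle_h2_grid(unname(y), ped$family_id)
    expect_lt(abs(fit$h2 - oracle), 1e-3)
  }
})

test_that("likelihood fit agrees with the moment estimator on balanced data", {
  ped <- make_pedigree(rep(2L, 2000L))
  y <- simulate_phenotype(ped, 0.6, seed = 77)
  ml <- fit_variance_components(y, ped)$h2
  mom <- sib_icc_h2(y, ped)
  expect_lt(abs(ml - mom), 0.05)
})

test_that("null phenotypes give near-zero heritability", {
  ped <- make_pedigree()
  h2s <- vapply(1:100, function(s) {
    fit_variance_components(simulate_phenotype(ped, 0, seed = 3000 + s),
                            ped)$h2
  }, numeric(1))
  expect_lt(median(h2s), 0.1)
  expect_lt(mean(h2s), 0.15)
})

test_that("degenerate and missing inputs are handled", {
  ped <- make_pedigree(rep(2L, 10L))
  const <- setNames(rep(1, 20), ped$subject_id)
  fit <- fit_variance_components(const, ped)
  expect_true(fit$degenerate)
  y <- simulate_phenotype(ped, 0.5, seed = 2)
  y[c(1, 5)] <- NA
  fit2 <- fit_variance_components(y, ped)
  expect_equal(fit2$n, 18)
})

test_that("REML and ML agree at large family counts", {
  ped <- make_pedigree(rep(2L, 1500L))
  y <- simulate_phenotype(ped, 0.8, seed = 9)
  ml <- fit_variance_components(y, ped, reml = FALSE)$h2
  reml <- fit_variance_components(y, ped, reml = TRUE)$h2
  expect_lt(abs(ml - reml), 0.03)
})

test_that("permutation p-values follow the counting rule", {
  expect_equal(perm_pvalue(21, 6000), 0.0035)
  expect_equal(perm_pvalue(389, 6000), 389 / 6000)
  expect_equal(perm_pvalue(6000, 6000), 1)
  expect_error(perm_pvalue(-1, 100))
  expect_error(perm_pvalue(101, 100))
})

test_that("permutation test is seed-reproducible and detects strong signal", {
  ped <- make_pedigree()
  y <- simulate_phenotype(ped, 0.9, seed = 4)
  a <- permutation_test(y, ped, n_perm = 300L, seed = 10)
  b <- permutation_test(y, ped, n_perm = 300L, seed = 10)
  expect_identical(a$k, b$k)
  expect_identical(a$p, b$p)
  expect_lt(a$p, 0.05)
  expect_equal(a$p, a$k / a$n_perm)
})

test_that("a boundary-zero estimate yields k = n_perm and p = 1", {
  # every permuted estimate is >= 0 = observed, ties counted
  ped <- make_pedigree(rep(2L, 60L))
  y <- simulate_phenotype(ped, 0, seed = 12345)
  fit <- fit_variance_components(y, ped)
  skip_seed <- 1L
  while (fit$h2 > 0) {  # find a null draw landing on the boundary
    skip_seed <- skip_seed + 1L
    y <- simulate_phenotype(ped, 0, seed = 12345 + skip_seed)
    fit <- fit_variance_components(y, ped)
  }
  pt <- permutation_test(y, ped, n_perm = 200L, seed = 6)
  expect_equal(pt$h2_observed, 0)
  expect_equal(pt$k, 200L)
  expect_equal(pt$p, 1)
})

test_that("Bonferroni adjustment over the battery uses the test count", {
  adj <- bonferroni(c(0.0005, 0.0035, 0.002), n_tests = 30L)
  expect_equal(adj$adjusted, c(0.015, 0.105, 0.06))
  expect_equal(adj$significant, c(TRUE, FALSE, FALSE))  # alpha / 30 = 0.00167
  expect_equal(bonferroni(0.5, n_tests = 30L)$adjusted, 1)  # capped at 1
})

test_that("Cohen's d is mean over SD and rejects degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(cohens_d(x), mean(x) / sd(x))
  expect_error(cohens_d(rep(2, 10)), "zero standard deviation")
  expect_error(cohens_d(c(1, NA)), "at least 2")
})

test_that("battery runs every phenotype with per-phenotype seeds", {
  fx <- make_fixtures()
  res <- run_heritability_battery(fx$phenotypes, fx$ped, n_perm = 50L,
                                  seed = 3L, n_tests = 2L)
  expect_equal(res$phenotype, c("pheno_a", "pheno_b"))
  expect_true(all(c("h2", "k", "p", "p_bonferroni", "significant",
                    "cohens_d", "n_used") %in% names(res)))
  expect_true(all(res$h2 >= 0 & res$h2 <= 1))
  expect_true(all(res$p >= res$k / 50 - 1e-12))
  # rerun is identical (derived seeds)
  res2 <- run_heritability_battery(fx$phenotypes, fx$ped, n_perm = 50L,
                                   seed = 3L, n_tests = 2L)
  expect_identical(res, res2)
  expect_error(run_heritability_battery(fx$phenotypes, fx$ped,
                                        phenotypes = "missing_col"),
               "missing_col")
})

test_that("the battery phenotype catalogue covers both hemispheres", {
  expect_equal(length(beta_phenotype_names()), 15)
  nm <- battery_phenotype_names()
  expect_equal(length(nm), 30)
  expect_equal(sum(startsWith(nm, "lh_")), 15)
  expect_equal(sum(startsWith(nm, "rh_")), 15)
  expect_true(all(c("rh_aperiodic_exponent", "lh_event_rate",
                    "rh_dispersion") %in% nm))
})
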