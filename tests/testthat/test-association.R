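test_that("allelic test reproduces textbook 2x2 arithmetic", {
  # equal frequencies: null identity
  null <- allelic_test(allele_counts(10, 90), allele_counts(20, 180))
  expect_equal(null$or, 1)
  expect_equal(null$p, 1)

  # cross-product odds ratio
  res <- allelic_test(allele_counts(10, 90), allele_counts(20, 80))
  expect_equal(res$or, (10 * 80) / (90 * 20))
  expect_equal(res$chi2, chi2_oracle_2x2(10, 90, 20, 80))
  expect_equal(res$df, 1L)

  # Woolf interval
  expect_equal(res$ci95,
               exp(log(res$or) + c(-1, 1) * 1.959964 *
                     sqrt(1 / 10 + 1 / 90 + 1 / 20 + 1 / 80)))
})

test_that("zero cells trigger the Haldane correction, empty margins flag", {
  res <- allelic_test(allele_counts(0, 100), allele_counts(10, 90))
  expect_match(res$note, "Haldane")
  expect_equal(res$or, (0.5 * 90.5) / (100.5 * 10.5))
  bad <- allelic_test(allele_counts(0, 0), allele_counts(10, 90))
  expect_true(is.na(bad$p))
  expect_match(bad$note, "degenerate")
})

test_that("genotype collapse matches the dominant/recessive definitions", {
  case <- genotype_counts(c(66, 271, 179))
  ctrl <- genotype_counts(c(47, 118, 67))
  rec <- genotypic_test(case, ctrl, "recessive")
  expect_equal(rec$or, (66 * (118 + 67)) / ((271 + 179) * 47))
  dom <- genotypic_test(case, ctrl, "dominant")
  expect_equal(dom$or, ((66 + 271) * 67) / (179 * (47 + 118)))

  # without heterozygotes the two collapses coincide
  c2 <- genotype_counts(c(30, 0, 70)); n2 <- genotype_counts(c(10, 0, 90))
  expect_equal(genotypic_test(c2, n2, "dominant")$or,
               genotypic_test(c2, n2, "recessive")$or)

  # zero homozygous-minor everywhere: Haldane-corrected OR, flagged, no test
  z <- genotypic_test(genotype_counts(c(0, 50, 50)),
                      genotype_counts(c(0, 40, 60)), "recessive")
  expect_match(z$note, "Haldane")
  expect_equal(z$or, (0.5 * 100.5) / (100.5 * 0.5))
  expect_true(is.na(z$p))
})

test_that("label swaps invert the odds ratio and preserve the p-value", {
  set.seed(12)
  for (i in 1:20) {
    a <- allele_counts(rpois(1, 40) + 1, rpois(1, 60) + 1)
    b <- allele_counts(rpois(1, 40) + 1, rpois(1, 60) + 1)
    ab <- allelic_test(a, b)
    ba <- allelic_test(b, a)
    expect_equal(ba$or, 1 / ab$or)
    expect_equal(ba$chi2, ab$chi2)
    expect_equal(ba$p, ab$p)
    # allele-label swap likewise
    sw <- allelic_test(allele_counts(a$allele_count_major,
                                     a$allele_count_minor),
                       allele_counts(b$allele_count_major,
                                     b$allele_count_minor))
    expect_equal(sw$or, 1 / ab$or)
    expect_equal(sw$p, ab$p)
  }
})

test_that("best model selection minimises p with fixed tie precedence", {
  mk <- function(model, p) structure(list(model = model, p = p),
                                     class = "assoc_result")
  expect_equal(best_model(list(mk("allelic", 0.04)))$model, "allelic")
  expect_equal(best_model(list(mk("allelic", 0.04),
                               mk("recessive", 0.003)))$model, "recessive")
  expect_equal(best_model(list(mk("recessive", 0.01),
                               mk("dominant", 0.01),
                               mk("allelic", 0.01)))$model, "allelic")
  expect_equal(best_model(list(mk("recessive", 0.01),
                               mk("dominant", 0.01)))$model, "dominant")
})

test_that("multi-group heterogeneity test matches Pearson arithmetic", {
  g1 <- allele_counts(30, 70); g2 <- allele_counts(30, 70)
  g3 <- allele_counts(30, 70)
  expect_equal(multigroup_allele_test(list(g1, g2, g3))$p, 1)

  # two groups reduce to the allelic test
  a <- allele_counts(25, 75); b <- allele_counts(40, 60)
  two <- multigroup_allele_test(list(a, b))
  expect_equal(two$chi2, allelic_test(a, b)$chi2)
  expect_equal(two$df, 1L)

  # hand-computed Pearson chi2 on a 3x2 table with one divergent group
  tab <- rbind(c(30, 70), c(30, 70), c(50, 50))
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2_hand <- sum((tab - exp_tab)^2 / exp_tab)
  three <- multigroup_allele_test(list(allele_counts(30, 70),
                                       allele_counts(30, 70),
                                       allele_counts(50, 50)))
  expect_equal(three$chi2, chi2_hand)
  expect_equal(three$df, 2L)
})

test_that("analytic power is exact at the null and monotone in design", {
  expect_equal(allelic_power(500, 500, 0.4, 1, alpha = 0.05), 0.05,
               tolerance = 1e-12)
  base <- allelic_power(300, 300, 0.4, 1.5, 0.001)
  expect_gt(allelic_power(600, 300, 0.4, 1.5, 0.001), base)
  expect_gt(allelic_power(300, 300, 0.4, 1.8, 0.001), base)
  expect_gt(allelic_power(300, 300, 0.4, 1 / 1.5, 0.001), 0)
  expect_gt(allelic_power(300, 300, 0.4, 1.5, 0.01), base)
  # protective and risk odds ratios of equal magnitude: |ln psi| symmetry
  expect_gt(allelic_power(300, 300, 0.4, 1.5, 0.001),
            allelic_power(300, 300, 0.4, 1.2, 0.001))
})
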