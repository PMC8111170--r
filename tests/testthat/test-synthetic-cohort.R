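test_that("haplotype pools hit their target frequencies and LD regime", {
  panel <- data.frame(maf = c(0.4, 0.3), block = c(1, 1))
  pool <- simulate_haplotype_pool(panel, 200000, within_block_rho = 0,
                                  seed = 11)
  freq <- colMeans(pool$haplotypes)
  expect_lt(abs(freq[1] - 0.4), 0.005)
  expect_lt(abs(freq[2] - 0.3), 0.005)
  r2 <- cor(pool$haplotypes[, 1], pool$haplotypes[, 2])^2
  expect_lt(r2, 0.001)

  tight <- simulate_haplotype_pool(data.frame(maf = c(0.5, 0.5),
                                              block = c(1, 1)),
                                   200000, within_block_rho = 0.99,
                                   seed = 12)
  r2t <- cor(tight$haplotypes[, 1], tight$haplotypes[, 2])^2
  # numeric-integration oracle for the latent threshold model: at maf 0.5
  # the binary correlation is 2/pi * asin(rho) = 0.9097, so r2 = 0.8276
  expect_lt(abs(r2t - threshold_model_r2(0.99, 0.5, 0.5)), 0.01)
  expect_gt(r2t, 0.8)

  expect_error(simulate_haplotype_pool(panel, 100, within_block_rho = 1),
               "within_block_rho")
  expect_error(simulate_haplotype_pool(panel, 100,
                                       within_block_rho = -0.1),
               "within_block_rho")
})

test_that("blocks are mutually independent", {
  panel <- data.frame(maf = rep(0.4, 4), block = c(1, 1, 2, 2))
  pool <- simulate_haplotype_pool(panel, 100000, within_block_rho = 0.9,
                                  seed = 13)
  within <- cor(pool$haplotypes[, 1], pool$haplotypes[, 2])^2
  between <- cor(pool$haplotypes[, 2], pool$haplotypes[, 3])^2
  expect_gt(within, 0.4)
  expect_lt(between, 0.001)
})

test_that("case/control sampling respects the disease model", {
  pool <- one_marker_pool(0.4)
  # null model: case and control frequencies agree within sampling error
  null <- simulate_case_control(pool, disease_model(0.05), 4000, 4000,
                                seed = 21)
  f_case <- mean(null$genotypes[null$individuals$group == "CASE", 1]) / 2
  f_ctrl <- mean(null$genotypes[null$individuals$group == "CONTROL", 1]) / 2
  se <- sqrt(0.4 * 0.6 / 8000)
  expect_lt(abs(f_case - f_ctrl), 4 * se)

  # psi = 1.5 at maf 0.4: case allele odds 0.4/0.6 * 1.5 = 1, so the case
  # frequency approaches one half in the low-prevalence regime
  eff <- simulate_case_control(pool, disease_model(0.01, c(snp01 = 1.5)),
                               20000, 100, seed = 22)
  f_case <- mean(eff$genotypes[eff$individuals$group == "CASE", 1]) / 2
  expect_lt(abs(f_case - 0.5), 0.01)

  # determinism contract
  a <- simulate_case_control(pool, disease_model(0.05), 100, 100, seed = 7)
  b <- simulate_case_control(pool, disease_model(0.05), 100, 100, seed = 7)
  expect_identical(a, b)
})

test_that("simulated trios are Mendel-consistent and distort transmission
          only under association with ascertainment", {
  pool <- simulate_haplotype_pool(data.frame(maf = c(0.4, 0.3),
                                             block = c(1, 2)),
                                  20000, seed = 31)
  tr <- simulate_trios(pool, disease_model(0.05), 500, seed = 32)
  for (id in tr$cohort$markers$id)
    expect_equal(mendel_error_rate(tr$trios, tr$cohort, id)$rate, 0)

  # null model, ascertained: transmitted and non-transmitted frequencies
  # agree within sampling error
  big <- simulate_trios(pool, disease_model(0.05), 20000, seed = 33)
  ps <- construct_pseudo_controls(big$trios, big$cohort)
  f_child <- mean(big$cohort$genotypes[big$trios$child, 1]) / 2
  f_pseudo <- mean(ps$genotypes[, 1]) / 2
  se <- sqrt(0.4 * 0.6 / (2 * 20000))
  expect_lt(abs(f_child - f_pseudo), 4 * se)

  # psi = 1.5, ascertained: transmitted frequency exceeds non-transmitted
  dist <- simulate_trios(pool, disease_model(0.05, c(snp01 = 1.5)),
                         20000, seed = 34)
  psd <- construct_pseudo_controls(dist$trios, dist$cohort)
  expect_gt(mean(dist$cohort$genotypes[dist$trios$child, 1]),
            mean(psd$genotypes[, 1]))

  tr2 <- simulate_trios(pool, disease_model(0.05), 50, seed = 35)
  expect_identical(tr2,
                   simulate_trios(pool, disease_model(0.05), 50, seed = 35))
})

test_that("founder genotypes are in Hardy-Weinberg equilibrium", {
  pool <- one_marker_pool(0.3)
  tr <- simulate_trios(pool, disease_model(0.05), 2000, seed = 41,
                       ascertain_affected_child = FALSE)
  founders <- c(tr$trios$father, tr$trios$mother)
  g <- tr$cohort$genotypes[founders, 1]
  p <- hwe_exact_test(c(sum(g == 2), sum(g == 1), sum(g == 0)))
  expect_gt(p, 0.001)
})

test_that("association tests achieve nominal type-I error on null cohorts", {
  pool <- one_marker_pool(0.3)
  mod <- disease_model(0.5)  # prevalence 1/2: no rejection-sampling waste
  n_rep <- 2000
  set.seed(55)
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cc <- simulate_case_control(pool, mod, 60, 60)
    g_case <- cc$genotypes[1:60, 1]
    g_ctrl <- cc$genotypes[61:120, 1]
    res <- allelic_test(
      genotype_counts(c(sum(g_case == 2), sum(g_case == 1),
                        sum(g_case == 0))),
      genotype_counts(c(sum(g_ctrl == 2), sum(g_ctrl == 1),
                        sum(g_ctrl == 0))))
    rej[r] <- !is.na(res$p) && res$p < 0.05
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 2 * se + 1e-9)
})
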