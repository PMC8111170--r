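test_that("dosage coding follows the panel minor allele and missing codes", {
  td <- withr::local_tempdir()
  ped <- file.path(td, "x.ped"); map <- file.path(td, "x.map")
  writeLines(c("11 m001 0 70405829"), map)
  # T is the minor allele (3 copies of T, 5 of G across the file)
  writeLines(c("F1 I1 0 0 1 2 T T",
               "F2 I2 0 0 1 2 G G",
               "F3 I3 0 0 1 1 T G",
               "F4 I4 0 0 1 1 G G",
               "F5 I5 0 0 1 1 0 0"), ped)
  co <- read_pedmap(ped, map)
  expect_equal(co$markers$allele_minor, "T")
  expect_equal(co$markers$allele_major, "G")
  expect_equal(unname(co$genotypes[, 1]), c(2L, 0L, 1L, 0L, NA))
  expect_equal(co$individuals$group,
               c("CASE", "CASE", "CONTROL", "CONTROL", "CONTROL"))
  # an exact allele-count tie resolves to the lexicographically smaller
  writeLines(c("F1 I1 0 0 1 2 T T", "F2 I2 0 0 1 2 G G"), ped)
  tie <- read_pedmap(ped, map)
  expect_equal(tie$markers$allele_minor, "G")
})

test_that("malformed and tri-allelic input is rejected with context", {
  td <- withr::local_tempdir()
  ped <- file.path(td, "x.ped"); map <- file.path(td, "x.map")
  writeLines("11 m001 0 500", map)
  writeLines(c("F1 I1 0 0 1 2 T T", "F2 I2 0 0 1 2 G"), ped)
  expect_error(read_pedmap(ped, map), "PED line 2")
  writeLines(c("F1 I1 0 0 1 2 T T", "F2 I2 0 0 1 2 G C"), ped)
  expect_error(read_pedmap(ped, map), "m001")
})

test_that("trios are inferred from parent-id columns", {
  td <- withr::local_tempdir()
  ped <- file.path(td, "x.ped"); map <- file.path(td, "x.map")
  writeLines("11 m001 0 500", map)
  writeLines(c("T1 dad 0 0 1 1 T G",
               "T1 mum 0 0 2 1 T T",
               "T1 kid dad mum 1 2 T T",
               "U1 solo 0 0 1 1 G G"), ped)
  co <- read_pedmap(ped, map)
  expect_equal(nrow(co$trios), 1L)
  expect_equal(co$trios$father, 1L)
  expect_equal(co$trios$mother, 2L)
  expect_equal(co$trios$child, 3L)
})

test_that("write/read round trip is the identity on random cohorts", {
  td <- withr::local_tempdir()
  for (seed in 1:5) {
    co <- rand_cohort(n = 50, m = 10, seed = seed, miss_prob = 0.05)
    ped <- file.path(td, paste0(seed, ".ped"))
    map <- file.path(td, paste0(seed, ".map"))
    write_pedmap(co, ped, map)
    back <- read_pedmap(ped, map)
    expect_equal(unname(back$genotypes), unname(co$genotypes))
    expect_equal(back$markers$allele_minor, co$markers$allele_minor)
    expect_equal(back$markers$pos, co$markers$pos)
    expect_equal(back$individuals$iid, co$individuals$iid)
  }
  # tiny hand-sized case from the same path
  co3 <- rand_cohort(n = 3, m = 2, seed = 99)
  write_pedmap(co3, file.path(td, "t.ped"), file.path(td, "t.map"))
  expect_equal(unname(read_pedmap(file.path(td, "t.ped"),
                                  file.path(td, "t.map"))$genotypes),
               unname(co3$genotypes))
})

test_that("empty cohorts and missing genotypes serialise correctly", {
  td <- withr::local_tempdir()
  co <- rand_cohort(4, 2, seed = 1)
  co$genotypes[2, 1] <- NA_integer_
  write_pedmap(co, file.path(td, "m.ped"), file.path(td, "m.map"))
  tok <- strsplit(readLines(file.path(td, "m.ped"))[2], " ")[[1]]
  expect_equal(tok[7:8], c("0", "0"))
  empty <- cohort(co$markers,
                  co$individuals[0, , drop = FALSE],
                  co$genotypes[0, , drop = FALSE])
  write_pedmap(empty, file.path(td, "e.ped"), file.path(td, "e.map"))
  expect_equal(length(readLines(file.path(td, "e.ped"))), 0L)
  expect_equal(length(readLines(file.path(td, "e.map"))), 2L)
})

test_that("genotype counts, MAF and missing rate are consistent", {
  co <- make_cohort(matrix(c(2L, 1L, 0L), 3, 1),
                    groups = rep("CONTROL", 3))
  ct <- genotype_counts(co, "m001", "CONTROL")
  expect_equal(c(ct$n_hom_minor, ct$n_het, ct$n_hom_major, ct$n_missing),
               c(1, 1, 1, 0))
  expect_equal(ct$maf, 0.5)

  all_na <- make_cohort(matrix(NA_integer_, 3, 1))
  ct2 <- genotype_counts(all_na, "m001")
  expect_false(ct2$maf_defined)
  expect_equal(ct2$missing_rate, 1)

  # published genotype row TT=47 TG=118 GG=67 gives the published MAF 0.457
  ct3 <- genotype_counts(c(47, 118, 67))
  expect_equal(ct3$allele_count_minor, 212)
  expect_equal(ct3$allele_count_major, 252)
  expect_equal(round(ct3$maf, 3), 0.457)

  expect_error(genotype_counts(co, "nope", "CONTROL"), "unknown marker")
  expect_error(genotype_counts(co, "m001", "NOPE"), "unknown group")
})

test_that("allele accounting and dosage recoding invariants hold", {
  for (seed in 1:5) {
    co <- rand_cohort(40, 6, seed = seed, miss_prob = 0.1)
    for (id in co$markers$id) {
      ct <- genotype_counts(co, id)
      n_nonmiss <- nrow(co$individuals) - ct$n_missing
      expect_equal(ct$allele_count_minor + ct$allele_count_major,
                   2 * n_nonmiss)
      # swapping minor/major maps maf -> 1 - maf and g -> 2 - g
      flipped <- genotype_counts(c(ct$n_hom_major, ct$n_het,
                                   ct$n_hom_minor, ct$n_missing))
      if (ct$maf_defined) expect_equal(flipped$maf, 1 - ct$maf)
    }
  }
})
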