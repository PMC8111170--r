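# Shared fixture builders and independent oracles.

# Random cohort with canonical allele orientation: the stored minor allele
# is the rarer one (lexicographically smaller on an exact tie), matching
# what read_pedmap infers, so PED/MAP round trips are exact.
rand_cohort <- function(n, m, seed, miss_prob = 0, groups = NULL) {
  set.seed(seed)
  g <- matrix(rbinom(n * m, 2L, runif(m, 0.15, 0.45)[rep(seq_len(m),
                                                         each = n)]),
              n, m)
  if (miss_prob > 0)
    g[runif(n * m) < miss_prob] <- NA_integer_
  al <- replicate(m, sort(sample(c("A", "C", "G", "T"), 2)))
  minor <- al[1, ]; major <- al[2, ]
  for (j in seq_len(m)) {
    cnt <- sum(g[, j], na.rm = TRUE)
    tot <- 2 * sum(!is.na(g[, j]))
    if (cnt * 2 > tot) {          # stored allele would be the common one
      g[, j] <- 2L - g[, j]
    }
    # on an exact tie the lexicographically smaller allele must be minor,
    # which sort() already guarantees
  }
  markers <- data.frame(id = sprintf("m%03d", seq_len(m)), chrom = "11",
                        pos = 1000 * seq_len(m), allele_minor = minor,
                        allele_major = major)
  if (is.null(groups))
    groups <- rep(c("CASE", "CONTROL"), length.out = n)
  ind <- data.frame(fid = sprintf("F%03d", seq_len(n)),
                    iid = sprintf("I%03d", seq_len(n)),
                    pat = "0", mat = "0", sex = 1L,
                    phenotype = ifelse(groups == "CASE", 2, 1),
                    group = groups)
  cohort(markers, ind, g)
}

# Minimal cohort from an explicit dosage matrix.
make_cohort <- function(g, groups = rep("CASE", nrow(g))) {
  g <- as.matrix(g)
  m <- ncol(g)
  markers <- data.frame(id = sprintf("m%03d", seq_len(m)), chrom = "11",
                        pos = 1000 * seq_len(m), allele_minor = "A",
                        allele_major = "G")
  ind <- data.frame(fid = sprintf("F%03d", seq_len(nrow(g))),
                    iid = sprintf("I%03d", seq_len(nrow(g))),
                    pat = "0", mat = "0", sex = 1L, phenotype = -9,
                    group = groups)
  cohort(markers, ind, g)
}

# Brute-force exact HWE oracle: enumerate every heterozygote count
# compatible with the allele counts and sum the unnormalised conditional
# probabilities (computed with plain factorials, valid for 2n <= 170) that
# do not exceed the observed configuration's.
hwe_enum_oracle <- function(n2, n1, n0) {
  n <- n2 + n1 + n0
  nA <- 2 * n2 + n1
  nB <- 2 * n0 + n1
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  w <- vapply(hets, function(h) {
    hom_r <- (min(nA, nB) - h) / 2
    hom_c <- n - hom_r - h
    factorial(n) / (factorial(hom_r) * factorial(h) * factorial(hom_c)) *
      2^h
  }, 0)
  pr <- w / sum(w)
  obs <- pr[hets == n1]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Pearson chi2 on a 2x2 table, direct formula.
chi2_oracle_2x2 <- function(a, b, c, d) {
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Numeric-integration oracle for the latent-Gaussian threshold model:
# haplotype r^2 implied by tetrachoric correlation rho and the two MAFs.
threshold_model_r2 <- function(rho, maf1, maf2) {
  t1 <- qnorm(maf1); t2 <- qnorm(maf2)
  p11 <- integrate(function(z)
    pnorm((t2 - rho * z) / sqrt(1 - rho^2)) * dnorm(z),
    -Inf, t1, rel.tol = 1e-10)$value
  d <- p11 - maf1 * maf2
  d^2 / (maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

# Single-marker haplotype pool at a given MAF (deterministic composition).
one_marker_pool <- function(maf, n_hap = 20000L) {
  k <- round(maf * n_hap)
  structure(list(
    markers = data.frame(id = "snp01", chrom = "11", pos = 1e6,
                         allele_minor = "A", allele_major = "G"),
    haplotypes = matrix(rep(c(1L, 0L), c(k, n_hap - k)), ncol = 1,
                        dimnames = list(NULL, "snp01")),
    blocks = 1L), class = "haplotype_pool")
}
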