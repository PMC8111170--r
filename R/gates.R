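# Sixth-order polynomial mapping genotype correlation to the correlation
# between two-sided association p-values, from the GATES method paper
# (Li MX, Gui HS, Kwan JSH, Sham PC (2011) "GATES: a rapid and powerful
# gene-based association test using extended Simes procedure", Am J Hum
# Genet 88:283-293).  Coefficients ordered from r^6 down to r^1.
.GATES_POLY <- c(0.2982, -0.0127, 0.0588, 0.0099, 0.6281, -0.0009)

#' Correlation between association p-values implied by genotype correlation
#'
#' Sixth-order polynomial approximation from the GATES publication (Li et
#' al. 2011, AJHG 88:283-293), clamped to `[-1, 1]`.  Since the p-values of
#' two-sided tests on perfectly (anti-)correlated genotypes coincide,
#' `|r| = 1` maps to exactly 1 rather than through the polynomial (which is
#' an approximation fitted on |r| < 1).
#'
#' @param r genotype correlation(s) in `[-1, 1]` (vector or matrix).
#' @return p-value correlation(s), same shape as `r`.
#' @export
p_correlation_from_genotype_r <- function(r) {
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE))
    stop("genotype correlation outside [-1, 1]")
  out <- .GATES_POLY[1] * r^6 + .GATES_POLY[2] * r^5 +
    .GATES_POLY[3] * r^4 + .GATES_POLY[4] * r^3 +
    .GATES_POLY[5] * r^2 + .GATES_POLY[6] * r
  out[abs(r) >= 1 - 1e-12] <- 1
  pmin(pmax(out, -1), 1)
}

#' Effective number of independent tests
#'
#' `m_e = m - sum_i (lambda_i - 1) I(lambda_i > 1)` over the eigenvalues of
#' a correlation matrix: fully independent tests give `m_e = m`, a rank-one
#' (perfectly correlated) matrix gives `m_e = 1`.
#'
#' @param lambda eigenvalues of an m x m correlation matrix.
#' @return Effective test count in `[1, m]`.
#' @export
effective_tests <- function(lambda) {
  if (any(lambda < -1e-8))
    stop("negative eigenvalue: correlation matrix is not positive ",
         "semi-definite")
  m <- length(lambda)
  m - sum((lambda - 1)[lambda > 1])
}

#' GATES gene-level p-value
#'
#' Combines per-SNP association p-values within a gene by the extended
#' Simes procedure: with p-values sorted ascending,
#' `p_gene = min_j m_e * p_(j) / m_e(j)`, where `m_e` is the effective
#' number of tests of the full p-value correlation matrix and `m_e(j)` that
#' of the submatrix of the j top-ranked SNPs.  The p-value correlation
#' matrix is obtained from the genotype correlation matrix through
#' [p_correlation_from_genotype_r()].
#'
#' @param p per-SNP p-values in (0, 1].
#' @param r_geno genotype correlation matrix between the same SNPs (order
#'   matching `p`); defaults to the identity (independent SNPs).
#' @param gene optional gene name.
#' @return An object of class `"gene_result"`: list with `gene`, `m`,
#'   `p_gene`, `m_e`, `m_e_j` (per-rank effective counts), `eigenvalues`.
#' @export
gates_pvalue <- function(p, r_geno = NULL, gene = NA_character_) {
  m <- length(p)
  stopifnot(m >= 1, all(p > 0), all(p <= 1))
  if (is.null(r_geno)) r_geno <- diag(1, m)
  r_geno <- as.matrix(r_geno)
  if (!all(dim(r_geno) == m))
    stop("r_geno must be ", m, " x ", m)
  ord <- order(p)
  ps <- p[ord]
  rr <- r_geno[ord, ord, drop = FALSE]
  pc <- p_correlation_from_genotype_r(rr)
  diag(pc) <- 1
  lam_all <- eigen(pc, symmetric = TRUE, only.values = TRUE)$values
  me <- effective_tests(pmax(lam_all, 0))
  me_j <- vapply(seq_len(m), function(j) {
    lam <- eigen(pc[seq_len(j), seq_len(j), drop = FALSE],
                 symmetric = TRUE, only.values = TRUE)$values
    effective_tests(pmax(lam, 0))
  }, 0)
  p_gene <- min(1, min(me * ps / me_j))
  structure(list(gene = gene, m = m, p_gene = p_gene, m_e = me,
                 m_e_j = me_j, eigenvalues = lam_all),
            class = "gene_result")
}

#' @export
print.gene_result <- function(x, ...) {
  cat("GATES", if (!is.na(x$gene)) paste0(" [", x$gene, "]"), ": ",
      x$m, " SNPs, m_e = ", signif(x$m_e, 4), ", gene-based p = ",
      signif(x$p_gene, 4), "\n", sep = "")
  invisible(x)
}
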