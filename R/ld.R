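#' EM estimate of two-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies for two biallelic markers from
#' unphased dosages.  Phase is ambiguous only for double heterozygotes;
#' the EM algorithm splits their expected contribution between the coupling
#' (minor-minor / major-major) and repulsion phases.  Frequencies are
#' initialised at linkage equilibrium (products of allele frequencies) and
#' iterated until the largest frequency change falls below `tol` or
#' `max_iter` iterations.
#'
#' @param gA,gB minor-allele dosage vectors (individuals with a missing
#'   value at either marker are dropped).
#' @param tol convergence tolerance on frequencies.
#' @param max_iter iteration cap.
#' @return Named numeric vector `c(mm, mM, Mm, MM)` of haplotype
#'   frequencies (first letter: allele at A, minor in lower case ... `mm`
#'   carries the minor allele at both markers).  Attributes: `iterations`,
#'   `loglik` (trace, one value per iteration, non-decreasing) and
#'   `monomorphic` flag.
#' @export
em_haplotype_freqs <- function(gA, gB, tol = 1e-10, max_iter = 1000L) {
  ok <- !is.na(gA) & !is.na(gB)
  gA <- gA[ok]; gB <- gB[ok]
  n <- length(gA)
  if (n < 2) stop("need at least 2 individuals complete at both markers")
  cnt <- matrix(0, 3, 3)  # cnt[a+1, b+1] = # individuals with dosages (a, b)
  for (a in 0:2) for (b in 0:2) cnt[a + 1, b + 1] <- sum(gA == a & gB == b)
  pA <- mean(gA) / 2
  pB <- mean(gB) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    f <- c(mm = pA * pB, mM = pA * (1 - pB), Mm = (1 - pA) * pB,
           MM = (1 - pA) * (1 - pB))
    return(structure(f, iterations = 0L, loglik = NA_real_,
                     monomorphic = TRUE))
  }
  # haplotype counts fully determined by all cells except the double het
  base <- c(mm = 0, mM = 0, Mm = 0, MM = 0)
  add <- function(h, k) base[h] <<- base[h] + k
  for (a in 0:2) for (b in 0:2) {
    k <- cnt[a + 1, b + 1]
    if (k == 0 || (a == 1 && b == 1)) next
    hapA <- c(rep("m", a), rep("M", 2 - a))      # alleles at A, 2 haplotypes
    hapB <- c(rep("m", b), rep("M", 2 - b))
    # at most one marker is heterozygous here, so this pairing is the only
    # one (up to exchanging the two haplotypes)
    add(paste0(hapA[1], hapB[1]), k)
    add(paste0(hapA[2], hapB[2]), k)
  }
  ndh <- cnt[2, 2]
  f <- c(mm = pA * pB, mM = pA * (1 - pB), Mm = (1 - pA) * pB,
         MM = (1 - pA) * (1 - pB))
  ll <- numeric(0)
  loglik <- function(f) {
    pr <- .geno_prob_table(f)
    sum(cnt[cnt > 0] * log(pr[cnt > 0]))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    cis <- f["mm"] * f["MM"]
    trans <- f["mM"] * f["Mm"]
    pc <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    k <- base
    k["mm"] <- k["mm"] + ndh * pc
    k["MM"] <- k["MM"] + ndh * pc
    k["mM"] <- k["mM"] + ndh * (1 - pc)
    k["Mm"] <- k["Mm"] + ndh * (1 - pc)
    f_new <- k / (2 * n)
    ll <- c(ll, loglik(f_new))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || it >= max_iter) break
  }
  structure(f, iterations = it, loglik = ll, monomorphic = FALSE)
}

# 3x3 table of P(dosage pair (a, b) | haplotype frequencies) under random
# union of gametes; rows index dosage at A (0..2), columns dosage at B.
.geno_prob_table <- function(f) {
  mm <- f[["mm"]]; mM <- f[["mM"]]; Mm <- f[["Mm"]]; MM <- f[["MM"]]
  matrix(c(MM^2,         2 * Mm * MM,               Mm^2,
           2 * mM * MM,  2 * mm * MM + 2 * mM * Mm, 2 * mm * Mm,
           mM^2,         2 * mm * mM,               mm^2),
         3, 3, byrow = TRUE)
}

#' Pairwise linkage disequilibrium from unphased genotypes
#'
#' Computes `D`, `r2` and `D'` from EM haplotype frequencies:
#' `D = f(mm) - pA pB`, `r2 = D^2 / (pA qA pB qB)` and
#' `D' = |D| / D_max` with `D_max` the admissible bound given the allele
#' frequencies.
#'
#' @inheritParams em_haplotype_freqs
#' @return An object of class `"ld_result"` with `freqs`, `pA`, `pB`, `D`,
#'   `r2`, `dprime`.  A monomorphic marker gives `r2 = 0`, `dprime = 0`,
#'   flagged via `monomorphic`.
#' @export
pairwise_ld <- function(gA, gB, tol = 1e-10, max_iter = 1000L) {
  f <- em_haplotype_freqs(gA, gB, tol = tol, max_iter = max_iter)
  pA <- unname(f["mm"] + f["mM"])
  pB <- unname(f["mm"] + f["Mm"])
  mono <- isTRUE(attr(f, "monomorphic"))
  D <- unname(f["mm"]) - pA * pB
  if (mono || pA %in% c(0, 1) || pB %in% c(0, 1)) {
    r2 <- 0; dp <- 0; D <- 0
  } else {
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    dp <- if (dmax > 0) abs(D) / dmax else 0
  }
  freqs <- stats::setNames(as.numeric(f), names(f))
  structure(list(freqs = freqs,
                 pA = pA, pB = pB, D = D, r2 = min(r2, 1),
                 dprime = min(dp, 1), monomorphic = mono,
                 em_iterations = attr(f, "iterations")),
            class = "ld_result")
}

#' Pairwise r2 (and D') matrices over a marker panel
#'
#' By default LD is estimated on the control sample, since case LD is
#' distorted at associated markers.
#'
#' @param x a cohort.
#' @param markers marker ids (default: whole panel).
#' @param groups group labels to estimate LD on; `NULL` for all
#'   individuals.
#' @return List of symmetric matrices `r2` and `dprime` with unit diagonal.
#' @export
ld_matrix <- function(x, markers = NULL, groups = c("CONTROL", "PSEUDO")) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(markers)) markers <- x$markers$id
  jm <- match(markers, x$markers$id)
  if (anyNA(jm)) stop("unknown marker: ", markers[is.na(jm)][1])
  rows <- if (is.null(groups)) seq_len(nrow(x$individuals))
          else which(x$individuals$group %in% groups)
  if (!length(rows)) stop("no individuals in the requested groups")
  M <- length(jm)
  r2 <- diag(1, M); dp <- diag(1, M)
  dimnames(r2) <- dimnames(dp) <- list(markers, markers)
  if (M > 1)
    for (i in 1:(M - 1)) for (j in (i + 1):M) {
      ld <- pairwise_ld(x$genotypes[rows, jm[i]], x$genotypes[rows, jm[j]])
      r2[i, j] <- r2[j, i] <- ld$r2
      dp[i, j] <- dp[j, i] <- ld$dprime
    }
  list(r2 = r2, dprime = dp)
}

#' Greedy r2-bin tag-SNP selection
#'
#' Repeatedly picks the unassigned marker with the most unassigned
#' neighbours whose pairwise r2 exceeds the threshold (ties broken by the
#' smallest base-pair position), forms a bin from the pick and those
#' neighbours, and makes the pick the bin's tag.  Markers correlated with
#' nothing become singleton bins tagging themselves.  The procedure is
#' deterministic for a fixed matrix.
#'
#' @param r2 square symmetric r2 matrix with unit diagonal (marker ids as
#'   dimnames).
#' @param threshold bin membership requires pairwise r2 strictly above this.
#' @param pos base-pair positions used for tie-breaking (defaults to column
#'   order).
#' @return An object of class `"tag_bins"`: list with `bins` (list of
#'   member-id vectors), `tags` (one id per bin) and `assignment` (bin
#'   index per marker).
#' @export
select_tag_snps <- function(r2, threshold = 0.8, pos = NULL) {
  if (!is.matrix(r2) || nrow(r2) != ncol(r2) ||
      max(abs(r2 - t(r2))) > 1e-8)
    stop("r2 must be a square symmetric matrix")
  m <- nrow(r2)
  ids <- colnames(r2)
  if (is.null(ids)) ids <- sprintf("m%d", seq_len(m))
  if (is.null(pos)) pos <- seq_len(m)
  adj <- r2 > threshold
  diag(adj) <- FALSE
  unassigned <- rep(TRUE, m)
  assignment <- integer(m)
  bins <- list(); tags <- character()
  while (any(unassigned)) {
    deg <- colSums(adj & unassigned) * unassigned
    cand <- which(unassigned)
    pick <- cand[order(-deg[cand], pos[cand])][1]
    members <- c(pick, which(adj[, pick] & unassigned))
    members <- unique(members)
    b <- length(bins) + 1L
    bins[[b]] <- ids[sort(members)]
    tags[b] <- ids[pick]
    assignment[members] <- b
    unassigned[members] <- FALSE
  }
  structure(list(bins = bins, tags = tags,
                 assignment = stats::setNames(assignment, ids),
                 threshold = threshold),
            class = "tag_bins")
}
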