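#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts at a biallelic marker: over all
#' heterozygote counts compatible with the observed allele counts, the
#' conditional probabilities (given allele counts, under random mating) that
#' do not exceed the observed configuration's probability are summed.  This
#' is the classic summation formulation (no mid-p adjustment).  Probabilities
#' are computed in log space and normalised, so counts in the thousands are
#' safe.
#'
#' @param counts a [genotype_counts()] object, or a numeric vector
#'   `c(n_hom_minor, n_het, n_hom_major)`.
#' @return The exact p-value.  A monomorphic marker returns `p = 1` with
#'   attribute `monomorphic = TRUE` (there is only one possible
#'   configuration).
#' @export
hwe_exact_test <- function(counts) {
  if (inherits(counts, "genotype_counts"))
    counts <- c(counts$n_hom_minor, counts$n_het, counts$n_hom_major)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n2 <- counts[1]; n1 <- counts[2]; n0 <- counts[3]
  n <- n2 + n1 + n0
  if (n < 1) stop("no non-missing genotypes")
  n_min <- 2 * n2 + n1
  n_maj <- 2 * n0 + n1
  if (n_min == 0 || n_maj == 0)
    return(structure(1, monomorphic = TRUE))
  rare <- min(n_min, n_maj)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het = h | n, allele counts) up to a shared constant
  lp <- hets * log(2) - lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (rare + hets) / 2)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  obs <- match(n1, hets)
  sum(pr[pr <= pr[obs] * (1 + 1e-7)])
}

#' Mendelian consistency of trio dosages
#'
#' A child genotype is consistent when each parent can transmit one of its
#' alleles to produce it: a homozygous parent must transmit its allele, a
#' heterozygote may transmit either.
#'
#' @param father,mother,child minor-allele dosages (vectors recycle).
#' @return Logical vector; `NA` where any member is missing.
#' @export
mendel_consistent <- function(father, mother, child) {
  # each parent transmits 1 (homozygous minor), 0 (homozygous major) or
  # either (heterozygote); reachable child dosages form a contiguous range
  lo <- (father == 2L) + (mother == 2L)
  hi <- (father >= 1L) + (mother >= 1L)
  child >= lo & child <= hi
}

#' Trio Mendel-error rate at one marker
#'
#' Trios with any missing member at the marker are skipped and excluded
#' from the denominator.
#'
#' @param trioset a [trio_set()].
#' @param x the cohort the trio indices refer to.
#' @param marker marker id.
#' @return List with `rate` (`NA` with `defined = FALSE` when no trio is
#'   evaluable), `n_evaluated`, and `errors` (indices of inconsistent trios).
#' @export
mendel_error_rate <- function(trioset, x, marker) {
  j <- match(marker, x$markers$id)
  if (is.na(j)) stop("unknown marker: ", marker)
  f <- x$genotypes[trioset$father, j]
  m <- x$genotypes[trioset$mother, j]
  c <- x$genotypes[trioset$child, j]
  complete <- !is.na(f) & !is.na(m) & !is.na(c)
  if (!any(complete))
    return(list(rate = NA_real_, defined = FALSE, n_evaluated = 0L,
                errors = integer()))
  ok <- mendel_consistent(f[complete], m[complete], c[complete])
  list(rate = mean(!ok), defined = TRUE, n_evaluated = sum(complete),
       errors = which(complete)[!ok])
}

#' SNP quality-control thresholds
#'
#' Exclusion is by strict inequality in every filter: a marker fails when
#' its MAF is *below* `maf_min`, its missing rate *above* `miss_max`, its
#' HWE exact p *below* `hwe_p_min`, or its Mendel-error rate *above*
#' `mendel_max`.  Boundary values pass.
#'
#' @param maf_min,miss_max,hwe_p_min,mendel_max thresholds in `[0, 1]`.
#' @return An object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(maf_min = 0.05, miss_max = 0.10,
                          hwe_p_min = 0.001, mendel_max = 0.05) {
  th <- list(maf_min = maf_min, miss_max = miss_max,
             hwe_p_min = hwe_p_min, mendel_max = mendel_max)
  stopifnot(all(unlist(th) >= 0), all(unlist(th) <= 1))
  structure(th, class = "qc_thresholds")
}

#' Apply the four SNP exclusion filters
#'
#' Per marker: MAF and missing rate over all individuals; the HWE exact test
#' on the community-control group and on trio founders (parents) separately,
#' failing if either falls below the threshold (pseudo-controls, being
#' synthetic genotypes, are never used for HWE); and the trio Mendel-error
#' rate when a trioset is supplied.  Statistics that cannot be computed
#' (no controls, no trios) are `NA` and never cause a failure.
#'
#' @param x a cohort.
#' @param trioset optional [trio_set()] for Mendel and founder-HWE checks.
#' @param thresholds a [qc_thresholds()].
#' @param control_groups group labels treated as community controls for the
#'   HWE filter.
#' @return An object of class `"qc_report"`: a list with `table` (per-marker
#'   statistics, verdicts and failed filters) and `survivors` (ids of
#'   passing markers, ordered by base-pair position).
#' @export
apply_qc <- function(x, trioset = NULL, thresholds = qc_thresholds(),
                     control_groups = "CONTROL") {
  stopifnot(inherits(x, "cohort"))
  m <- nrow(x$markers)
  if (m == 0) stop("empty marker panel")
  ctrl <- x$individuals$group %in% control_groups
  founders <- if (!is.null(trioset) && nrow(trioset))
    sort(unique(c(trioset$father, trioset$mother))) else integer()
  maf <- miss <- hwe_ctrl <- hwe_found <- mendel <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    id <- x$markers$id[j]
    all_ct <- genotype_counts(x, id)
    maf[j] <- all_ct$maf
    miss[j] <- all_ct$missing_rate
    if (any(ctrl)) {
      g <- x$genotypes[ctrl, j]
      cc <- c(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
              sum(g == 0L, na.rm = TRUE))
      if (sum(cc) > 0) hwe_ctrl[j] <- hwe_exact_test(cc)
    }
    if (length(founders)) {
      g <- x$genotypes[founders, j]
      fc <- c(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
              sum(g == 0L, na.rm = TRUE))
      if (sum(fc) > 0) hwe_found[j] <- hwe_exact_test(fc)
    }
    if (!is.null(trioset) && nrow(trioset))
      mendel[j] <- mendel_error_rate(trioset, x, id)$rate
  }
  fail_maf <- !is.na(maf) & maf < thresholds$maf_min
  fail_miss <- !is.na(miss) & miss > thresholds$miss_max
  fail_hwe <- (!is.na(hwe_ctrl) & hwe_ctrl < thresholds$hwe_p_min) |
    (!is.na(hwe_found) & hwe_found < thresholds$hwe_p_min)
  fail_mendel <- !is.na(mendel) & mendel > thresholds$mendel_max
  failed <- mapply(function(a, b, c, d)
    paste(c("maf", "missing", "hwe", "mendel")[c(a, b, c, d)],
          collapse = ","),
    fail_maf, fail_miss, fail_hwe, fail_mendel)
  verdict <- ifelse(nzchar(failed), "fail", "pass")
  tab <- data.frame(id = x$markers$id, chrom = x$markers$chrom,
                    pos = x$markers$pos, maf = maf, missing_rate = miss,
                    hwe_p_control = hwe_ctrl, hwe_p_founder = hwe_found,
                    mendel_rate = mendel, verdict = verdict,
                    failed_filters = failed, stringsAsFactors = FALSE)
  surv <- tab[tab$verdict == "pass", ]
  structure(list(table = tab,
                 survivors = surv$id[order(surv$chrom, surv$pos)],
                 thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  n <- nrow(x$table)
  cat("QC report: ", length(x$survivors), "/", n, " markers pass\n",
      sep = "")
  dropped <- x$table[x$table$verdict == "fail", c("id", "failed_filters")]
  if (nrow(dropped))
    cat(paste0("  excluded ", dropped$id, " (", dropped$failed_filters,
               ")\n"), sep = "")
  invisible(x)
}
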