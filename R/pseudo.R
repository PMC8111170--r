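#' Construct pseudo-controls from affected-child trios
#'
#' Under the Haplotype-Relative-Risk principle, the pair of parental alleles
#' *not* transmitted to the affected child forms the genotype of a matched
#' pseudo-control.  On dosages this is the allele-multiset identity
#' `pseudo = father + mother - child`, which is deterministic even for
#' double heterozygotes (no phase assignment is needed).  At a trio-marker
#' that is Mendel-inconsistent or not fully observed the pseudo-control is
#' set missing; a single warning summarises how many inconsistencies were
#' masked.
#'
#' One pseudo-control individual is produced per trio, labelled with group
#' `"PSEUDO"`, so downstream tests can treat them as ordinary unrelated
#' controls.
#'
#' @param trioset a [trio_set()].
#' @param x the cohort the trio indices refer to.
#' @return A `cohort` of pseudo-control individuals over the same panel.
#' @export
construct_pseudo_controls <- function(trioset, x) {
  stopifnot(inherits(trioset, "trioset"), inherits(x, "cohort"))
  n <- nrow(trioset)
  m <- nrow(x$markers)
  f <- x$genotypes[trioset$father, , drop = FALSE]
  mo <- x$genotypes[trioset$mother, , drop = FALSE]
  ch <- x$genotypes[trioset$child, , drop = FALSE]
  ps <- f + mo - ch
  complete <- !is.na(f) & !is.na(mo) & !is.na(ch)
  ok <- complete
  ok[complete] <- mendel_consistent(f[complete], mo[complete], ch[complete])
  n_bad <- sum(complete & !ok)
  ps[!ok] <- NA_integer_
  if (n_bad > 0)
    warning(n_bad, " Mendel-inconsistent trio-marker(s) set missing in ",
            "pseudo-controls")
  child_iid <- x$individuals$iid[trioset$child]
  ind <- data.frame(fid = x$individuals$fid[trioset$child],
                    iid = paste0("pseudo_", child_iid),
                    pat = "0", mat = "0", sex = 0L, phenotype = 1,
                    group = "PSEUDO")
  cohort(x$markers, ind, ps)
}
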