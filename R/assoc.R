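.Z95 <- 1.959964  # two-sided 95% normal quantile, fixed

# 2x2 machinery shared by the allelic and genotypic tests.
# Rows: case/control; columns: effect/reference category.
.test_2x2 <- function(a, b, c, d, marker, model, effect_allele) {
  tab <- matrix(c(a, b, c, d), 2L, 2L, byrow = TRUE)
  note <- NULL
  if (any(rowSums(tab) == 0)) {
    return(structure(list(marker = marker, model = model,
                          effect_allele = effect_allele, or = NA_real_,
                          ci95 = c(NA_real_, NA_real_), chi2 = NA_real_,
                          df = 1L, p = NA_real_, note = "degenerate margin"),
                     class = "assoc_result"))
  }
  if (any(colSums(tab) == 0)) {
    # category absent from both groups: no test, but a Haldane OR is still
    # reportable
    ht <- tab + 0.5
    or <- (ht[1, 1] * ht[2, 2]) / (ht[1, 2] * ht[2, 1])
    se <- sqrt(sum(1 / ht))
    return(structure(list(marker = marker, model = model,
                          effect_allele = effect_allele, or = or,
                          ci95 = exp(log(or) + c(-1, 1) * .Z95 * se),
                          chi2 = NA_real_, df = 1L, p = NA_real_,
                          note = paste("degenerate effect-category margin:",
                                       "Haldane OR only, no test")),
                     class = "assoc_result"))
  }
  ht <- tab
  if (any(tab == 0)) {
    ht <- tab + 0.5  # Haldane-Anscombe correction for OR/CI only
    note <- "zero cell: Haldane +0.5 applied to OR and CI"
  }
  or <- (ht[1, 1] * ht[2, 2]) / (ht[1, 2] * ht[2, 1])
  se <- sqrt(sum(1 / ht))
  ci <- exp(log(or) + c(-1, 1) * .Z95 * se)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(marker = marker, model = model,
                 effect_allele = effect_allele, or = or, ci95 = ci,
                 chi2 = unname(ct$statistic), df = 1L,
                 p = unname(ct$p.value), note = note),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(if (!is.na(x$marker)) paste0(x$marker, " ") else "", x$model,
      " model: OR = ", signif(x$or, 4), " (95% CI ",
      signif(x$ci95[1], 4), "-", signif(x$ci95[2], 4), "), chi2 = ",
      signif(x$chi2, 4), ", p = ", signif(x$p, 4), "\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Allelic chi-squared association test
#'
#' Pearson chi-squared test (no continuity correction) on the 2x2 table of
#' minor/major allele counts in cases versus controls, with the cross-product
#' odds ratio for the minor (effect) allele and its Woolf 95% confidence
#' interval `exp(ln OR +/- 1.96 sqrt(sum 1/cell))`.  When any cell is zero
#' the Haldane +0.5 correction is applied to every cell for the OR and CI
#' (the chi-squared statistic is computed on the uncorrected table).
#'
#' @param case,control [genotype_counts()] or [allele_counts()] objects.
#' @param marker optional marker id for labelling.
#' @return An object of class `"assoc_result"` with fields `or`, `ci95`,
#'   `chi2`, `df`, `p`.  Degenerate margins (a group with no counted
#'   alleles, or a monomorphic table) yield `NA` results flagged in `note`.
#' @export
allelic_test <- function(case, control, marker = NULL) {
  if (is.null(marker))
    marker <- if (!is.null(case$marker)) case$marker else NA_character_
  ea <- if (!is.null(case$effect_allele)) case$effect_allele
        else NA_character_
  .test_2x2(case$allele_count_minor, case$allele_count_major,
            control$allele_count_minor, control$allele_count_major,
            marker, "allelic", ea)
}

#' Genotypic association test under a dominant or recessive model
#'
#' Genotype counts are collapsed to 2x2 with respect to the minor (effect)
#' allele: the dominant model contrasts carriers (heterozygotes plus
#' homozygous-minor) against non-carriers, the recessive model contrasts
#' homozygous-minor against all others.  The collapsed table then goes
#' through the same chi-squared / OR machinery as [allelic_test()].
#'
#' @param case,control [genotype_counts()] objects.
#' @param model `"dominant"` or `"recessive"`.
#' @param marker optional marker id.
#' @return An `assoc_result`.
#' @export
genotypic_test <- function(case, control,
                           model = c("dominant", "recessive"),
                           marker = NULL) {
  model <- match.arg(model)
  if (is.null(marker))
    marker <- if (!is.na(case$marker)) case$marker else NA_character_
  collapse <- function(ct) {
    if (model == "dominant")
      c(ct$n_hom_minor + ct$n_het, ct$n_hom_major)
    else
      c(ct$n_hom_minor, ct$n_het + ct$n_hom_major)
  }
  ca <- collapse(case); co <- collapse(control)
  .test_2x2(ca[1], ca[2], co[1], co[2], marker, model, case$effect_allele)
}

#' Pick the most significant model for one marker
#'
#' Smallest p wins; exact ties are broken by the precedence
#' allelic > dominant > recessive.
#'
#' @param results list of `assoc_result` objects for one marker.
#' @return The winning `assoc_result`.
#' @export
best_model <- function(results) {
  stopifnot(length(results) >= 1)
  prec <- c(allelic = 1L, dominant = 2L, recessive = 3L)
  p <- vapply(results, function(r) if (is.na(r$p)) Inf else r$p, 0)
  rank <- prec[vapply(results, `[[`, "", "model")]
  results[[order(p, rank)[1]]]
}

#' Multi-group allelic heterogeneity test
#'
#' Pearson chi-squared test on the k x 2 table of minor/major allele counts
#' across k groups (df = k - 1), used e.g. to check that clinical groups or
#' control groups are homogeneous before aggregating them.
#'
#' @param counts_list list of two or more [genotype_counts()] /
#'   [allele_counts()] objects.
#' @return List with `chi2`, `df`, `p`; degenerate margins give `NA` with
#'   a `note`.
#' @export
multigroup_allele_test <- function(counts_list) {
  stopifnot(length(counts_list) >= 2)
  tab <- t(vapply(counts_list, function(ct)
    c(ct$allele_count_minor, ct$allele_count_major), c(0, 0)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chi2 = NA_real_, df = nrow(tab) - 1L, p = NA_real_,
                note = "degenerate margin"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Analytic power of the two-sided allelic test
#'
#' Normal-approximation power of the two-proportion comparison on allele
#' counts.  The case minor-allele frequency implied by a per-allele odds
#' ratio `psi` acting on the control allele odds is
#' `p1 = psi * p0/(1-p0) / (1 + psi * p0/(1-p0))`; allele totals are twice
#' the individual counts.  Power sums both rejection tails,
#' `Phi((d - z * SE0)/SE1) + Phi((-d - z * SE0)/SE1)` with `d = |p1 - p0|`,
#' `SE0` the pooled null standard error of the frequency difference and
#' `SE1` its alternative-hypothesis standard error, so the null case
#' `psi = 1` returns exactly `alpha`.
#'
#' @param n_case,n_control numbers of individuals per group.
#' @param p0 control minor-allele frequency, in (0, 1).
#' @param psi per-allele odds ratio (> 0).
#' @param alpha two-sided significance level, in (0, 1).
#' @return Power in `[0, 1]`.
#' @export
allelic_power <- function(n_case, n_control, p0, psi, alpha = 0.001) {
  stopifnot(n_case > 0, n_control > 0, p0 > 0, p0 < 1, psi > 0,
            alpha > 0, alpha < 1)
  odds1 <- psi * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  n1 <- 2 * n_case
  n2 <- 2 * n_control
  pbar <- (n1 * p1 + n2 * p0) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n2)
  z <- stats::qnorm(1 - alpha / 2)
  d <- abs(p1 - p0)
  stats::pnorm((d - z * se0) / se1) + stats::pnorm((-d - z * se0) / se1)
}
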