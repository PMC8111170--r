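#' Construct a genotyped cohort
#'
#' A cohort bundles a marker panel, an individual table and a dosage matrix.
#' Genotypes are coded as the number of copies of the panel minor allele
#' (0, 1, 2) with `NA` for missing.  The minor allele is a property of the
#' panel, fixed once (normally from the full combined sample at load time),
#' so per-group frequencies above 0.5 are legitimate and odds ratios stay
#' oriented to one effect allele across all group contrasts.
#'
#' @param markers data frame with columns `id`, `chrom`, `pos`,
#'   `allele_minor`, `allele_major`.  Positions are 1-based base pairs and
#'   are carried as opaque metadata.
#' @param individuals data frame with columns `fid`, `iid`, `pat`, `mat`,
#'   `sex`, `phenotype`, `group`.  `pat`/`mat` are parental individual ids
#'   ("0" when unknown); `group` is a free label such as `"CASE"`,
#'   `"CONTROL"` or `"PSEUDO"`.
#' @param genotypes integer matrix, individuals in rows, markers in columns,
#'   values in \{0, 1, 2, NA\}.
#' @return An object of class `"cohort"`.
#' @export
cohort <- function(markers, individuals, genotypes) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  need_m <- c("id", "chrom", "pos", "allele_minor", "allele_major")
  if (!all(need_m %in% names(markers)))
    stop("markers must have columns: ", paste(need_m, collapse = ", "))
  need_i <- c("fid", "iid", "pat", "mat", "sex", "phenotype", "group")
  for (col in setdiff(need_i, names(individuals)))
    individuals[[col]] <- switch(col, sex = 0L, phenotype = -9, pat = "0",
                                 mat = "0", fid = individuals$iid,
                                 group = "UNKNOWN", stop("missing iid"))
  individuals <- individuals[, need_i]
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(individuals) ||
      ncol(genotypes) != nrow(markers))
    stop("genotype matrix is ", nrow(genotypes), "x", ncol(genotypes),
         " but cohort declares ", nrow(individuals), " individuals and ",
         nrow(markers), " markers")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype dosages must be in {0, 1, 2, NA}")
  if (anyDuplicated(markers$id))
    stop("duplicated marker id in panel: ",
         markers$id[duplicated(markers$id)][1])
  if (any(markers$allele_minor == markers$allele_major))
    stop("minor and major allele coincide at marker ",
         markers$id[markers$allele_minor == markers$allele_major][1])
  if (any(markers$pos <= 0)) stop("marker positions must be positive")
  colnames(genotypes) <- markers$id
  rownames(genotypes) <- NULL
  structure(list(markers = markers, individuals = individuals,
                 genotypes = genotypes),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$individuals$group)
  cat("cohort: ", nrow(x$individuals), " individuals x ",
      nrow(x$markers), " markers\n", sep = "")
  cat("groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Trio index set
#'
#' Links father/mother/child rows of a cohort.  Indices must be valid,
#' pairwise distinct within a trio, and no child may appear twice.
#'
#' @param father,mother,child integer row indices into a cohort.
#' @param n_individuals cohort size used for validation (optional).
#' @return An object of class `"trioset"` (a data frame).
#' @export
trio_set <- function(father, mother, child, n_individuals = NULL) {
  tr <- data.frame(father = as.integer(father), mother = as.integer(mother),
                   child = as.integer(child))
  if (nrow(tr)) {
    if (any(tr$father == tr$mother | tr$father == tr$child |
            tr$mother == tr$child))
      stop("trio members must be pairwise distinct")
    if (anyDuplicated(tr$child))
      stop("a child appears in more than one trio")
    if (!is.null(n_individuals) &&
        (any(tr < 1L) || any(tr > n_individuals)))
      stop("trio index outside cohort")
  }
  class(tr) <- c("trioset", "data.frame")
  tr
}

#' Per-marker genotype and allele counts
#'
#' Counts homozygous-minor, heterozygous, homozygous-major and missing
#' genotypes for one marker over a subset of groups, and derives minor/major
#' allele counts, minor-allele frequency and missing rate.
#'
#' @param x a `cohort`, or a numeric vector
#'   `c(n_hom_minor, n_het, n_hom_major)` (optionally a 4th element,
#'   missing count) for direct construction.
#' @param ... passed to methods.
#' @return An object of class `"genotype_counts"`.
#' @export
genotype_counts <- function(x, ...) UseMethod("genotype_counts")

#' @rdname genotype_counts
#' @param marker marker id.
#' @param groups character vector of group labels to include; `NULL` means
#'   all individuals.
#' @export
genotype_counts.cohort <- function(x, marker, groups = NULL, ...) {
  j <- match(marker, x$markers$id)
  if (is.na(j)) stop("unknown marker: ", marker)
  if (is.null(groups)) {
    keep <- rep(TRUE, nrow(x$individuals))
  } else {
    known <- unique(x$individuals$group)
    if (length(bad <- setdiff(groups, known)))
      stop("unknown group label(s): ", paste(bad, collapse = ", "))
    keep <- x$individuals$group %in% groups
  }
  if (!any(keep)) stop("empty group subset")
  g <- x$genotypes[keep, j]
  new_genotype_counts(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                      sum(g == 0L, na.rm = TRUE), sum(is.na(g)),
                      marker = marker,
                      effect_allele = x$markers$allele_minor[j])
}

#' @rdname genotype_counts
#' @export
genotype_counts.numeric <- function(x, ...) {
  if (length(x) == 3L) x <- c(x, 0)
  if (length(x) != 4L || any(x < 0))
    stop("expected c(n_hom_minor, n_het, n_hom_major[, n_missing])")
  new_genotype_counts(x[1], x[2], x[3], x[4], ...)
}

new_genotype_counts <- function(n2, n1, n0, nm, marker = NA_character_,
                                effect_allele = NA_character_) {
  n_total <- n2 + n1 + n0 + nm
  ac_min <- 2 * n2 + n1
  ac_maj <- 2 * n0 + n1
  structure(list(marker = marker, effect_allele = effect_allele,
                 n_hom_minor = n2, n_het = n1, n_hom_major = n0,
                 n_missing = nm,
                 allele_count_minor = ac_min, allele_count_major = ac_maj,
                 maf = if (ac_min + ac_maj > 0) ac_min / (ac_min + ac_maj)
                       else NA_real_,
                 maf_defined = ac_min + ac_maj > 0,
                 missing_rate = if (n_total > 0) nm / n_total else NA_real_),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("genotype counts",
      if (!is.na(x$marker)) paste0(" [", x$marker, "]"), ": ",
      x$n_hom_minor, "/", x$n_het, "/", x$n_hom_major,
      " (hom-minor/het/hom-major), ", x$n_missing, " missing, maf = ",
      if (x$maf_defined) signif(x$maf, 4) else "undefined", "\n", sep = "")
  invisible(x)
}

#' Allele counts without genotype resolution
#'
#' Minimal container for a minor/major allele count pair, e.g. reconstructed
#' from a published minor-allele frequency and a sample size.  Accepted by
#' [allelic_test()] wherever full genotype counts are not available.
#'
#' @param minor,major non-negative allele counts (need not be integers when
#'   reconstructed from rounded frequencies).
#' @param marker optional marker id.
#' @return An object of class `"allele_counts"`.
#' @export
allele_counts <- function(minor, major, marker = NA_character_) {
  if (minor < 0 || major < 0) stop("allele counts must be non-negative")
  structure(list(marker = marker, allele_count_minor = minor,
                 allele_count_major = major,
                 maf = if (minor + major > 0) minor / (minor + major)
                       else NA_real_),
            class = "allele_counts")
}

#' Reconstruct allele counts from a frequency and a sample size
#'
#' @param maf minor-allele frequency.
#' @param n_individuals number of diploid individuals (2 alleles each).
#' @param marker optional marker id.
#' @return An `allele_counts` object with `2 * n * maf` minor alleles.
#' @export
allele_counts_from_maf <- function(maf, n_individuals,
                                   marker = NA_character_) {
  stopifnot(maf >= 0, maf <= 1, n_individuals >= 0)
  tot <- 2 * n_individuals
  allele_counts(tot * maf, tot * (1 - maf), marker = marker)
}

#' Pool allele counts across groups
#'
#' Sums minor and major allele counts over several `allele_counts` or
#' `genotype_counts` objects, e.g. to aggregate clinical groups into one
#' comparison sample.
#'
#' @param ... objects with `allele_count_minor`/`allele_count_major` fields,
#'   or a single list of them.
#' @return An `allele_counts` object.
#' @export
combine_allele_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], c("allele_counts",
                                               "genotype_counts")))
    xs <- xs[[1]]
  allele_counts(sum(vapply(xs, `[[`, 0, "allele_count_minor")),
                sum(vapply(xs, `[[`, 0, "allele_count_major")))
}

#' Subset a cohort to a set of markers
#'
#' @param x a cohort.
#' @param ids marker ids to keep (order preserved as given).
#' @return A cohort over the reduced panel.
#' @export
subset_markers <- function(x, ids) {
  j <- match(ids, x$markers$id)
  if (anyNA(j)) stop("unknown marker: ", ids[is.na(j)][1])
  cohort(x$markers[j, , drop = FALSE], x$individuals,
         x$genotypes[, j, drop = FALSE])
}

#' Stack cohorts that share a marker panel
#'
#' Individuals are concatenated in the order given; marker panels must be
#' identical (same ids, positions and allele orientation).
#'
#' @param ... cohorts, or a single list of cohorts.
#' @return A combined cohort.
#' @export
merge_cohorts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "cohort")) xs <- xs[[1]]
  ref <- xs[[1]]$markers
  for (x in xs[-1])
    if (!identical(x$markers$id, ref$id) ||
        !identical(x$markers$allele_minor, ref$allele_minor))
      stop("cohorts have incompatible marker panels")
  cohort(ref, do.call(rbind, lapply(xs, `[[`, "individuals")),
         do.call(rbind, lapply(xs, `[[`, "genotypes")))
}
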