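#' Default candidate-SNP panel specification
#'
#' A two-gene autosomal panel emulating the study design the simulator is
#' built around: 13 SNPs in one LD block on chromosome 11 and 7 SNPs in a
#' second block on chromosome 22, with minor-allele frequencies in the
#' 0.25-0.52 range typical of tag SNPs chosen at MAF >= 10%.
#'
#' @return A data frame with columns `maf`, `block`, `chrom`, `gene`.
#' @export
default_study_panel <- function() {
  data.frame(
    maf = c(0.439, 0.416, 0.421, 0.446, 0.412, 0.400, 0.373, 0.457, 0.438,
            0.452, 0.334, 0.336, 0.420,
            0.405, 0.344, 0.316, 0.386, 0.487, 0.450, 0.407),
    block = rep(1:2, c(13L, 7L)),
    chrom = rep(c("11", "22"), c(13L, 7L)),
    gene = rep(c("GENE_A", "GENE_B"), c(13L, 7L)))
}

#' Simulate a haplotype pool with block LD structure
#'
#' Haplotypes are drawn from a latent-Gaussian threshold model: within each
#' LD block the latent variables follow a first-order autoregressive process
#' with correlation `within_block_rho`; blocks are mutually independent.  A
#' marker carries the minor allele when its latent variable falls below the
#' `qnorm(maf)` threshold, so the empirical minor-allele frequency converges
#' to the target as the pool grows.
#'
#' @param panel data frame with columns `maf` and `block` (optionally
#'   `id`, `chrom`, `pos`, `allele_minor`, `allele_major`, `gene`).
#' @param n_haplotypes pool size (>= 2).
#' @param within_block_rho AR(1) latent correlation, in `[0, 1)`.
#' @param seed optional integer seed.
#' @return An object of class `"haplotype_pool"`: list with `markers`,
#'   binary matrix `haplotypes` (haplotype x marker) and `blocks`.
#' @export
simulate_haplotype_pool <- function(panel, n_haplotypes,
                                    within_block_rho = 0.8, seed = NULL) {
  panel <- as.data.frame(panel)
  stopifnot(all(panel$maf > 0), all(panel$maf < 1), n_haplotypes >= 2)
  if (within_block_rho < 0 || within_block_rho >= 1)
    stop("within_block_rho must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(panel)
  if (is.null(panel$block)) panel$block <- 1L
  if (is.null(panel$id)) panel$id <- sprintf("snp%02d", seq_len(m))
  if (is.null(panel$chrom)) panel$chrom <- as.character(panel$block)
  if (is.null(panel$pos)) panel$pos <- 1e6 + 5000 * seq_len(m)
  if (is.null(panel$allele_minor)) panel$allele_minor <- "A"
  if (is.null(panel$allele_major)) panel$allele_major <- "G"
  z <- matrix(stats::rnorm(n_haplotypes * m), n_haplotypes, m)
  rho <- within_block_rho
  if (m > 1 && rho > 0) {
    w <- sqrt(1 - rho^2)
    for (j in 2:m)
      if (panel$block[j] == panel$block[j - 1L])
        z[, j] <- rho * z[, j - 1L] + w * z[, j]
  }
  hap <- matrix(0L, n_haplotypes, m)
  for (j in seq_len(m)) hap[, j] <- as.integer(z[, j] < stats::qnorm(panel$maf[j]))
  colnames(hap) <- panel$id
  markers <- panel[, c("id", "chrom", "pos", "allele_minor", "allele_major")]
  if (!is.null(panel$gene)) markers$gene <- panel$gene
  structure(list(markers = markers, haplotypes = hap,
                 blocks = panel$block),
            class = "haplotype_pool")
}

#' Log-additive disease model
#'
#' Disease risk follows a logistic model that is log-additive across
#' markers: `logit P(affected) = logit(prevalence) + sum_m g_m * log(psi_m)`
#' where `g_m` is the minor-allele dosage and `psi_m` the per-allele odds
#' ratio.  The default prevalence of 0.05 keeps the disease rare enough
#' that odds ratios approximate relative risks.
#'
#' @param prevalence baseline probability of disease for a zero-dosage
#'   individual, in (0, 1).
#' @param or named numeric vector of per-allele odds ratios by marker id;
#'   markers not named have psi = 1.
#' @return An object of class `"disease_model"`.
#' @export
disease_model <- function(prevalence = 0.05, or = NULL) {
  stopifnot(prevalence > 0, prevalence < 1)
  if (!is.null(or)) {
    stopifnot(all(or > 0))
    if (is.null(names(or)) && length(or) > 0)
      stop("per-allele odds ratios must be named by marker id")
  }
  structure(list(prevalence = prevalence, or = or),
            class = "disease_model")
}

.affection_prob <- function(dosage, markers, model) {
  eta <- rep(stats::qlogis(model$prevalence), nrow(dosage))
  if (!is.null(model$or)) {
    idx <- match(names(model$or), markers$id)
    if (anyNA(idx)) stop("odds ratio named for unknown marker: ",
                         names(model$or)[is.na(idx)][1])
    g <- dosage[, idx, drop = FALSE]
    g[is.na(g)] <- 0L
    eta <- eta + drop(g %*% log(model$or))
  }
  stats::plogis(eta)
}

.draw_individuals <- function(pool, n) {
  i1 <- sample.int(nrow(pool$haplotypes), n, replace = TRUE)
  i2 <- sample.int(nrow(pool$haplotypes), n, replace = TRUE)
  pool$haplotypes[i1, , drop = FALSE] + pool$haplotypes[i2, , drop = FALSE]
}

#' Simulate an unrelated case/control sample
#'
#' Individuals are formed from two haplotypes drawn at random from the pool;
#' affection status is sampled from the [disease_model()] and individuals
#' are accumulated by rejection until the requested case and control counts
#' are reached.
#'
#' @param pool a [simulate_haplotype_pool()] result.
#' @param model a [disease_model()].
#' @param n_cases,n_controls requested counts.
#' @param seed optional integer seed; a fixed seed reproduces the cohort
#'   exactly.
#' @param max_attempts cap on rejection-sampling batches before giving up
#'   (guards against degenerate prevalence).
#' @return A `cohort` with groups `"CASE"` and `"CONTROL"` (cases first).
#' @export
simulate_case_control <- function(pool, model, n_cases, n_controls,
                                  seed = NULL, max_attempts = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(pool, "haplotype_pool"), nrow(pool$haplotypes) > 0)
  case_rows <- list(); ctrl_rows <- list()
  nca <- 0L; nco <- 0L
  batch <- max(1000L, n_cases + n_controls)
  attempts <- 0L
  while ((nca < n_cases || nco < n_controls)) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not reach requested case/control counts after ",
           max_attempts, " sampling batches")
    g <- .draw_individuals(pool, batch)
    aff <- stats::rbinom(batch, 1L, .affection_prob(g, pool$markers, model))
    if (nca < n_cases && any(aff == 1L)) {
      take <- which(aff == 1L)[seq_len(min(n_cases - nca, sum(aff == 1L)))]
      case_rows[[length(case_rows) + 1L]] <- g[take, , drop = FALSE]
      nca <- nca + length(take)
    }
    if (nco < n_controls && any(aff == 0L)) {
      take <- which(aff == 0L)[seq_len(min(n_controls - nco, sum(aff == 0L)))]
      ctrl_rows[[length(ctrl_rows) + 1L]] <- g[take, , drop = FALSE]
      nco <- nco + length(take)
    }
  }
  geno <- rbind(do.call(rbind, case_rows), do.call(rbind, ctrl_rows))
  n <- n_cases + n_controls
  ind <- data.frame(
    fid = sprintf("F%05d", seq_len(n)), iid = sprintf("I%05d", seq_len(n)),
    pat = "0", mat = "0", sex = 1L,
    phenotype = rep(c(2, 1), c(n_cases, n_controls)),
    group = rep(c("CASE", "CONTROL"), c(n_cases, n_controls)))
  cohort(pool$markers, ind, geno)
}

#' Simulate affected-child trios
#'
#' Parents are drawn as random pool individuals; the child receives one
#' uniformly chosen haplotype from each parent, so every trio is
#' Mendel-consistent by construction.  With `ascertain_affected_child` set,
#' whole families are resampled until the child is affected under the
#' disease model, reproducing ascertainment through an affected proband
#' (which induces transmission distortion at associated markers).
#'
#' @inheritParams simulate_case_control
#' @param n_trios number of father/mother/child families.
#' @param ascertain_affected_child keep only families with an affected
#'   child.
#' @return A list with elements `cohort` (groups `"PARENT"`/`"CASE"`, rows
#'   ordered father, mother, child per family) and `trios` (a [trio_set()]).
#' @export
simulate_trios <- function(pool, model, n_trios, seed = NULL,
                           ascertain_affected_child = TRUE,
                           max_attempts = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(pool, "haplotype_pool"), n_trios >= 1)
  H <- pool$haplotypes
  nh <- nrow(H)
  fa1 <- list(); fa2 <- list(); mo1 <- list(); mo2 <- list()
  tf <- list(); tm <- list()
  kept <- 0L
  batch <- max(1000L, n_trios)
  attempts <- 0L
  while (kept < n_trios) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not ascertain ", n_trios, " affected-child trios after ",
           max_attempts, " sampling batches")
    f1 <- sample.int(nh, batch, TRUE); f2 <- sample.int(nh, batch, TRUE)
    m1 <- sample.int(nh, batch, TRUE); m2 <- sample.int(nh, batch, TRUE)
    pick_f <- stats::runif(batch) < 0.5  # TRUE: father transmits hap 1
    pick_m <- stats::runif(batch) < 0.5
    ch <- H[ifelse(pick_f, f1, f2), , drop = FALSE] +
      H[ifelse(pick_m, m1, m2), , drop = FALSE]
    keep <- if (ascertain_affected_child)
      stats::rbinom(batch, 1L, .affection_prob(ch, pool$markers, model)) == 1L
    else rep(TRUE, batch)
    take <- which(keep)[seq_len(min(n_trios - kept, sum(keep)))]
    if (length(take)) {
      fa1[[length(fa1) + 1L]] <- f1[take]; fa2[[length(fa2) + 1L]] <- f2[take]
      mo1[[length(mo1) + 1L]] <- m1[take]; mo2[[length(mo2) + 1L]] <- m2[take]
      tf[[length(tf) + 1L]] <- pick_f[take]; tm[[length(tm) + 1L]] <- pick_m[take]
      kept <- kept + length(take)
    }
  }
  f1 <- unlist(fa1); f2 <- unlist(fa2); m1 <- unlist(mo1); m2 <- unlist(mo2)
  pick_f <- unlist(tf); pick_m <- unlist(tm)
  father <- H[f1, , drop = FALSE] + H[f2, , drop = FALSE]
  mother <- H[m1, , drop = FALSE] + H[m2, , drop = FALSE]
  child <- H[ifelse(pick_f, f1, f2), , drop = FALSE] +
    H[ifelse(pick_m, m1, m2), , drop = FALSE]
  n <- n_trios
  geno <- matrix(NA_integer_, 3L * n, ncol(H))
  geno[seq(1L, 3L * n, 3L), ] <- father
  geno[seq(2L, 3L * n, 3L), ] <- mother
  geno[seq(3L, 3L * n, 3L), ] <- child
  fid <- rep(sprintf("T%05d", seq_len(n)), each = 3L)
  role <- rep(c("f", "m", "c"), n)
  iid <- paste0(fid, role)
  ind <- data.frame(
    fid = fid, iid = iid,
    pat = ifelse(role == "c", paste0(fid, "f"), "0"),
    mat = ifelse(role == "c", paste0(fid, "m"), "0"),
    sex = rep(c(1L, 2L, 1L), n),
    phenotype = rep(c(-9, -9, 2), n),
    group = rep(c("PARENT", "PARENT", "CASE"), n))
  co <- cohort(pool$markers, ind, geno)
  tr <- trio_set(seq(1L, 3L * n, 3L), seq(2L, 3L * n, 3L),
                 seq(3L, 3L * n, 3L), n_individuals = 3L * n)
  list(cohort = co, trios = tr)
}
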