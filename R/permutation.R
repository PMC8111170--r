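# Fast Pearson chi2 for a batch of 2x2 tables given effect-category counts.
# a: case effect count, n1: case total, cb: column (overall) effect count,
# N: grand total.  Degenerate margins give chi2 = 0.
.chi2_2x2 <- function(a, n1, cb, N) {
  b <- n1 - a
  c <- cb - a
  n2 <- N - n1
  d <- n2 - c
  den <- n1 * n2 * cb * (N - cb)
  num <- N * (a * d - b * c)^2
  out <- ifelse(den > 0, num / den, 0)
  out
}

#' Family-wise max-T permutation correction
#'
#' Case/control labels are permuted uniformly while genotype rows (and hence
#' inter-marker LD) stay fixed; each permutation records the maximum test
#' statistic across the marker set, and the adjusted p-value of marker *m*
#' is `(1 + #\{perm: max chi2 >= observed chi2_m\}) / (n_perm + 1)`.  All
#' individuals in the case and control groups (pseudo-controls included)
#' are treated as exchangeable units.  Genotypes missing at a marker drop
#' out of that marker's table only (complete-case per marker).
#'
#' Markers analysed under the allelic model contribute allele counts (two
#' per individual); markers under a dominant or recessive model contribute
#' collapsed genotype categories (one per individual).
#'
#' With `exhaustive = TRUE` every distinct case-label assignment is
#' enumerated instead (feasible only for tiny samples) and the adjusted p
#' is the exact proportion of assignments whose maximum statistic reaches
#' the observed one.
#'
#' @param x a cohort containing both label sets.
#' @param markers marker ids to include (default: whole panel).
#' @param n_perm number of random permutations (ignored when exhaustive).
#' @param seed optional integer seed.
#' @param models single model or per-marker vector, each of
#'   `"allelic"`, `"dominant"`, `"recessive"`.
#' @param case_groups,control_groups group labels defining the two sides.
#' @param exhaustive enumerate all assignments exactly.
#' @param chunk permutations processed per block (memory control).
#' @return An object of class `"permutation_result"`: data frame `table`
#'   with per-marker `chi2`, `p_raw`, `p_adj`, plus `n_perm` and `seed`.
#' @export
maxT_permutation <- function(x, markers = NULL, n_perm = 10000L,
                             seed = NULL, models = "allelic",
                             case_groups = "CASE",
                             control_groups = c("CONTROL", "PSEUDO"),
                             exhaustive = FALSE, chunk = 1000L) {
  stopifnot(inherits(x, "cohort"))
  if (!exhaustive && n_perm < 1) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(markers)) markers <- x$markers$id
  jm <- match(markers, x$markers$id)
  if (anyNA(jm)) stop("unknown marker: ", markers[is.na(jm)][1])
  M <- length(jm)
  models <- rep_len(match.arg(models, c("allelic", "dominant", "recessive"),
                              several.ok = TRUE), M)
  is_case <- x$individuals$group %in% case_groups
  is_ctrl <- x$individuals$group %in% control_groups
  if (!any(is_case) || !any(is_ctrl))
    stop("both case and control labels must be present")
  keep <- which(is_case | is_ctrl)
  n <- length(keep)
  n_case <- sum(is_case)
  # per-marker score per individual and per-individual unit count
  S <- matrix(0, n, M)
  U <- matrix(0, n, M)
  for (k in seq_len(M)) {
    g <- x$genotypes[keep, jm[k]]
    s <- switch(models[k],
                allelic = g,
                dominant = as.integer(g >= 1L),
                recessive = as.integer(g == 2L))
    u <- if (models[k] == "allelic") 2 else 1
    nm <- !is.na(g)
    S[nm, k] <- s[nm]
    U[nm, k] <- u
  }
  utot <- colSums(U)          # total units per marker
  cb <- colSums(S)            # overall effect-category count per marker
  obs_lab <- as.numeric(is_case[keep])
  a_obs <- drop(crossprod(S, obs_lab))
  n1_obs <- drop(crossprod(U, obs_lab))
  chi2_obs <- .chi2_2x2(a_obs, n1_obs, cb, utot)
  p_raw <- stats::pchisq(chi2_obs, df = 1, lower.tail = FALSE)
  p_raw[chi2_obs == 0] <- 1

  count_ge <- numeric(M)
  if (exhaustive) {
    sets <- utils::combn(n, n_case)
    n_eff <- ncol(sets)
    for (start in seq(1L, n_eff, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n_eff)
      P <- matrix(0, n, length(idx))
      P[cbind(as.vector(sets[, idx, drop = FALSE]),
              rep(seq_along(idx), each = n_case))] <- 1
      A <- crossprod(S, P); N1 <- crossprod(U, P)
      chi2 <- .chi2_2x2(A, N1, cb, utot)
      mx <- apply(chi2, 2L, max)
      for (k in seq_len(M))
        count_ge[k] <- count_ge[k] + sum(mx >= chi2_obs[k] - 1e-12)
    }
    p_adj <- count_ge / n_eff
    n_used <- n_eff
  } else {
    done <- 0L
    while (done < n_perm) {
      k_now <- min(chunk, n_perm - done)
      P <- matrix(0, n, k_now)
      for (b in seq_len(k_now))
        P[sample.int(n, n_case), b] <- 1
      A <- crossprod(S, P); N1 <- crossprod(U, P)
      chi2 <- .chi2_2x2(A, N1, cb, utot)
      mx <- apply(chi2, 2L, max)
      for (k in seq_len(M))
        count_ge[k] <- count_ge[k] + sum(mx >= chi2_obs[k] - 1e-12)
      done <- done + k_now
    }
    p_adj <- (1 + count_ge) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(table = data.frame(id = markers, model = models,
                                    chi2 = chi2_obs, p_raw = p_raw,
                                    p_adj = p_adj,
                                    stringsAsFactors = FALSE),
                 n_perm = n_used, seed = seed, exhaustive = exhaustive),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("max-T permutation (",
      if (x$exhaustive) "exhaustive, " else "", x$n_perm,
      if (x$exhaustive) " assignments" else " permutations", ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
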