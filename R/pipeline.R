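#' Read a run configuration file
#'
#' The configuration is YAML with the following (all optional unless noted)
#' sections:
#'
#' * `seed`, `n_perm`, `nominal_threshold`
#' * `inputs`: `trios: {ped, map}` plus `groups: [{label, ped, map}, ...]`
#' * `synthetic`: `n_trios`, `group_sizes` (named), `n_controls`,
#'   `within_block_rho`, `prevalence`, `or` (named per marker), and an
#'   optional `panel` list of `{maf, block}` rows (defaults to
#'   [default_study_panel()])
#' * `qc`: any of the [qc_thresholds()] fields
#' * `contrasts` (required): list of `{name, case_groups, control_groups}`
#' * `primary_contrast`: name of the contrast driving model selection and
#'   permutation (default: first contrast)
#' * `genes`: list of `{name, markers}`
#' * `ld_groups`: groups on which LD / genotype correlation is estimated
#'
#' @param path YAML file path.
#' @return A validated list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list built in code rather than read from
#'   file.
#' @export
as_run_config <- function(cfg) {
  if (is.null(cfg$contrasts) || !length(cfg$contrasts))
    stop("configuration must declare at least one contrast")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$n_perm)) cfg$n_perm <- 10000L
  if (is.null(cfg$nominal_threshold)) cfg$nominal_threshold <- 0.05
  if (is.null(cfg$primary_contrast))
    cfg$primary_contrast <- cfg$contrasts[[1]]$name
  if (is.null(cfg$ld_groups)) cfg$ld_groups <- c("CONTROL", "PSEUDO")
  nm <- vapply(cfg$contrasts, `[[`, "", "name")
  if (!cfg$primary_contrast %in% nm)
    stop("primary_contrast '", cfg$primary_contrast,
         "' is not a declared contrast")
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.load_stage <- function(config) {
  if (!is.null(config$inputs)) {
    parts <- list()
    trios <- NULL
    if (!is.null(config$inputs$trios)) {
      tc <- read_pedmap(config$inputs$trios$ped, config$inputs$trios$map)
      trios_local <- tc$trios
      tc$individuals$group <- ifelse(
        seq_len(nrow(tc$individuals)) %in% trios_local$child,
        "CASE", "PARENT")
      parts$trios <- tc
      trios <- trios_local
    }
    for (g in config$inputs$groups) {
      gc <- read_pedmap(g$ped, g$map)
      gc$individuals$group <- g$label
      parts[[g$label]] <- gc
    }
    parts <- lapply(parts, function(p) { p$trios <- NULL; p })
    co <- merge_cohorts(parts)
    if (!is.null(trios)) {
      offset <- 0L  # trio cohort is merged first
      trios <- trio_set(trios$father + offset, trios$mother + offset,
                        trios$child + offset, nrow(co$individuals))
    }
    list(cohort = co, trios = trios)
  } else if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    panel <- if (is.null(sy$panel)) default_study_panel()
             else do.call(rbind, lapply(sy$panel, as.data.frame))
    pool <- simulate_haplotype_pool(
      panel, n_haplotypes = sy$n_haplotypes %||% 20000L,
      within_block_rho = sy$within_block_rho %||% 0.8)
    or <- if (!is.null(sy$or)) unlist(sy$or) else NULL
    model <- disease_model(prevalence = sy$prevalence %||% 0.05, or = or)
    parts <- list(); trios <- NULL
    if (!is.null(sy$n_trios) && sy$n_trios > 0) {
      tr <- simulate_trios(pool, model, sy$n_trios)
      parts$trios <- tr$cohort
      trios <- tr$trios
    }
    for (lab in names(sy$group_sizes %||% list())) {
      cc <- simulate_case_control(pool, model, sy$group_sizes[[lab]], 0)
      cc$individuals$group <- lab
      parts[[lab]] <- cc
    }
    if (!is.null(sy$n_controls) && sy$n_controls > 0) {
      cc <- simulate_case_control(pool, model, 0, sy$n_controls)
      parts$controls <- cc
    }
    co <- merge_cohorts(parts)
    list(cohort = co, trios = trios)
  } else stop("configuration provides neither inputs nor a synthetic spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full association workflow
#'
#' Stages, in order: load (files or synthetic simulation) -> SNP quality
#' control -> pseudo-control construction from trios -> per-contrast allelic
#' tests -> genotypic models with best-model selection for SNPs nominally
#' significant on the primary contrast -> max-T permutation correction on
#' the primary contrast -> LD matrix -> GATES gene-level tests per contrast.
#' The configuration seed is set once at the start, so a given
#' (configuration, seed) pair yields an identical result bundle.
#'
#' @param config a [read_run_config()] / [as_run_config()] object.
#' @param out_dir optional directory: result tables are written there as
#'   TSV (`snp_table.tsv`, `model_table.tsv`, `perm_table.tsv`,
#'   `gene_table.tsv`, `qc_report.tsv`, `ld_r2.tsv`, `log.txt`).  On any
#'   stage failure partial outputs are removed.
#' @return List with `snp_table`, `model_table`, `perm`, `gene_table`,
#'   `qc`, `ld`, `cohort`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- if (inherits(config, "run_config")) config
            else as_run_config(config)
  set.seed(config$seed)
  log <- list(seed = config$seed, n_perm = config$n_perm,
              config = unclass(config))

  loaded <- .stage("load", .load_stage(config))
  co <- loaded$cohort
  trios <- loaded$trios
  log$n_loaded <- nrow(co$individuals)

  th <- do.call(qc_thresholds, config$qc %||% list())
  qc <- .stage("qc", apply_qc(co, trios, th))
  co <- .stage("qc", subset_markers(co, qc$survivors))
  log$n_markers_pass_qc <- length(qc$survivors)

  if (!is.null(trios) && nrow(trios)) {
    pseudo <- .stage("pseudo",
                     suppressWarnings(construct_pseudo_controls(trios, co)))
    keep_parents <- !seq_len(nrow(co$individuals)) %in%
      c(trios$father, trios$mother)
    co <- merge_cohorts(cohort(co$markers,
                               co$individuals[keep_parents, , drop = FALSE],
                               co$genotypes[keep_parents, , drop = FALSE]),
                        pseudo)
    log$n_pseudo_controls <- nrow(pseudo$individuals)
  }
  log$n_analysis <- nrow(co$individuals)

  mk <- co$markers$id
  contrast_of <- function(name)
    config$contrasts[[which(vapply(config$contrasts, `[[`, "", "name") ==
                              name)]]
  snp_rows <- list()
  for (ct in config$contrasts) {
    for (id in mk) {
      ca <- .stage("assoc", genotype_counts(co, id,
                                            unlist(ct$case_groups)))
      cn <- .stage("assoc", genotype_counts(co, id,
                                            unlist(ct$control_groups)))
      res <- allelic_test(ca, cn, marker = id)
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        contrast = ct$name, id = id, effect_allele = res$effect_allele,
        maf_case = ca$maf, maf_control = cn$maf, or = res$or,
        ci_low = res$ci95[1], ci_high = res$ci95[2], chi2 = res$chi2,
        p = res$p, stringsAsFactors = FALSE)
    }
  }
  snp_table <- do.call(rbind, snp_rows)

  prim <- contrast_of(config$primary_contrast)
  prim_rows <- snp_table[snp_table$contrast == prim$name, ]
  hits <- prim_rows$id[!is.na(prim_rows$p) &
                         prim_rows$p < config$nominal_threshold]
  model_rows <- list()
  for (id in hits) {
    ca <- genotype_counts(co, id, unlist(prim$case_groups))
    cn <- genotype_counts(co, id, unlist(prim$control_groups))
    cand <- list(allelic_test(ca, cn, marker = id),
                 genotypic_test(ca, cn, "dominant", marker = id),
                 genotypic_test(ca, cn, "recessive", marker = id))
    bm <- best_model(cand)
    model_rows[[length(model_rows) + 1L]] <- data.frame(
      id = id, model = bm$model, or = bm$or, ci_low = bm$ci95[1],
      ci_high = bm$ci95[2], chi2 = bm$chi2, p = bm$p,
      stringsAsFactors = FALSE)
  }
  model_table <- if (length(model_rows)) do.call(rbind, model_rows)
    else data.frame(id = character(), model = character(), or = numeric(),
                    ci_low = numeric(), ci_high = numeric(),
                    chi2 = numeric(), p = numeric())

  perm <- .stage("perm", maxT_permutation(
    co, markers = mk, n_perm = config$n_perm,
    case_groups = unlist(prim$case_groups),
    control_groups = unlist(prim$control_groups)))

  ld <- .stage("ld", ld_matrix(co, groups = config$ld_groups))

  gene_rows <- list()
  for (gene in config$genes %||% list()) {
    gmk <- intersect(unlist(gene$markers), mk)
    if (!length(gmk)) next
    rows <- if (is.null(config$ld_groups)) seq_len(nrow(co$individuals))
            else which(co$individuals$group %in% config$ld_groups)
    G <- co$genotypes[rows, match(gmk, co$markers$id), drop = FALSE]
    rg <- stats::cor(G, use = "pairwise.complete.obs")
    rg[is.na(rg)] <- 0; diag(rg) <- 1
    for (ct in config$contrasts) {
      pv <- snp_table$p[snp_table$contrast == ct$name &
                          snp_table$id %in% gmk]
      names(pv) <- snp_table$id[snp_table$contrast == ct$name &
                                  snp_table$id %in% gmk]
      pv <- pv[gmk]
      ok <- !is.na(pv)
      if (!any(ok)) next
      gr <- .stage("gene", gates_pvalue(pv[ok], rg[ok, ok, drop = FALSE],
                                        gene = gene$name))
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene = gene$name, contrast = ct$name, n_snps = gr$m,
        m_e = gr$m_e, p_gene = gr$p_gene, stringsAsFactors = FALSE)
    }
  }
  gene_table <- if (length(gene_rows)) do.call(rbind, gene_rows)
    else data.frame(gene = character(), contrast = character(),
                    n_snps = integer(), m_e = numeric(),
                    p_gene = numeric())

  out <- list(snp_table = snp_table, model_table = model_table,
              perm = perm, gene_table = gene_table, qc = qc, ld = ld,
              cohort = co, log = log)
  if (!is.null(out_dir)) .write_bundle(out, out_dir)
  out
}

.write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

.write_bundle <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  on_fail <- function(e) { unlink(written); stop(e) }
  tryCatch({
    wr <- function(df, name) {
      p <- file.path(out_dir, name)
      .write_tsv(df, p)
      written <<- c(written, p)
    }
    wr(out$snp_table, "snp_table.tsv")
    wr(out$model_table, "model_table.tsv")
    wr(out$perm$table, "perm_table.tsv")
    wr(out$gene_table, "gene_table.tsv")
    wr(out$qc$table, "qc_report.tsv")
    r2 <- as.data.frame(out$ld$r2)
    r2 <- cbind(id = rownames(out$ld$r2), r2)
    wr(r2, "ld_r2.tsv")
    lg <- file.path(out_dir, "log.txt")
    writeLines(c(paste("seed:", out$log$seed),
                 paste("n_perm:", out$log$n_perm),
                 paste("individuals loaded:", out$log$n_loaded),
                 paste("markers passing QC:", out$log$n_markers_pass_qc),
                 paste("pseudo-controls:",
                       out$log$n_pseudo_controls %||% 0),
                 paste("individuals analysed:", out$log$n_analysis)), lg)
    written <<- c(written, lg)
  }, error = on_fail)
  invisible(written)
}
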