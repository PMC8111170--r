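#' Read a PLINK text PED/MAP file pair
#'
#' Parses white-space separated PED/MAP files into a [cohort()].  Dosages are
#' coded against the minor allele determined from the whole file (ties broken
#' lexicographically, the alphabetically smaller allele becoming minor).
#' Allele code `0` marks a missing allele; a pair with any missing allele is
#' coded `NA`.  Sex and phenotype columns are read but not validated.
#'
#' Trios are inferred where the paternal and maternal id columns both resolve
#' to individuals within the same family id in the file; the resulting
#' [trio_set()] is attached as the `trios` element of the returned cohort
#' (an empty trioset when no trio resolves).
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param group_map named character vector translating phenotype codes to
#'   group labels; phenotypes not listed become `"UNKNOWN"`.
#' @return A `cohort` with a `trios` element.
#' @export
read_pedmap <- function(ped_path, map_path,
                        group_map = c("1" = "CONTROL", "2" = "CASE")) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_tok)
  if (length(nf) && !all(nf %in% c(3L, 4L)))
    stop("malformed MAP line ", which(!nf %in% c(3L, 4L))[1],
         ": expected 3 or 4 fields")
  m <- length(map_tok)
  map_df <- data.frame(
    chrom = vapply(map_tok, `[`, "", 1),
    id    = vapply(map_tok, `[`, "", 2),
    pos   = as.numeric(vapply(map_tok, function(t) t[length(t)], "")))

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6L + 2L * m)
      stop("malformed PED line ", i, ": expected ", 6L + 2L * m,
           " fields, found ", length(tok))
    meta[[i]] <- tok[1:6]
    if (m) {
      al <- tok[-(1:6)]
      a1[i, ] <- al[seq(1L, 2L * m, 2L)]
      a2[i, ] <- al[seq(2L, 2L * m, 2L)]
    }
  }
  meta <- do.call(rbind, meta)
  individuals <- data.frame(fid = meta[, 1], iid = meta[, 2],
                            pat = meta[, 3], mat = meta[, 4],
                            sex = suppressWarnings(as.integer(meta[, 5])),
                            phenotype = suppressWarnings(as.numeric(meta[, 6])),
                            stringsAsFactors = FALSE)
  individuals$group <- unname(group_map[as.character(individuals$phenotype)])
  individuals$group[is.na(individuals$group)] <- "UNKNOWN"

  geno <- matrix(NA_integer_, n, m)
  allele_minor <- character(m)
  allele_major <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2L)
      stop("more than two alleles at marker ", map_df$id[j], ": ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0L) alleles <- c("N", "0")  # fully missing column
    if (length(alleles) == 1L) alleles <- c(alleles, "N")  # monomorphic
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    # minor = rarer allele; exact tie -> lexicographically smaller (alleles
    # are already sorted, so the tie falls through to alleles[1])
    minor <- if (cnt[2] < cnt[1]) alleles[2] else alleles[1]
    major <- setdiff(alleles, minor)
    allele_minor[j] <- minor
    allele_major[j] <- major
    ok <- a1[, j] != "0" & a2[, j] != "0"
    geno[ok, j] <- (a1[ok, j] == minor) + (a2[ok, j] == minor)
  }
  markers <- data.frame(id = map_df$id, chrom = map_df$chrom,
                        pos = map_df$pos, allele_minor = allele_minor,
                        allele_major = allele_major,
                        stringsAsFactors = FALSE)
  out <- cohort(markers, individuals, geno)

  # trio inference: pat/mat ids resolving within the same family
  key <- paste(individuals$fid, individuals$iid)
  fa <- match(paste(individuals$fid, individuals$pat), key)
  mo <- match(paste(individuals$fid, individuals$mat), key)
  is_child <- !is.na(fa) & !is.na(mo) & individuals$pat != "0" &
    individuals$mat != "0"
  out$trios <- trio_set(fa[is_child], mo[is_child], which(is_child),
                        n_individuals = n)
  out
}

#' Write a cohort as a PLINK text PED/MAP pair
#'
#' Inverse of [read_pedmap()]: dosage 2 becomes a homozygous minor pair,
#' 1 a minor/major pair, 0 homozygous major, and `NA` the missing code
#' `0 0`.  Re-reading the emitted files reproduces the dosage matrix exactly
#' whenever the stored minor allele is the one [read_pedmap()] would infer
#' (i.e. it is the rarer allele, or the lexicographically smaller one at
#' frequency one half).
#'
#' @param x a cohort.
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_pedmap <- function(x, ped_path, map_path) {
  stopifnot(inherits(x, "cohort"))
  mk <- x$markers
  writeLines(paste(mk$chrom, mk$id, 0, format(mk$pos, scientific = FALSE,
                                              trim = TRUE)), map_path)
  ind <- x$individuals
  n <- nrow(ind)
  m <- nrow(mk)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- x$genotypes[i, ]
    al <- character(2L * m)
    if (m) {
      a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, mk$allele_minor,
                                         mk$allele_major))
      a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, mk$allele_minor,
                                         mk$allele_major))
      al[seq(1L, 2L * m, 2L)] <- a1
      al[seq(2L, 2L * m, 2L)] <- a2
    }
    lines[i] <- paste(c(ind$fid[i], ind$iid[i], ind$pat[i], ind$mat[i],
                        ind$sex[i], ind$phenotype[i], al), collapse = " ")
  }
  con <- file(ped_path, "w")
  on.exit(close(con))
  if (n) writeLines(lines, con)
  invisible(c(ped = ped_path, map = map_path))
}
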