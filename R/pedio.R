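#' Case-family genotype panel
#'
#' The in-memory container used throughout the package: a rectangular panel
#' of minor-allele dosages for the mother, father and affected child of each
#' case family, at each SNP. Every family has a dosage slot (possibly `NA`)
#' for every SNP; a parent that was never genotyped is recorded as absent and
#' carries `NA` at all SNPs.
#'
#' @param snps data.frame of SNP metadata with columns `snp_id`,
#'   `chromosome`, `position`, `allele_minor`, `allele_major`, `gene`,
#'   `pathway`.
#' @param families data.frame with columns `family_id`, `stratum`
#'   (population-group label used for QC stratification),
#'   `mother_present`, `father_present`.
#' @param m,f,c integer matrices (families x SNPs) of minor-allele dosages
#'   0/1/2 with `NA` for missing calls.
#' @return an object of class `trio_panel`.
#' @export
trio_panel <- function(snps, families, m, f, c) {
  nf <- nrow(families); ns <- nrow(snps)
  for (mat in list(m = m, f = f, c = c)) {
    if (!is.matrix(mat) || nrow(mat) != nf || ncol(mat) != ns)
      stop("dosage matrices must be families x SNPs (", nf, " x ", ns, ")")
    v <- mat[!is.na(mat)]
    if (length(v) && (any(v < 0) || any(v > 2)))
      stop("dosages must be in {0, 1, 2} or NA")
  }
  if (anyDuplicated(snps$snp_id)) stop("duplicated snp_id in panel")
  if (anyDuplicated(families$family_id)) stop("duplicated family_id in panel")
  structure(list(snps = snps, families = families,
                 m = m, f = f, c = c),
            class = "trio_panel")
}

#' @export
print.trio_panel <- function(x, ...) {
  cat(sprintf("trio_panel: %d families x %d SNPs (%d full trios)\n",
              nrow(x$families), nrow(x$snps),
              sum(x$families$mother_present & x$families$father_present)))
  invisible(x)
}

#' Number of families / SNPs in a panel
#' @param panel a [trio_panel].
#' @return an integer count.
#' @export
n_families <- function(panel) nrow(panel$families)

#' @rdname n_families
#' @export
n_snps <- function(panel) nrow(panel$snps)

#' Extract the trios of one SNP
#'
#' @param panel a [trio_panel].
#' @param snp SNP id or column index.
#' @return data.frame with columns `family_id`, `m`, `f`, `c`, `stratum`.
#' @export
panel_trios <- function(panel, snp) {
  j <- if (is.character(snp)) match(snp, panel$snps$snp_id) else as.integer(snp)
  if (is.na(j) || j < 1 || j > n_snps(panel)) stop("unknown SNP: ", snp)
  data.frame(family_id = panel$families$family_id,
             m = panel$m[, j], f = panel$f[, j], c = panel$c[, j],
             stratum = panel$families$stratum,
             stringsAsFactors = FALSE)
}

#' Keep a subset of SNPs
#' @param panel a [trio_panel].
#' @param keep logical or integer index over SNPs.
#' @return a [trio_panel] restricted to the selected SNPs.
#' @export
panel_subset <- function(panel, keep) {
  trio_panel(panel$snps[keep, , drop = FALSE], panel$families,
             panel$m[, keep, drop = FALSE],
             panel$f[, keep, drop = FALSE],
             panel$c[, keep, drop = FALSE])
}

PATHWAYS <- c("folate", "homocysteine", "transsulfuration")

normalize_pathway <- function(x) {
  x <- tolower(trimws(x))
  ifelse(x %in% PATHWAYS, x, "other")
}

#' Read a SNP annotation table
#'
#' Reads a tab- or comma-separated annotation table with header columns
#' `snp_id`, `chr`, `pos`, `minor`, `major`, `gene`, `pathway`. Pathway
#' strings are mapped case-insensitively onto
#' folate / homocysteine / transsulfuration; anything else becomes `"other"`.
#'
#' @param path path to the annotation file (TSV or CSV; `\r\n` tolerated).
#' @return data.frame of SNP metadata (see [trio_panel()] `snps` slot).
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          comment.char = "")
  need <- c("snp_id", "chr", "pos", "minor", "major", "gene", "pathway")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(snp_id = as.character(df$snp_id),
                    chromosome = as.character(df$chr),
                    position = as.integer(df$pos),
                    allele_minor = as.character(df$minor),
                    allele_major = as.character(df$major),
                    gene = as.character(df$gene),
                    pathway = normalize_pathway(df$pathway),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$snp_id)) stop("duplicated snp_id in annotation")
  if (any(out$allele_minor == out$allele_major))
    stop("allele_minor must differ from allele_major")
  out
}

split_fields <- function(lines) {
  strsplit(trimws(gsub("\r$", "", lines)), "[ \t]+")
}

#' Read a pedigree-format genotype panel
#'
#' Reads classic pedigree text files: a PED file with six fixed columns
#' (family ID, individual ID, father ID, mother ID, sex, phenotype) followed
#' by two allele columns per SNP (`0` = missing call), and a MAP file with
#' one row per SNP (chromosome, SNP id, genetic distance, position). Each
#' family is reduced to one affected case child (phenotype code 2) plus
#' whichever parents are genotyped; dosages count the minor allele, which is
#' determined from founder (parental) allele counts unless an annotation
#' table overrides it.
#'
#' The reader deliberately accepts Mendelian-inconsistent trios: consistency
#' is a quality-control question, answered by [qc_filter()].
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param annotation optional data.frame from [read_annotation()]; when
#'   given, allele orientation and SNP metadata are taken from it.
#' @param strata optional named character vector mapping family IDs to
#'   population-stratum labels; unnamed families get `"ALL"`.
#' @return a [trio_panel].
#' @export
read_ped <- function(ped_path, map_path, annotation = NULL, strata = NULL) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (length(map_lines)) {
    map <- utils::read.table(text = map_lines, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(map) < 4) stop("MAP file must have 4 columns (chr, snp, cM, pos)")
  } else {
    map <- data.frame(V1 = character(), V2 = character(),
                      V3 = numeric(), V4 = integer())
  }
  snp_ids <- as.character(map[[2]])
  ns <- length(snp_ids)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- split_fields(lines)
  expected <- 6L + 2L * ns
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) != expected)
      stop("malformed PED line ", i, ": expected ", expected,
           " fields, found ", length(fields[[i]]))
  }
  if (length(fields) == 0L) {
    ped <- data.frame(fid = character(), iid = character(),
                      father = character(), mother = character(),
                      sex = character(), phe = character())
    alle <- matrix(character(), 0, 2 * ns)
  } else {
    mat <- do.call(rbind, fields)
    ped <- data.frame(fid = mat[, 1], iid = mat[, 2], father = mat[, 3],
                      mother = mat[, 4], sex = mat[, 5], phe = mat[, 6],
                      stringsAsFactors = FALSE)
    alle <- mat[, -(1:6), drop = FALSE]
  }
  ok <- alle %in% c("A", "C", "G", "T", "0")
  if (!all(ok)) stop("invalid allele code(s) in PED: ",
                     paste(unique(alle[!ok]), collapse = ", "))

  fam_ids <- unique(ped$fid)
  nf <- length(fam_ids)
  a1 <- alle[, seq(1, by = 2, length.out = ns), drop = FALSE]
  a2 <- alle[, seq(2, by = 2, length.out = ns), drop = FALSE]

  rows <- split(seq_len(nrow(ped)), factor(ped$fid, levels = fam_ids))
  child_row <- mother_row <- father_row <- rep(NA_integer_, nf)
  for (i in seq_len(nf)) {
    r <- rows[[i]]
    if (anyDuplicated(ped$iid[r]))
      stop("duplicated individual ID within family ", fam_ids[i])
    aff <- r[ped$phe[r] == "2"]
    if (length(aff) == 0L)
      stop("family ", fam_ids[i], " has no affected (phenotype 2) child; ",
           "a case-only file must contain one case child per family")
    if (length(aff) > 1L) {
      aff <- aff[order(ped$iid[aff])]
      warning("family ", fam_ids[i], " has ", length(aff),
              " affected children; keeping ", ped$iid[aff[1]])
    }
    ch <- aff[1]
    child_row[i] <- ch
    mother_row[i] <- r[match(ped$mother[ch], ped$iid[r])]
    father_row[i] <- r[match(ped$father[ch], ped$iid[r])]
  }

  geno_dosage <- function(rowsel, j, minor) {
    x1 <- a1[rowsel, j]; x2 <- a2[rowsel, j]
    miss <- is.na(rowsel) | x1 == "0" | x2 == "0"
    d <- (x1 == minor) + (x2 == minor)
    d[miss] <- NA_integer_
    as.integer(d)
  }

  if (!is.null(annotation)) {
    snps <- annotation[match(snp_ids, annotation$snp_id), , drop = FALSE]
    if (anyNA(snps$snp_id))
      stop("annotation lacks SNP(s): ",
           paste(snp_ids[is.na(snps$snp_id)], collapse = ", "))
    rownames(snps) <- NULL
  } else {
    snps <- data.frame(snp_id = snp_ids,
                       chromosome = as.character(map[[1]]),
                       position = as.integer(map[[4]]),
                       allele_minor = rep(NA_character_, ns),
                       allele_major = rep(NA_character_, ns),
                       gene = rep(NA_character_, ns),
                       pathway = rep("other", ns),
                       stringsAsFactors = FALSE)
    founder_rows <- c(mother_row, father_row)
    founder_rows <- founder_rows[!is.na(founder_rows)]
    for (j in seq_len(ns)) {
      al <- c(a1[founder_rows, j], a2[founder_rows, j])
      al <- al[al != "0"]
      if (length(al) == 0L) {      # no founder calls: fall back to everyone
        al <- c(a1[, j], a2[, j]); al <- al[al != "0"]
      }
      if (length(al) == 0L) {      # SNP entirely uncalled
        snps$allele_minor[j] <- "A"; snps$allele_major[j] <- "C"
        next
      }
      tab <- table(al)
      alleles <- names(tab)
      if (length(alleles) == 1L) {
        snps$allele_major[j] <- alleles
        snps$allele_minor[j] <- setdiff(c("A", "C", "G", "T"), alleles)[1]
      } else {
        if (length(alleles) > 2L)
          stop("SNP ", snp_ids[j], " has >2 alleles: not biallelic")
        # minor = rarer allele among founders; 0.50 ties break to the
        # ASCII-lowest character
        o <- order(tab, alleles)
        snps$allele_minor[j] <- alleles[o[1]]
        snps$allele_major[j] <- alleles[o[2]]
      }
    }
  }

  m <- f <- cc <- matrix(NA_integer_, nf, ns,
                         dimnames = list(fam_ids, snp_ids))
  for (j in seq_len(ns)) {
    minor <- snps$allele_minor[j]
    cc[, j] <- geno_dosage(child_row, j, minor)
    m[, j] <- geno_dosage(mother_row, j, minor)
    f[, j] <- geno_dosage(father_row, j, minor)
  }

  stratum <- rep("ALL", nf)
  if (!is.null(strata)) {
    hit <- match(fam_ids, names(strata))
    stratum[!is.na(hit)] <- unname(strata[hit[!is.na(hit)]])
  }
  families <- data.frame(
    family_id = fam_ids, stratum = stratum,
    # a parent absent from the pedigree, or missing at every SNP, is
    # structurally absent (matters for no-call denominators in QC)
    mother_present = !is.na(mother_row) & rowSums(!is.na(m)) > 0,
    father_present = !is.na(father_row) & rowSums(!is.na(f)) > 0,
    stringsAsFactors = FALSE)
  if (ns == 0L) { families$mother_present <- !is.na(mother_row)
                  families$father_present <- !is.na(father_row) }
  rownames(families) <- NULL
  trio_panel(snps, families, m, f, cc)
}

#' Write a panel as pedigree-format files
#'
#' Inverse of [read_ped()]: writes one PED row per family member (father,
#' mother, case child) and a 4-column MAP file. Missing dosages and absent
#' parents are written as `0 0` genotype pairs; heterozygotes are written
#' minor allele first. A panel written here and read back yields a
#' dosage-identical panel.
#'
#' @param panel a [trio_panel].
#' @param ped_path,map_path output paths.
#' @return invisibly, `panel`.
#' @export
write_ped <- function(panel, ped_path, map_path) {
  snps <- panel$snps
  gtxt <- function(d, minor, major) {
    out <- rep("0 0", length(d))
    out[!is.na(d) & d == 0] <- paste(major, major)
    out[!is.na(d) & d == 1] <- paste(minor, major)
    out[!is.na(d) & d == 2] <- paste(minor, minor)
    out
  }
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n_families(panel))) {
    fid <- panel$families$family_id[i]
    ids <- paste0(fid, c("_f", "_m", "_c"))
    g <- vapply(seq_len(n_snps(panel)), function(j) {
      gtxt(c(panel$f[i, j], panel$m[i, j], panel$c[i, j]),
           snps$allele_minor[j], snps$allele_major[j])
    }, character(3))
    g <- if (n_snps(panel)) matrix(g, nrow = 3) else matrix("", 3, 0)
    lines <- c(
      paste(c(fid, ids[1], "0", "0", "1", "1", g[1, ]), collapse = " "),
      paste(c(fid, ids[2], "0", "0", "2", "1", g[2, ]), collapse = " "),
      paste(c(fid, ids[3], ids[1], ids[2], "0", "2", g[3, ]), collapse = " "))
    writeLines(lines, con)
  }
  utils::write.table(
    data.frame(snps$chromosome, snps$snp_id, rep(0, nrow(snps)),
               snps$position),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(panel)
}

#' Write a SNP annotation table
#'
#' @param snps the `snps` slot of a [trio_panel] (or any data.frame with the
#'   same columns).
#' @param path output TSV path.
#' @return invisibly, `snps`.
#' @export
write_annotation <- function(snps, path) {
  out <- data.frame(snp_id = snps$snp_id, chr = snps$chromosome,
                    pos = snps$position, minor = snps$allele_minor,
                    major = snps$allele_major, gene = snps$gene,
                    pathway = snps$pathway, stringsAsFactors = FALSE)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(snps)
}
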