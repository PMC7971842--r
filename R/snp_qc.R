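#' Quality-control thresholds for per-SNP filters
#'
#' @param max_nocall maximum tolerated no-call (missing-genotype) proportion.
#' @param max_mendel_error maximum tolerated trio Mendelian-error rate.
#' @param min_maf minimum founder minor allele frequency.
#' @param hwe_alpha significance level for the exact Hardy-Weinberg test,
#'   applied within each population stratum; a SNP fails if any stratum's
#'   p-value falls below it.
#' @return a named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_nocall = 0.10, max_mendel_error = 0.05,
                          min_maf = 0.05, hwe_alpha = 1e-4) {
  vals <- c(max_nocall, max_mendel_error, min_maf, hwe_alpha)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("thresholds must lie in [0, 1]")
  structure(list(max_nocall = max_nocall,
                 max_mendel_error = max_mendel_error,
                 min_maf = min_maf, hwe_alpha = hwe_alpha),
            class = "qc_thresholds")
}

#' Mendelian consistency of a complete trio
#'
#' Can the child's minor-allele dosage arise from one allele of the mother
#' and one of the father? Vectorised over trios.
#'
#' @param m,f,c complete (non-missing) dosages in \{0, 1, 2\}.
#' @return logical vector, `TRUE` where the trio is Mendelian-consistent.
#' @examples
#' mendelian_consistent(0, 0, 1)   # FALSE: no minor allele available
#' mendelian_consistent(2, 2, 2)   # TRUE: forced transmission
#' @export
mendelian_consistent <- function(m, f, c) {
  args <- cbind(m, f, c)
  if (anyNA(args) || any(!(args %in% 0:2)))
    stop("dosages must be non-missing values in {0, 1, 2}")
  # child's maternal allele am and paternal allele af satisfy am + af = c,
  # with am possible iff mother's dosage allows it (dosage 1 allows both)
  can_give <- function(parent, allele)
    (allele == 0 & parent <= 1) | (allele == 1 & parent >= 1)
  (c >= 1 & can_give(m, 1) & can_give(f, c - 1)) |
    (c <= 1 & can_give(m, 0) & can_give(f, c))
}

# parent-child (duo) impossibility: opposite homozygotes
duo_consistent <- function(parent, child) {
  !((parent == 0 & child == 2) | (parent == 2 & child == 0))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on founder genotype counts, using the
#' probability-ordering convention: the p-value is the sum, over all
#' heterozygote counts consistent with the observed allele counts, of
#' conditional probabilities no larger than that of the observed table.
#'
#' @param n0,n1,n2 nonnegative integer genotype counts: major homozygotes,
#'   heterozygotes, minor homozygotes.
#' @return exact p-value in (0, 1]; returns 1 with a warning when all counts
#'   are zero.
#' @examples
#' hwe_exact_p(21, 48, 31)
#' @export
hwe_exact_p <- function(n0, n1, n2) {
  cnt <- c(n0, n1, n2)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("genotype counts must be nonnegative integers")
  n <- n0 + n1 + n2
  if (n == 0L) {
    warning("all genotype counts are zero: HWE test undefined, returning 1")
    return(1)
  }
  n_minor <- n1 + 2 * n2            # rarer allele count (either orientation works)
  n_minor <- min(n_minor, 2 * n - n_minor)
  # possible heterozygote counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log conditional probability of each table given allele counts
  lp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(hom_maj + 1) - lgamma(h + 1) - lgamma(hom_min + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(n1, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' Apply per-SNP quality-control filters to a panel
#'
#' A SNP is retained iff its no-call rate is at most `max_nocall`, its
#' Mendelian-error rate at most `max_mendel_error`, its founder minor allele
#' frequency at least `min_maf`, and its exact HWE p-value in every
#' population stratum at least `hwe_alpha`. The report covers all input SNPs,
#' including excluded ones; excluded SNPs are dropped before modelling, never
#' imputed.
#'
#' Rates follow these conventions: the no-call rate divides missing genotype
#' slots by the slots of family members actually genotyped in the study
#' (structurally absent parents are not counted as no-calls); the
#' Mendelian-error rate counts inconsistent complete trios plus impossible
#' parent-child duos, over complete trios plus informative duos; MAF is
#' computed from founders (parents) pooled across strata, since case children
#' are ascertainment-biased.
#'
#' @param panel a [trio_panel].
#' @param thresholds a [qc_thresholds] object.
#' @return list with `panel` (the passing SNPs) and `report`, a data.frame
#'   with one row per input SNP: `snp_id`, `nocall_rate`,
#'   `mendel_error_rate`, `maf`, `hwe_p_min`, per-stratum `hwe_p.<stratum>`
#'   columns, `pass`, `fail_reasons` (comma-separated subset of
#'   nocall/mendel/maf/hwe).
#' @export
qc_filter <- function(panel, thresholds = qc_thresholds()) {
  if (n_snps(panel) == 0L) stop("panel has no SNPs")
  th <- thresholds
  fams <- panel$families
  strata <- sort(unique(fams$stratum))
  ns <- n_snps(panel)

  nocall <- mendel <- maf <- numeric(ns)
  hwe <- matrix(NA_real_, ns, length(strata),
                dimnames = list(NULL, strata))
  for (j in seq_len(ns)) {
    m <- panel$m[, j]; f <- panel$f[, j]; c <- panel$c[, j]

    slots <- 1 + fams$mother_present + fams$father_present
    miss <- is.na(c) +
      (fams$mother_present & is.na(m)) + (fams$father_present & is.na(f))
    nocall[j] <- sum(miss) / sum(slots)

    trio <- !is.na(m) & !is.na(f) & !is.na(c)
    duo_m <- !is.na(m) & is.na(f) & !is.na(c)
    duo_f <- is.na(m) & !is.na(f) & !is.na(c)
    n_err <- 0L
    if (any(trio))
      n_err <- n_err + sum(!mendelian_consistent(m[trio], f[trio], c[trio]))
    n_err <- n_err + sum(!duo_consistent(m[duo_m], c[duo_m])) +
      sum(!duo_consistent(f[duo_f], c[duo_f]))
    denom <- sum(trio) + sum(duo_m) + sum(duo_f)
    mendel[j] <- if (denom > 0) n_err / denom else 0

    founder <- c(m, f)
    maf[j] <- if (all(is.na(founder))) 0 else mean(founder, na.rm = TRUE) / 2

    for (s in seq_along(strata)) {
      in_s <- fams$stratum == strata[s]
      g <- c(m[in_s], f[in_s]); g <- g[!is.na(g)]
      hwe[j, s] <- if (length(g) == 0) 1 else
        suppressWarnings(hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2)))
    }
  }
  hwe_min <- apply(hwe, 1, min)

  reasons <- vapply(seq_len(ns), function(j) {
    r <- c(if (nocall[j] > th$max_nocall) "nocall",
           if (mendel[j] > th$max_mendel_error) "mendel",
           if (maf[j] < th$min_maf) "maf",
           if (hwe_min[j] < th$hwe_alpha) "hwe")
    paste(r, collapse = ",")
  }, character(1))
  pass <- reasons == ""

  report <- data.frame(snp_id = panel$snps$snp_id,
                       nocall_rate = nocall, mendel_error_rate = mendel,
                       maf = maf, hwe_p_min = hwe_min,
                       stringsAsFactors = FALSE)
  hp <- as.data.frame(hwe)
  names(hp) <- paste0("hwe_p.", strata)
  report <- cbind(report, hp,
                  data.frame(pass = pass, fail_reasons = reasons,
                             stringsAsFactors = FALSE))
  list(panel = panel_subset(panel, pass), report = report)
}
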