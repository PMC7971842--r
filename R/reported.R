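#' Published top-20 parent-of-origin results for obstructive heart defects
#'
#' The top-20 SNP summary published by the NBDPS candidate-gene scan of
#' obstructive heart defects (569 case families, 877 SNPs in folate,
#' homocysteine and transsulfuration pathway genes): per-SNP paternal-versus-
#' maternal relative risks, 95% confidence intervals and likelihood-ratio
#' p-values. The underlying genotypes are restricted, so this printed summary
#' is the only recomputable anchor for significance-call checks.
#'
#' @return data.frame with columns `snp_id`, `alleles` (referent/risk),
#'   `chr`, `gene`, `pathway` (normalised to the package's pathway enum),
#'   `rr`, `ci_lower`, `ci_upper`, `p_value`.
#' @examples
#' tab <- reported_top20()
#' sum(tab$p_value <= bonferroni_threshold(0.05, 877))   # 4
#' @export
reported_top20 <- function() {
  path <- system.file("extdata", "nbdps_ohd_top20.tsv", package = "poescan",
                      mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$pathway <- normalize_pathway(df$pathway)
  df
}

#' Flag Bonferroni-significant rows of a reported results table
#'
#' @param table data.frame with a `p_value` column (e.g. [reported_top20()]).
#' @param alpha family-wise level.
#' @param n_snps_tested Bonferroni denominator: SNPs tested in the scan the
#'   table summarises (not the number of printed rows).
#' @return the table with a logical `significant` column appended.
#' @export
flag_significant <- function(table, alpha = 0.05, n_snps_tested) {
  thr <- bonferroni_threshold(alpha, n_snps_tested)
  table$significant <- table$p_value <= thr
  table
}
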