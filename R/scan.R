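#' Configuration for a multi-SNP parent-of-origin scan
#'
#' @param alpha family-wise significance level (Bonferroni-controlled).
#' @param maternal fit maternal genotype relative risks (see [fit_snp()]).
#' @param qc a [qc_thresholds] object, or `NULL` to skip quality control
#'   (the panel is then assumed already filtered).
#' @param top_k number of rows flagged for the summary table.
#' @return a named list of class `scan_config`.
#' @export
scan_config <- function(alpha = 0.05, maternal = TRUE,
                        qc = qc_thresholds(), top_k = 20) {
  stopifnot(alpha > 0, alpha < 1, top_k >= 1)
  structure(list(alpha = alpha, maternal = maternal, qc = qc,
                 top_k = as.integer(top_k)),
            class = "scan_config")
}

#' Bonferroni-corrected per-SNP significance threshold
#'
#' @param alpha family-wise level.
#' @param n_snps number of SNPs actually tested.
#' @return `alpha / n_snps` (exact division; round only for display).
#' @examples
#' bonferroni_threshold(0.05, 877)   # 5.70e-5 at 3 significant digits
#' @export
bonferroni_threshold <- function(alpha, n_snps) {
  if (length(n_snps) != 1 || is.na(n_snps) || n_snps < 1)
    stop("n_snps must be a positive count")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / n_snps
}

#' Scan a panel for parent-of-origin effects
#'
#' Runs per-SNP quality control (unless disabled), fits the parent-of-origin
#' log-linear model at every passing SNP, and applies a Bonferroni-corrected
#' significance threshold whose denominator is the number of SNPs actually
#' tested (post-QC). Families whose case child is uncalled at a SNP are
#' dropped for that SNP only.
#'
#' @param panel a [trio_panel].
#' @param annotation optional data.frame from [read_annotation()]; when
#'   given, it overrides the panel's SNP metadata (matched by `snp_id`).
#' @param config a [scan_config].
#' @return an object of class `poe_scan`: list with
#'   \describe{
#'     \item{results}{data.frame sorted by ascending p (ties by chromosome,
#'       position): `snp_id`, `alleles` (referent/risk, i.e. major/minor),
#'       `chromosome`, `position`, `gene`, `pathway`, `rr_poe`, `ci_lower`,
#'       `ci_upper`, `p_value`, `n_informative`, `converged`, `significant`,
#'       `top` (row belongs to the top-k summary).}
#'     \item{manhattan}{data.frame `chromosome`, `position`, `snp_id`,
#'       `neglog10_p` (plot-ready).}
#'     \item{rr_by_pathway}{data.frame `pathway`, `snp_id`, `rr_poe` (the
#'       relative-risk distribution product).}
#'     \item{qc_report}{the QC report over all input SNPs.}
#'     \item{threshold}{the Bonferroni per-SNP threshold used.}
#'     \item{n_tested}{Bonferroni denominator.}
#'   }
#' @export
run_scan <- function(panel, annotation = NULL, config = scan_config()) {
  stopifnot(inherits(panel, "trio_panel"), inherits(config, "scan_config"))
  if (!is.null(annotation)) {
    hit <- match(panel$snps$snp_id, annotation$snp_id)
    if (anyNA(hit))
      stop("annotation lacks SNP(s): ",
           paste(panel$snps$snp_id[is.na(hit)], collapse = ", "))
    keep_alleles <- panel$snps[, c("allele_minor", "allele_major")]
    panel$snps <- annotation[hit, , drop = FALSE]
    rownames(panel$snps) <- NULL
    # dosages were computed against the panel's own minor allele; keep it
    panel$snps$allele_minor <- keep_alleles$allele_minor
    panel$snps$allele_major <- keep_alleles$allele_major
  }

  if (!is.null(config$qc)) {
    qcres <- qc_filter(panel, config$qc)
    tested <- qcres$panel
    qc_report <- qcres$report
  } else {
    tested <- panel
    qc_report <- NULL
  }
  nt <- n_snps(tested)
  if (nt == 0L) {
    warning("no SNPs passed QC: empty scan")
    empty <- data.frame()
    return(structure(list(results = empty, manhattan = empty,
                          rr_by_pathway = empty, qc_report = qc_report,
                          threshold = NA_real_, n_tested = 0L),
                     class = "poe_scan"))
  }
  thr <- bonferroni_threshold(config$alpha, nt)

  rows <- lapply(seq_len(nt), function(j) {
    tr <- panel_trios(tested, j)
    tr <- tr[!is.na(tr$c), , drop = FALSE]
    fit <- withCallingHandlers(
      fit_snp(tr[, c("m", "f", "c")], maternal = config$maternal),
      warning = function(w) invokeRestart("muffleWarning"))
    s <- tested$snps[j, ]
    data.frame(snp_id = s$snp_id,
               alleles = paste0(s$allele_major, "/", s$allele_minor),
               chromosome = s$chromosome, position = s$position,
               gene = s$gene, pathway = s$pathway,
               rr_poe = fit$rr_poe, ci_lower = fit$ci95[[1]],
               ci_upper = fit$ci95[[2]], p_value = fit$p_value,
               n_informative = fit$n_informative,
               converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  results$significant <- results$p_value <= thr
  o <- order(results$p_value,
             suppressWarnings(as.numeric(results$chromosome)),
             results$chromosome, results$position)
  results <- results[o, , drop = FALSE]
  rownames(results) <- NULL
  results$top <- seq_len(nrow(results)) <= config$top_k

  manhattan <- data.frame(chromosome = results$chromosome,
                          position = results$position,
                          snp_id = results$snp_id,
                          neglog10_p = -log10(results$p_value),
                          stringsAsFactors = FALSE)
  rr_by_pathway <- results[order(results$pathway, results$snp_id),
                           c("pathway", "snp_id", "rr_poe")]
  rownames(rr_by_pathway) <- NULL

  structure(list(results = results, manhattan = manhattan,
                 rr_by_pathway = rr_by_pathway, qc_report = qc_report,
                 threshold = thr, n_tested = nt),
            class = "poe_scan")
}

#' @export
print.poe_scan <- function(x, ...) {
  cat(sprintf("Parent-of-origin scan: %d SNPs tested, threshold %.3g\n",
              x$n_tested, x$threshold))
  if (x$n_tested > 0) {
    cat(sprintf("  significant SNPs: %d\n", sum(x$results$significant)))
    k <- min(5L, nrow(x$results))
    print(x$results[seq_len(k),
                    c("snp_id", "gene", "pathway", "rr_poe", "p_value",
                      "significant")])
  }
  invisible(x)
}

#' Write scan products as tab-separated files
#'
#' Emits `results.tsv` (the ranked results table), `manhattan.tsv`,
#' `rr_by_pathway.tsv`, `qc_report.tsv` (when QC ran) and `scan_log.txt`
#' (threshold and configuration echo) into a directory.
#'
#' @param scan a `poe_scan` from [run_scan()].
#' @param dir output directory (created if needed).
#' @param config the [scan_config] used (echoed into the log).
#' @return invisibly, the directory path.
#' @export
write_scan <- function(scan, dir, config = scan_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(scan$results, "results.tsv")
  w(scan$manhattan, "manhattan.tsv")
  w(scan$rr_by_pathway, "rr_by_pathway.tsv")
  if (!is.null(scan$qc_report)) w(scan$qc_report, "qc_report.tsv")
  writeLines(c(sprintf("n_tested\t%d", scan$n_tested),
               sprintf("threshold\t%.6g", scan$threshold),
               sprintf("alpha\t%g", config$alpha),
               sprintf("maternal\t%s", config$maternal),
               sprintf("top_k\t%d", config$top_k)),
             file.path(dir, "scan_log.txt"))
  invisible(dir)
}
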