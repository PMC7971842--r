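#' Configuration for the synthetic case-family generator
#'
#' Defaults emulate the study design the package targets: 569 case families
#' ascertained on an affected child, 38.7% of them full trios and the
#' remainder missing one parent (overwhelmingly the father), biallelic SNPs
#' with founder MAF at least 0.05.
#'
#' @param n_families number of case families.
#' @param n_snps number of SNPs.
#' @param maf_range interval within `[0.05, 0.5]` from which each SNP's
#'   founder minor allele frequency is drawn uniformly.
#' @param mafs optional explicit per-SNP MAF vector (overrides `maf_range`).
#' @param signal_snps named list mapping SNP indices (as names, e.g.
#'   `list("3" = poe_params(W = 0.3))`) to true [poe_params]; unlisted SNPs
#'   are simulated under the null (all relative risks 1).
#' @param full_trio_fraction probability a family has both parents genotyped.
#' @param father_missing_given_incomplete probability the missing parent of
#'   an incomplete family is the father.
#' @param nocall_rate per-genotype missing-call probability on top of the
#'   family completeness pattern.
#' @param n_strata 1 (single pooled stratum `"ALL"`) or 2; with 2 strata a
#'   fraction of families is labelled `"POP2"` and its founders are drawn
#'   out of Hardy-Weinberg equilibrium with inbreeding coefficient
#'   `inbreeding_f` (for exercising the stratified HWE filter).
#' @param stratum2_fraction fraction of families in the second stratum.
#' @param inbreeding_f inbreeding coefficient of the second stratum.
#' @param seed integer RNG seed; a fixed seed reproduces the panel exactly.
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(n_families = 569, n_snps = 1,
                       maf_range = c(0.05, 0.5), mafs = NULL,
                       signal_snps = list(),
                       full_trio_fraction = 0.387,
                       father_missing_given_incomplete = 0.9,
                       nocall_rate = 0, n_strata = 1,
                       stratum2_fraction = 0.3, inbreeding_f = 0.15,
                       seed = 1L) {
  stopifnot(n_families >= 1, n_snps >= 1,
            full_trio_fraction >= 0, full_trio_fraction <= 1,
            father_missing_given_incomplete >= 0,
            father_missing_given_incomplete <= 1,
            nocall_rate >= 0, nocall_rate < 1,
            n_strata %in% 1:2)
  if (is.null(mafs)) {
    stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
              maf_range[1] <= maf_range[2])
  } else stopifnot(length(mafs) == n_snps, all(mafs > 0), all(mafs <= 0.5))
  for (p in signal_snps) stopifnot(inherits(p, "poe_params"))
  structure(list(n_families = n_families, n_snps = n_snps,
                 maf_range = maf_range, mafs = mafs,
                 signal_snps = signal_snps,
                 full_trio_fraction = full_trio_fraction,
                 father_missing_given_incomplete = father_missing_given_incomplete,
                 nocall_rate = nocall_rate, n_strata = n_strata,
                 stratum2_fraction = stratum2_fraction,
                 inbreeding_f = inbreeding_f, seed = as.integer(seed)),
            class = "sim_config")
}

# parental genotype probabilities at MAF q with inbreeding coefficient F
genotype_freqs <- function(q, f_inbreed = 0) {
  p <- 1 - q
  c(p^2 + f_inbreed * p * q, 2 * p * q * (1 - f_inbreed),
    q^2 + f_inbreed * p * q)
}

# vectorised ascertained sampling of n case families at one SNP:
# parents under (possibly inbred) random mating, fair Mendelian transmission
# with tracked origin, acceptance proportional to R_c * S_m * (W if the
# child's single minor allele is paternal)
sample_case_families <- function(n, maf, params, f_inbreed = 0) {
  gp <- genotype_freqs(maf, f_inbreed)
  R <- c(1, params$R1, params$R2)
  S <- c(1, params$S1, params$S2)
  cells <- cell_table_cache()
  max_mult <- max(R[cells$c + 1] * S[cells$m + 1] *
                    ifelse(cells$origin == "paternal", params$W, 1))
  if (!is.finite(max_mult) || max_mult <= 0)
    stop("acceptance normalisation failed: non-finite risk multiplier")
  m <- f <- cc <- integer(0)
  while (length(cc) < n) {
    k <- max(100L, ceiling(1.5 * (n - length(cc)) * max_mult))
    mm <- sample(0:2, k, replace = TRUE, prob = gp)
    ff <- sample(0:2, k, replace = TRUE, prob = gp)
    am <- stats::rbinom(k, 1, mm / 2)
    af <- stats::rbinom(k, 1, ff / 2)
    ch <- am + af
    pat <- ch == 1L & af == 1L
    mult <- R[ch + 1] * S[mm + 1] * ifelse(pat, params$W, 1)
    acc <- stats::runif(k) < mult / max_mult
    m <- c(m, mm[acc]); f <- c(f, ff[acc]); cc <- c(cc, ch[acc])
  }
  data.frame(m = m[1:n], f = f[1:n], c = cc[1:n])   # origin tag discarded
}

#' Simulate one ascertained case family at a SNP
#'
#' Parents are drawn under Hardy-Weinberg random mating at the given MAF;
#' each parent transmits an allele fairly, with the parental origin of the
#' child's alleles tracked internally; the family is accepted into the case
#' sample with probability proportional to
#' `R_c * S_m * (W if the single minor allele is paternally derived)`
#' (rejection sampling against the maximum risk multiplier). The origin tag
#' is discarded after acceptance — it is unobservable in real data.
#'
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @param params true [poe_params] of the disease model.
#' @return one-row data.frame with minor-allele dosages `m`, `f`, `c`.
#' @export
simulate_family <- function(maf, params = poe_params()) {
  stopifnot(maf > 0, maf <= 0.5)
  sample_case_families(1L, maf, params)
}

#' Simulate a case-family genotype panel
#'
#' Generates a rectangular panel under the log-linear trio model. Family
#' completeness is assigned once per family, so missingness is family-wise
#' consistent across SNPs: a family is a full trio with probability
#' `full_trio_fraction`, otherwise its father (or mother) is structurally
#' absent. Additional per-genotype no-calls are sprinkled at `nocall_rate`.
#' SNP columns are generated independently (no linkage disequilibrium).
#'
#' The true per-SNP parameters and MAFs are attached as the `truth` element
#' for parameter-recovery tests.
#'
#' @param config a [sim_config].
#' @return a [trio_panel] with an extra `truth` element
#'   (`list(mafs, params)`).
#' @examples
#' p <- simulate_panel(sim_config(n_families = 50, n_snps = 2, seed = 42))
#' p
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_families; ns <- config$n_snps

  stratum <- rep("ALL", nf)
  if (config$n_strata == 2)
    stratum[stats::runif(nf) < config$stratum2_fraction] <- "POP2"

  full <- stats::runif(nf) < config$full_trio_fraction
  father_absent <- !full &
    stats::runif(nf) < config$father_missing_given_incomplete
  mother_absent <- !full & !father_absent

  mafs <- if (is.null(config$mafs))
    stats::runif(ns, config$maf_range[1], config$maf_range[2]) else config$mafs
  null_params <- poe_params()
  truth_params <- rep(list(null_params), ns)
  for (nm in names(config$signal_snps))
    truth_params[[as.integer(nm)]] <- config$signal_snps[[nm]]

  bases <- c("A", "C", "G", "T")
  minor <- sample(bases, ns, replace = TRUE)
  major <- vapply(minor, function(b) sample(setdiff(bases, b), 1), "")
  snps <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(ns)),
    chromosome = as.character(1 + (seq_len(ns) - 1) %% 22),
    position = 1000L + 1000L * seq_len(ns),
    allele_minor = minor, allele_major = unname(major),
    gene = paste0("GENE", 1 + (seq_len(ns) - 1) %/% 5),
    pathway = c("folate", "homocysteine", "transsulfuration",
                "other")[1 + (seq_len(ns) - 1) %% 4],
    stringsAsFactors = FALSE)

  m <- f <- cc <- matrix(NA_integer_, nf, ns)
  for (j in seq_len(ns)) {
    for (s in unique(stratum)) {
      rows <- which(stratum == s)
      fam <- sample_case_families(length(rows), mafs[j], truth_params[[j]],
                                  if (s == "POP2") config$inbreeding_f else 0)
      m[rows, j] <- fam$m; f[rows, j] <- fam$f; cc[rows, j] <- fam$c
    }
  }
  m[mother_absent, ] <- NA_integer_
  f[father_absent, ] <- NA_integer_
  if (config$nocall_rate > 0) {
    drop <- function(x) {
      hit <- matrix(stats::runif(length(x)) < config$nocall_rate, nrow(x))
      x[hit] <- NA_integer_
      x
    }
    pres_m <- !mother_absent; pres_f <- !father_absent
    m[pres_m, ] <- drop(m[pres_m, , drop = FALSE])
    f[pres_f, ] <- drop(f[pres_f, , drop = FALSE])
    cc <- drop(cc)
  }

  families <- data.frame(
    family_id = sprintf("fam%05d", seq_len(nf)),
    stratum = stratum,
    mother_present = !mother_absent,
    father_present = !father_absent,
    stringsAsFactors = FALSE)
  panel <- trio_panel(snps, families, m, f, cc)
  panel$truth <- list(mafs = mafs, params = truth_params)
  panel
}
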