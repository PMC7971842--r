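#' Model parameters for the case-parent trio log-linear model
#'
#' Constructs the parameter set of the log-linear parent-of-origin model:
#' six mating-type stratum weights, child genotype relative risks, maternal
#' genotype relative risks, and the parent-of-origin relative risk.
#'
#' The mating-type strata index the six unordered parental genotype pairs in
#' the fixed order \{2,2\}, \{2,1\}, \{2,0\}, \{1,1\}, \{1,0\}, \{0,0\}
#' (minor-allele dosages). The sixth stratum weight is the identifiability
#' gauge and is fixed at 1; ordered heterogeneous parental pairs within a
#' stratum share the same weight (parental mating symmetry).
#'
#' @param mu numeric vector of 6 positive mating-stratum weights;
#'   `mu[6]` must equal 1 (gauge).
#' @param R1,R2 relative risk of disease for a child carrying 1 resp. 2
#'   copies of the minor allele, versus 0 copies.
#' @param S1,S2 relative risk associated with a mother carrying 1 resp. 2
#'   copies of the minor allele, versus 0 copies (maternal genetic effect).
#' @param W parent-of-origin relative risk: the disease-risk multiplier when
#'   a heterozygous child's single minor allele is paternally derived,
#'   relative to maternally derived. `W = 1` means no imprinting effect.
#' @return an object of class `poe_params` (a named list).
#' @examples
#' poe_params()                      # the null model
#' poe_params(W = 0.3, R1 = 1.2)    # paternal protection, mild child effect
#' @export
poe_params <- function(mu = rep(1, 6), R1 = 1, R2 = 1, S1 = 1, S2 = 1, W = 1) {
  mu <- as.numeric(mu)
  if (length(mu) != 6L) stop("'mu' must have length 6 (one weight per mating stratum)")
  vals <- c(mu, R1, R2, S1, S2, W)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all parameters must be finite and strictly positive")
  if (abs(mu[6] - 1) > 1e-12)
    stop("mu[6] is the identifiability gauge and must equal 1")
  structure(list(mu = mu, R1 = R1, R2 = R2, S1 = S1, S2 = S2, W = W),
            class = "poe_params")
}

#' @export
print.poe_params <- function(x, ...) {
  cat("Case-parent trio log-linear model parameters\n")
  cat("  mating strata mu {2,2},{2,1},{2,0},{1,1},{1,0},{0,0}: ",
      paste(signif(x$mu, 4), collapse = ", "), "\n")
  cat(sprintf("  child RR      R1 = %.4g, R2 = %.4g\n", x$R1, x$R2))
  cat(sprintf("  maternal RR   S1 = %.4g, S2 = %.4g\n", x$S1, x$S2))
  cat(sprintf("  parent-of-origin RR W = %.4g\n", x$W))
  invisible(x)
}

# stratum index of the unordered parental dosage pair {m,f}:
# {2,2}=1, {2,1}=2, {2,0}=3, {1,1}=4, {1,0}=5, {0,0}=6
mating_stratum <- function(m, f) {
  hi <- pmax(m, f); lo <- pmin(m, f)
  ifelse(hi == 2 & lo == 2, 1L,
  ifelse(hi == 2 & lo == 1, 2L,
  ifelse(hi == 2 & lo == 0, 3L,
  ifelse(hi == 1 & lo == 1, 4L,
  ifelse(hi == 1 & lo == 0, 5L, 6L)))))
}

#' Enumerate the case-trio genotype cells of the log-linear model
#'
#' Enumerates every Mendelian-consistent (mother, father, child) minor-allele
#' dosage configuration, together with its mating stratum, Mendelian
#' transmission factor and, for heterozygous children, the parental origin of
#' the single minor allele. The doubly-heterozygous-parent, heterozygous-child
#' configuration (1,1,1) is the only one whose origin is ambiguous; it is
#' split into a maternal-origin and a paternal-origin cell (transmission
#' factor 1/4 each), giving 16 cells over 15 observable genotype categories.
#'
#' The unnormalised cell weight under parameters `theta` is
#' `mu[j] * t * R_c * S_m * (W if origin is paternal)`, with `R_0 = S_0 = 1`.
#'
#' @return a data.frame with one row per cell and columns `m`, `f`, `c`
#'   (dosages), `stratum` (1..6), `t` (transmission factor), `origin`
#'   (`"maternal"`, `"paternal"` or `"none"`), and `category` (the observable
#'   category label `"m/f/c"`).
#' @examples
#' ct <- build_cell_table()
#' nrow(ct)                                   # 16
#' subset(ct, m == 1 & f == 1)                # the Mendelian quartering
#' @export
build_cell_table <- function() {
  rows <- list()
  for (m in 2:0) for (f in 2:0) {
    # alleles transmitted by a parent of dosage d: P(minor) = d/2
    for (am in 0:1) for (af in 0:1) {
      pm <- if (m == 2) (am == 1) * 1 else if (m == 0) (am == 0) * 1 else 0.5
      pf <- if (f == 2) (af == 1) * 1 else if (f == 0) (af == 0) * 1 else 0.5
      t <- pm * pf
      if (t == 0) next
      c_ <- am + af
      origin <- if (c_ == 1L) (if (am == 1) "maternal" else "paternal") else "none"
      key <- paste(m, f, c_, origin, sep = "|")
      if (is.null(rows[[key]])) {
        rows[[key]] <- data.frame(m = m, f = f, c = c_,
                                  stratum = mating_stratum(m, f),
                                  t = t, origin = origin,
                                  stringsAsFactors = FALSE)
      } else {
        rows[[key]]$t <- rows[[key]]$t + t
      }
    }
  }
  ct <- do.call(rbind, rows)
  ct <- ct[order(-ct$m, -ct$f, -ct$c, ct$origin), ]
  rownames(ct) <- NULL
  ct$category <- paste(ct$m, ct$f, ct$c, sep = "/")
  ct
}

# package-lifetime cache: the table is a pure constant
cell_table_cache <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- build_cell_table()
    tab
  }
})

#' Labels of the 15 observable trio genotype categories
#'
#' @return character vector of `"m/f/c"` labels in canonical (cell-table) order.
#' @export
observable_categories <- function() unique(cell_table_cache()$category)

cell_weights <- function(params, cells = cell_table_cache()) {
  stopifnot(inherits(params, "poe_params"))
  R <- c(1, params$R1, params$R2)
  S <- c(1, params$S1, params$S2)
  params$mu[cells$stratum] * cells$t * R[cells$c + 1L] * S[cells$m + 1L] *
    ifelse(cells$origin == "paternal", params$W, 1)
}

#' Cell probabilities of the trio model
#'
#' Normalised probabilities of the 16 case-trio cells under a parameter set.
#' The Poisson log-linear formulation for cell counts is equivalent, for the
#' structural parameters, to this multinomial conditional on the total count.
#'
#' @param params a [poe_params] object.
#' @return numeric vector of 16 probabilities (summing to 1), named by cell
#'   `"m/f/c"` or `"m/f/c:origin"` for the split heterozygous cell.
#' @examples
#' p <- cell_probs(poe_params())
#' sum(p)   # 1
#' @export
cell_probs <- function(params) {
  cells <- cell_table_cache()
  w <- cell_weights(params, cells)
  p <- w / sum(w)
  names(p) <- ifelse(cells$category == "1/1/1",
                     paste0(cells$category, ":", substr(cells$origin, 1, 3)),
                     cells$category)
  p
}

# collapse 16 cell probabilities to the 15 observable categories
observable_probs <- function(params) {
  cells <- cell_table_cache()
  p <- cell_probs(params)
  as.vector(rowsum(p, cells$category, reorder = FALSE))
}

#' Complete-data multinomial log-likelihood
#'
#' Log-likelihood of complete case-trio counts under the log-linear model.
#' Counts may be given per observable category (length 15, canonical order of
#' [observable_categories()]) or per cell (length 16, cell-table order), in
#' which case the two origin cells of the ambiguous (1,1,1) category are
#' summed internally — parental origin is never observable.
#'
#' @param counts numeric vector of nonnegative counts, length 15 or 16.
#' @param params a [poe_params] object.
#' @return the multinomial log-likelihood (a scalar; 0 when all counts are 0).
#' @export
loglik_complete <- function(counts, params) {
  cells <- cell_table_cache()
  if (length(counts) == nrow(cells)) {
    counts <- as.vector(rowsum(as.numeric(counts), cells$category, reorder = FALSE))
  } else if (length(counts) != length(observable_categories())) {
    stop("'counts' must have length 15 (observable categories) or 16 (cells)")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  pi <- observable_probs(params)
  pos <- counts > 0
  sum(counts[pos] * log(pi[pos]))
}

# compatibility matrix: one row per trio pattern (NA = missing member),
# one column per cell; TRUE where the cell is consistent with the observation
compat_matrix <- function(m, f, c, cells = cell_table_cache()) {
  n <- length(c)
  if (any(is.na(c))) stop("case child dosage must not be missing")
  M <- matrix(FALSE, n, nrow(cells))
  for (k in seq_len(nrow(cells))) {
    M[, k] <- (is.na(m) | m == cells$m[k]) &
              (is.na(f) | f == cells$f[k]) &
              (c == cells$c[k])
  }
  M
}

# aggregate trios into unique observed patterns for fast likelihoods:
# returns list(compat = pattern x cell 0/1 matrix, n = pattern counts)
aggregate_patterns <- function(trios) {
  m <- trios$m; f <- trios$f; c <- trios$c
  if (any(is.na(c))) stop("every family entering the model must have a genotyped case child")
  key <- paste(ifelse(is.na(m), ".", m), ifelse(is.na(f), ".", f), c, sep = "/")
  tab <- table(key)
  first <- match(names(tab), key)
  C <- compat_matrix(m[first], f[first], c[first])
  bad <- rowSums(C) == 0
  if (any(bad))
    stop("Mendelian-inconsistent trio pattern(s): ",
         paste(names(tab)[bad], collapse = ", "),
         " (QC should have removed these families)")
  list(compat = C * 1, n = as.numeric(tab), pattern = names(tab))
}

#' Observed-data log-likelihood with missing-parent marginalisation
#'
#' Log-likelihood of a set of case families, each an affected child with
#' zero, one or two genotyped parents. A family's probability is the sum of
#' cell probabilities over all complete cells compatible with the observed
#' members' dosages, marginalising any missing parent under the same
#' mating-stratum parameters; with no missing data this equals
#' [loglik_complete()] on the category counts.
#'
#' @param trios a data.frame with numeric columns `m`, `f`, `c` (minor-allele
#'   dosages 0/1/2, `NA` = missing; `c` must never be `NA`).
#' @param params a [poe_params] object.
#' @return the observed-data log-likelihood (a scalar).
#' @examples
#' tr <- data.frame(m = c(0, 2), f = c(NA, NA), c = c(0, 2))
#' loglik_observed(tr, poe_params())
#' @export
loglik_observed <- function(trios, params) {
  agg <- aggregate_patterns(trios)
  p <- cell_probs(params)
  pfam <- as.vector(agg$compat %*% p)
  sum(agg$n * log(pfam))
}
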