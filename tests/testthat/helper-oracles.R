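# Independent brute-force oracles. These re-derive model quantities from
# first principles (allele-level enumeration) and deliberately share no code
# with the package internals they check.

# enumerate the trio cells by walking every parental allele transmission:
# returns data.frame(m, f, c, origin, prob) where prob is the Mendelian
# transmission probability within the ordered parental pair
oracle_cells <- function() {
  transmit <- function(d) switch(as.character(d),
    "0" = data.frame(a = 0, p = 1),
    "1" = data.frame(a = c(0, 1), p = c(0.5, 0.5)),
    "2" = data.frame(a = 1, p = 1))
  out <- NULL
  for (m in 0:2) for (f in 0:2) {
    tm <- transmit(m); tf <- transmit(f)
    for (i in seq_len(nrow(tm))) for (k in seq_len(nrow(tf))) {
      c_ <- tm$a[i] + tf$a[k]
      origin <- if (c_ != 1) "none" else if (tm$a[i] == 1) "maternal" else "paternal"
      out <- rbind(out, data.frame(m = m, f = f, c = c_, origin = origin,
                                   prob = tm$p[i] * tf$p[k]))
    }
  }
  stats::aggregate(prob ~ m + f + c + origin, data = out, FUN = sum)
}

# stratum of the unordered parental pair, same labelling convention as the
# model ({2,2}=1, {2,1}=2, {2,0}=3, {1,1}=4, {1,0}=5, {0,0}=6)
oracle_stratum <- function(m, f) {
  key <- paste(sort(c(m, f), decreasing = TRUE), collapse = ",")
  match(key, c("2,2", "2,1", "2,0", "1,1", "1,0", "0,0"))
}

# unnormalised cell weight, computed directly from the parameter definition
oracle_weight <- function(cell, pp) {
  R <- c(1, pp$R1, pp$R2); S <- c(1, pp$S1, pp$S2)
  pp$mu[oracle_stratum(cell$m, cell$f)] * cell$prob *
    R[cell$c + 1] * S[cell$m + 1] *
    (if (cell$origin == "paternal") pp$W else 1)
}

oracle_cell_probs <- function(pp, cells = oracle_cells()) {
  w <- vapply(seq_len(nrow(cells)),
              function(i) oracle_weight(cells[i, ], pp), numeric(1))
  cbind(cells, p = w / sum(w))
}

# observed-data log-likelihood by exhaustive compatibility filtering
oracle_loglik_observed <- function(trios, pp) {
  cp <- oracle_cell_probs(pp)
  ll <- 0
  for (i in seq_len(nrow(trios))) {
    ok <- (is.na(trios$m[i]) | cp$m == trios$m[i]) &
          (is.na(trios$f[i]) | cp$f == trios$f[i]) &
          (cp$c == trios$c[i])
    ll <- ll + log(sum(cp$p[ok]))
  }
  ll
}

# Mendelian consistency by enumerating the 2x2 parental allele choices
oracle_mendel <- function(m, f, c) {
  give <- function(d) unique(c(if (d >= 1) 1, if (d <= 1) 0))
  any(outer(give(m), give(f), "+") == c)
}

# exact HWE p-value by full enumeration over heterozygote counts,
# probability-ordering convention
oracle_hwe <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- n1 + 2 * n2
  na <- min(na, 2 * n - na)
  hets <- seq(na %% 2, na, by = 2)
  pr <- vapply(hets, function(h) {
    exp(lchoose(n, (na - h) / 2) + lchoose(n - (na - h) / 2, h) +
          h * log(2) - (lchoose(2 * n, na)))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n1]
  sum(pr[pr <= obs + 1e-12])
}

# random positive parameter set (log-normal draws)
random_params <- function(w_range = c(0.1, 5)) {
  poe_params(mu = c(exp(stats::rnorm(5, 0, 0.5)), 1),
             R1 = exp(stats::rnorm(1, 0, 0.4)),
             R2 = exp(stats::rnorm(1, 0, 0.4)),
             S1 = exp(stats::rnorm(1, 0, 0.3)),
             S2 = exp(stats::rnorm(1, 0, 0.3)),
             W = exp(stats::runif(1, log(w_range[1]), log(w_range[2]))))
}

# hand-built five-SNP panel in which each QC filter trips exactly once
make_qc_fixture <- function() {
  base <- simulate_panel(sim_config(n_families = 60, n_snps = 5,
                                    mafs = c(0.3, 0.3, 0.3, 0.3, 0.5),
                                    full_trio_fraction = 1, seed = 2024))
  # SNP 2: excessive no-calls (30/180 slots > 10%)
  base$m[1:30, 2] <- NA_integer_
  # SNP 3: Mendelian errors in 10/60 complete trios (> 5%)
  hom <- which(base$m[, 3] + base$f[, 3] == 0)[1:10]
  stopifnot(all(!is.na(hom)))
  base$c[hom, 3] <- 2L
  # SNP 4: founder MAF 4/120 < 5% (4 heterozygous mothers, rest wild-type)
  base$m[, 4] <- c(rep(1L, 4), rep(0L, 56))
  base$f[, 4] <- 0L
  base$c[, 4] <- 0L
  base$c[1:4, 4] <- c(0L, 1L, 0L, 1L)
  # SNP 5: gross HWE violation (every founder heterozygous)
  base$m[, 5] <- 1L
  base$f[, 5] <- 1L
  base$c[, 5] <- rep(c(0L, 1L, 2L), 20)
  base
}
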