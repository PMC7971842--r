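test_that("cell table matches allele-transmission enumeration", {
  ct <- build_cell_table()
  oc <- oracle_cells()

  expect_equal(nrow(ct), nrow(oc))      # 16 cells
  expect_equal(nrow(ct), 16L)
  expect_equal(length(observable_categories()), 15L)

  key <- function(d) paste(d$m, d$f, d$c, d$origin)
  hit <- match(key(ct), key(oc))
  expect_false(anyNA(hit))
  expect_equal(ct$t, oc$prob[hit])

  # transmission factors sum to 1 within each of the 9 ordered parental pairs
  sums <- tapply(ct$t, paste(ct$m, ct$f), sum)
  expect_equal(as.numeric(sums), rep(1, 9))

  # only the doubly-heterozygous het-child cell is split by origin
  split_cat <- names(which(table(ct$category) == 2))
  expect_equal(split_cat, "1/1/1")
  expect_setequal(ct$origin[ct$category == "1/1/1"], c("maternal", "paternal"))
  expect_true(all(ct$origin[ct$c != 1] == "none"))
  expect_true(all(ct$origin[ct$c == 1] %in% c("maternal", "paternal")))

  # forced maternal transmission: parents (m=2, f=1) yield only c=2 and
  # c=1-maternal, each with factor 1/2
  sub <- ct[ct$m == 2 & ct$f == 1, ]
  expect_equal(sort(sub$c), c(1, 2))
  expect_equal(sub$t, c(0.5, 0.5))
  expect_equal(sub$origin[sub$c == 1], "maternal")

  # Mendelian quartering for het x het parents
  sub <- ct[ct$m == 1 & ct$f == 1, ]
  expect_equal(nrow(sub), 4L)
  expect_equal(sub$t, rep(0.25, 4))
})

test_that("cell probabilities normalise and respect the weight definition", {
  # null model: probabilities proportional to mu[j] * t alone
  ct <- build_cell_table()
  p0 <- cell_probs(poe_params(mu = c(3, 2, 1, 5, 4, 1)))
  w0 <- c(3, 2, 1, 5, 4, 1)[ct$stratum] * ct$t
  expect_equal(unname(p0), w0 / sum(w0), tolerance = 1e-12)

  # generic parameter point against the independent oracle
  pp <- poe_params(mu = c(1, 2, 1, 4, 2, 1), R1 = 1.5, R2 = 2,
                   S1 = 1.2, S2 = 1.4, W = 0.5)
  op <- oracle_cell_probs(pp)
  key <- function(m, f, c, o) paste(m, f, c, o)
  hit <- match(key(ct$m, ct$f, ct$c, ct$origin),
               key(op$m, op$f, op$c, op$origin))
  expect_equal(unname(cell_probs(pp)), op$p[hit], tolerance = 1e-12)

  # normalisation for random parameter points
  set.seed(11)
  for (i in 1:25) expect_equal(sum(cell_probs(random_params())), 1,
                               tolerance = 1e-12)

  # mirror symmetry at the null: with W = 1 and no maternal-effect
  # asymmetry, the maternal (2,1,1) cell equals its paternal (1,2,1) mirror
  pp <- poe_params(mu = c(1, 3, 2, 1, 2, 1), R1 = 1.4, R2 = 1.9,
                   S1 = 1, S2 = 1, W = 1)
  p <- cell_probs(pp)
  expect_equal(unname(p["2/1/1"]), unname(p["1/2/1"]))
  expect_equal(unname(p["1/0/1"]), unname(p["0/1/1"]))
  expect_equal(unname(p["2/0/1"]), unname(p["0/2/1"]))

  expect_error(poe_params(W = -1), "positive")
  expect_error(poe_params(mu = c(1, 1, 1, 1, 1, 2)), "gauge")
})

test_that("complete-data log-likelihood behaves as a multinomial", {
  pp <- poe_params(mu = c(1, 2, 1, 4, 2, 1), R1 = 1.5, R2 = 2,
                   S1 = 1.2, S2 = 1.4, W = 0.5)
  expect_equal(loglik_complete(rep(0, 15), pp), 0)

  # a single trio in the paternal-origin category (0,2,1): log-likelihood
  # equals log pi(0,2,1) and increases with W
  cnt <- numeric(15)
  cnt[match("0/2/1", observable_categories())] <- 1
  probs <- cell_probs(pp)
  expect_equal(loglik_complete(cnt, pp), log(unname(probs["0/2/1"])))
  lls <- vapply(c(0.3, 0.6, 1, 2, 4),
                function(w) loglik_complete(cnt, poe_params(W = w)),
                numeric(1))
  expect_true(all(diff(lls) > 0))

  # counts proportional to the model's own probabilities sit at a maximum
  set.seed(21)
  cnt <- 500 * as.vector(rowsum(cell_probs(pp), build_cell_table()$category,
                                reorder = FALSE))
  ll_star <- loglik_complete(cnt, pp)
  for (i in 1:20) {
    jit <- random_params()
    expect_lt(loglik_complete(cnt, jit), ll_star + 1e-9)
  }

  # 16-cell input collapses the split cell
  p16 <- 300 * unname(cell_probs(pp))
  p15 <- as.vector(rowsum(p16, build_cell_table()$category, reorder = FALSE))
  expect_equal(loglik_complete(p16, pp), loglik_complete(p15, pp))
})

test_that("observed-data likelihood marginalises missing parents correctly", {
  pp <- poe_params(mu = c(1.2, 0.8, 1, 2.5, 1.5, 1), R1 = 1.3, R2 = 1.7,
                   S1 = 1.1, S2 = 0.9, W = 0.4)
  probs <- cell_probs(pp)

  # father missing, m=0, c=0: only (0,0,0) and (0,1,0) are compatible
  ll <- loglik_observed(data.frame(m = 0, f = NA, c = 0), pp)
  expect_equal(ll, log(unname(probs["0/0/0"] + probs["0/1/0"])))
  # father missing, m=2, c=2
  ll <- loglik_observed(data.frame(m = 2, f = NA, c = 2), pp)
  expect_equal(ll, log(unname(probs["2/2/2"] + probs["2/1/2"])))

  # equals the complete-data likelihood when nothing is missing
  set.seed(31)
  tr <- sample_panel <- simulate_panel(sim_config(n_families = 200, n_snps = 1,
                                                  mafs = 0.3,
                                                  full_trio_fraction = 1,
                                                  seed = 5))
  tr <- panel_trios(sample_panel, 1)
  cnt <- table(factor(paste(tr$m, tr$f, tr$c, sep = "/"),
                      levels = observable_categories()))
  expect_equal(loglik_observed(tr[, c("m", "f", "c")], pp),
               loglik_complete(as.numeric(cnt), pp))

  # marginalisation consistency: summing a hidden parent's values
  # reproduces the complete-trio distribution
  for (mm in 0:2) for (cc in 0:2) {
    direct <- tryCatch(
      exp(loglik_observed(data.frame(m = mm, f = NA, c = cc), pp)),
      error = function(e) NA)
    if (is.na(direct)) next
    by_sum <- 0
    for (ff in 0:2)
      if (oracle_mendel(mm, ff, cc))
        by_sum <- by_sum +
          exp(loglik_observed(data.frame(m = mm, f = ff, c = cc), pp))
    expect_equal(direct, by_sum, tolerance = 1e-12)
  }

  # inconsistent pattern is rejected
  expect_error(loglik_observed(data.frame(m = 0, f = 0, c = 2), pp),
               "inconsistent")
  expect_error(loglik_observed(data.frame(m = 1, f = 1, c = NA), pp),
               "child")
})

test_that("likelihood is parent-label symmetric at the null", {
  # with W = 1 and S1 = S2 = 1, swapping mother and father genotypes in
  # every family leaves the likelihood unchanged
  pp <- poe_params(mu = c(1.5, 0.7, 1.2, 2, 0.9, 1), R1 = 1.4, R2 = 2.2,
                   S1 = 1, S2 = 1, W = 1)
  set.seed(41)
  pan <- simulate_panel(sim_config(n_families = 300, n_snps = 1, mafs = 0.25,
                                   full_trio_fraction = 0.6, seed = 6))
  tr <- panel_trios(pan, 1)[, c("m", "f", "c")]
  swapped <- data.frame(m = tr$f, f = tr$m, c = tr$c)
  expect_equal(loglik_observed(tr, pp), loglik_observed(swapped, pp),
               tolerance = 1e-10)
})
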