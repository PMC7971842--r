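# --- internal parameterisation ----------------------------------------------
#
# The likelihood is maximised over unconstrained log-scale parameters:
#   log mu for every ACTIVE mating stratum except the gauge stratum,
#   log R1, log R2, [log S1, log S2], [log W].
# A stratum none of whose cells is compatible with any observed family is
# inactive: its mu MLE is the boundary value 0, imposed by deleting its
# cells from the model support (the limit mu -> 0) rather than letting the
# optimiser chase -Inf. The gauge stratum (mu = 1) is the {0,0} stratum
# when active, else the highest-index active stratum.
#
# Cell log-weights are linear in the log-scale parameters, so the objective
# carries its exact gradient.

make_objective <- function(agg, maternal, poe, active) {
  cells <- cell_table_cache()
  keep <- cells$stratum %in% active
  cells <- cells[keep, , drop = FALSE]
  C <- agg$compat[, keep, drop = FALSE]
  n <- agg$n
  N <- sum(n)
  gauge <- max(active)
  free_mu <- setdiff(active, gauge)

  X <- cbind(
    vapply(free_mu, function(s) as.numeric(cells$stratum == s),
           numeric(nrow(cells))),
    as.numeric(cells$c == 1), as.numeric(cells$c == 2))
  if (maternal)
    X <- cbind(X, as.numeric(cells$m == 1), as.numeric(cells$m == 2))
  if (poe) X <- cbind(X, as.numeric(cells$origin == "paternal"))
  np <- ncol(X)
  idx <- list(mu = seq_along(free_mu), R = length(free_mu) + 1:2)
  if (maternal) idx$S <- length(free_mu) + 3:4
  if (poe) idx$W <- np
  base <- log(cells$t)

  weights_of <- function(theta) {
    lw <- base + as.vector(X %*% theta)
    exp(lw - max(lw))
  }
  negll <- function(theta) {
    w <- weights_of(theta)
    -(sum(n * log(as.vector(C %*% w))) - N * log(sum(w)))
  }
  grad <- function(theta) {
    w <- weights_of(theta)
    p <- as.vector(C %*% w)
    r <- as.vector(crossprod(C, n / p))          # per-cell responsibility
    -(as.vector(crossprod(X, w * r)) - N * as.vector(crossprod(X, w)) / sum(w))
  }
  list(negll = negll, grad = grad, n_par = np, idx = idx,
       free_mu = free_mu, gauge = gauge, active = active)
}

# deterministic jitter for optimiser restarts, independent of the user's RNG
restart_jitter <- function(n_par, k) {
  if (k == 1) return(rep(0, n_par))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(74000 + k)
  stats::rnorm(n_par, sd = 0.4)
}

optimise_model <- function(obj, n_restarts = 3) {
  best <- NULL
  for (k in seq_len(n_restarts)) {
    start <- restart_jitter(obj$n_par, k)
    fit <- tryCatch(
      stats::optim(start, obj$negll, gr = obj$grad, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(list(par = NULL, loglik = NA, converged = FALSE))
  list(par = best$par, loglik = -best$value,
       converged = best$convergence == 0)
}

theta_to_params <- function(theta, obj, maternal, poe) {
  mu <- rep(0, 6)                    # inactive strata sit at the boundary
  mu[obj$free_mu] <- exp(theta[obj$idx$mu])
  mu[obj$gauge] <- 1
  structure(list(mu = mu,
                 R1 = exp(theta[obj$idx$R[1]]),
                 R2 = exp(theta[obj$idx$R[2]]),
                 S1 = if (maternal) exp(theta[obj$idx$S[1]]) else 1,
                 S2 = if (maternal) exp(theta[obj$idx$S[2]]) else 1,
                 W = if (poe) exp(theta[obj$idx$W]) else 1),
            class = "poe_params")
}

# families whose compatible cell set touches an origin-tagged cell carry
# direct information on the parent-of-origin parameter
count_informative <- function(agg) {
  cells <- cell_table_cache()
  tagged <- cells$origin %in% c("maternal", "paternal")
  hit <- rowSums(agg$compat[, tagged, drop = FALSE]) > 0
  sum(agg$n[hit])
}

#' Wald confidence interval for a relative risk
#'
#' @param logW_hat point estimate on the log scale.
#' @param se_logW its standard error (positive).
#' @param level confidence level.
#' @return named numeric `c(lower, upper)` on the relative-risk scale.
#' @examples
#' wald_ci(log(0.11), 0.49)
#' @export
wald_ci <- function(logW_hat, se_logW, level = 0.95) {
  if (!is.finite(se_logW) || se_logW <= 0) stop("se_logW must be positive")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  c(lower = exp(logW_hat - z * se_logW), upper = exp(logW_hat + z * se_logW))
}

#' Fit the parent-of-origin log-linear model at one SNP
#'
#' Maximises the observed-data multinomial likelihood over mating-stratum
#' weights, child genotype relative risks, optional maternal genotype
#' relative risks, and the parent-of-origin relative risk `W`, on the log
#' scale (quasi-Newton with analytic gradients and deterministic jittered
#' restarts). The null model constrains `W = 1`; the imprinting test is the
#' likelihood-ratio statistic `2(l_full - l_null)` against chi-squared with
#' 1 df. Standard errors come from the numerically differentiated observed
#' information at the optimum; the interval for `W` is Wald on the log
#' scale. Families with a missing parent enter through
#' compatibility-marginalisation ([loglik_observed()]).
#'
#' When no family is compatible with an origin-tagged cell, `W` is not
#' identified: the fit is flagged (`rr_poe = NA`, `p_value = 1`) with a
#' warning.
#'
#' @param trios data.frame with columns `m`, `f`, `c` (dosages, `NA` =
#'   missing parent; `c` never missing), e.g. from [panel_trios()].
#' @param counts alternatively, a numeric vector of complete-trio category
#'   counts (length 15, order of [observable_categories()], or length 16 by
#'   cell); exactly one of `trios`/`counts` must be given. Counts need not
#'   be integers, which permits fitting expected-count tables.
#' @param maternal include maternal genotype relative risks S1, S2
#'   (`FALSE` constrains S1 = S2 = 1).
#' @param level confidence level for the Wald interval.
#' @param n_restarts optimiser restarts from jittered starting points.
#' @return an object of class `poe_fit`: list with `params_hat`
#'   ([poe_params]), `rr_poe` (the MLE of W), `se_logW`, `ci95`,
#'   `loglik_full`, `loglik_null`, `lrt_stat`, `p_value`, `converged`,
#'   `n_informative`, `n_families`.
#' @examples
#' sim <- simulate_panel(sim_config(n_families = 150, n_snps = 1, seed = 7))
#' fit_snp(panel_trios(sim, 1))
#' @export
fit_snp <- function(trios = NULL, counts = NULL, maternal = TRUE,
                    level = 0.95, n_restarts = 3) {
  if (is.null(trios) == is.null(counts))
    stop("supply exactly one of 'trios' or 'counts'")
  if (is.null(trios)) {
    cells <- cell_table_cache()
    if (length(counts) == nrow(cells))
      counts <- as.vector(rowsum(as.numeric(counts), cells$category,
                                 reorder = FALSE))
    cats <- observable_categories()
    if (length(counts) != length(cats))
      stop("'counts' must have length 15 or 16")
    if (any(counts < 0)) stop("counts must be nonnegative")
    keep <- counts > 0
    parts <- do.call(rbind, strsplit(cats[keep], "/"))
    agg <- aggregate_patterns(data.frame(m = as.integer(parts[, 1]),
                                         f = as.integer(parts[, 2]),
                                         c = as.integer(parts[, 3])))
    agg$n <- counts[keep][match(agg$pattern,
                                paste(parts[, 1], parts[, 2], parts[, 3],
                                      sep = "/"))]
  } else {
    agg <- aggregate_patterns(trios)
  }
  n_fam <- sum(agg$n)
  if (n_fam <= 0) stop("no families to fit")

  cells <- cell_table_cache()
  touched <- colSums(agg$compat) > 0
  active <- sort(unique(cells$stratum[touched]))
  n_informative <- count_informative(agg)

  obj_null <- make_objective(agg, maternal, poe = FALSE, active)
  fit_null <- optimise_model(obj_null, n_restarts)

  if (n_informative == 0) {
    warning("no origin-informative families: parent-of-origin RR is not identified")
    params <- if (isTRUE(fit_null$converged))
      theta_to_params(fit_null$par, obj_null, maternal, poe = FALSE) else NULL
    return(structure(list(params_hat = params, rr_poe = NA_real_,
                          se_logW = NA_real_, ci95 = c(NA_real_, NA_real_),
                          loglik_full = fit_null$loglik,
                          loglik_null = fit_null$loglik,
                          lrt_stat = 0, p_value = 1,
                          converged = isTRUE(fit_null$converged),
                          n_informative = 0L, n_families = n_fam),
                     class = "poe_fit"))
  }

  obj_full <- make_objective(agg, maternal, poe = TRUE, active)
  fit_full <- optimise_model(obj_full, n_restarts)
  if (is.null(fit_full$par) || is.null(fit_null$par))
    stop("optimiser failed on all restarts")
  converged <- isTRUE(fit_full$converged) && isTRUE(fit_null$converged)

  params <- theta_to_params(fit_full$par, obj_full, maternal, poe = TRUE)
  logW <- log(params$W)

  H <- tryCatch(stats::optimHess(fit_full$par, obj_full$negll,
                                 gr = obj_full$grad),
                error = function(e) NULL)
  se_logW <- NA_real_
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
    v <- V[obj_full$idx$W, obj_full$idx$W]
    if (is.finite(v) && v > 0) se_logW <- sqrt(v)
  }
  ci <- if (is.finite(se_logW)) wald_ci(logW, se_logW, level)
        else c(lower = NA_real_, upper = NA_real_)

  lrt <- 2 * (fit_full$loglik - fit_null$loglik)
  if (lrt < 0) {
    if (lrt < -1e-8) warning("negative LRT statistic (", signif(lrt, 3),
                             "): optimiser trouble; clipping to 0")
    lrt <- 0
  }
  structure(list(params_hat = params, rr_poe = params$W, se_logW = se_logW,
                 ci95 = ci, loglik_full = fit_full$loglik,
                 loglik_null = fit_null$loglik, lrt_stat = lrt,
                 p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 converged = converged, n_informative = n_informative,
                 n_families = n_fam),
            class = "poe_fit")
}

#' @export
print.poe_fit <- function(x, ...) {
  cat("Parent-of-origin log-linear fit\n")
  cat(sprintf("  families: %d (%d origin-informative)\n",
              round(x$n_families), round(x$n_informative)))
  if (is.na(x$rr_poe)) {
    cat("  W not identified (no origin-informative families)\n")
  } else {
    cat(sprintf("  RR (paternal vs maternal origin) = %.3f (95%% CI %.3f, %.3f)\n",
                x$rr_poe, x$ci95[1], x$ci95[2]))
    cat(sprintf("  LRT = %.3f, p = %.3g%s\n", x$lrt_stat, x$p_value,
                if (x$converged) "" else "  [NOT converged]"))
  }
  invisible(x)
}
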