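#' Collapsed genotype scores
#'
#' Collapses the qualifying variants of a unit into one marker per sample:
#' 0 = no qualifying variant, 1 = only heterozygous qualifying variants,
#' 2 = at least one homozygous qualifying variant. Missing genotypes count as
#' non-carrier for that variant.
#'
#' @param cohort A `cohort_genotype_matrix`.
#' @param unit An [aggregation_unit()] or character vector of packed keys.
#' @return `data.table` with `sample`, `score`.
#' @export
collapse_genotype_scores <- function(cohort, unit) {
  keys <- if (inherits(unit, "aggregation_unit")) unit$member_keys else as.character(unit)
  keys <- intersect(keys, colnames(cohort$dosage))
  d <- cohort$dosage[, keys, drop = FALSE]
  d[is.na(d)] <- 0L
  score <- ifelse(apply(d == 2L, 1L, any), 2L,
                  ifelse(apply(d == 1L, 1L, any), 1L, 0L))
  data.table::data.table(sample = rownames(cohort$dosage), score = as.integer(score))
}

#' Simulate collapsed scores for control cohorts
#'
#' Uses the hypergeometric engine: per iteration the drawn alt alleles of
#' each variant are placed uniformly without replacement into the `2 N`
#' allele slots of `n_controls` individuals, and each individual's collapsed
#' score follows from its slots. The "conservative" summary of simulated
#' carrier counts is configurable: the iteration-wise upper quartile
#' (default) makes control carrier estimates err high, weakening case-control
#' contrast rather than inflating it.
#'
#' @param ac,an Per-variant AC/AN for the ancestry being simulated.
#' @param n_controls Simulated control cohort size.
#' @param iterations Iterations; default `1e4`.
#' @param seed Optional seed.
#' @param summary `"upper_quartile"` (default) or `"mean"`.
#' @return List with `score_counts` (iterations x 3 matrix of score 0/1/2
#'   counts), `summary_counts` (the chosen per-score summary, rounded to
#'   integers summing to `n_controls`), and `carrier_mean`.
#' @export
simulate_control_scores <- function(ac, an, n_controls, iterations = 1e4,
                                    seed = NULL, summary = c("upper_quartile", "mean")) {
  summary <- match.arg(summary)
  if (!is.null(seed)) set.seed(seed)
  m <- .sim_control_scores(as.integer(ac), as.integer(an),
                           as.integer(n_controls), as.integer(iterations))
  colnames(m) <- c("n0", "n1", "n2")
  carriers <- m[, "n1"] + m[, "n2"]
  summ <- if (summary == "mean") colMeans(m) else
    c(NA, stats::quantile(m[, "n1"], 0.75), stats::quantile(m[, "n2"], 0.75))
  # round score-1/2 counts, give the remainder to score 0
  n1 <- round(unname(summ[[2]])); n2 <- round(unname(summ[[3]]))
  counts <- c(n0 = n_controls - n1 - n2, n1 = n1, n2 = n2)
  list(score_counts = m, summary_counts = counts, carrier_mean = mean(carriers))
}

#' Odds ratio from collapsed scores
#'
#' Logistic regression of disease status on the collapsed score; the OR is
#' `exp(coefficient)` with a Wald 95% CI. With binary scores (no
#' homozygotes) this equals the 2x2 carrier cross-product OR. Complete
#' separation (or any non-finite Wald interval) falls back to Firth
#' bias-reduced logistic regression, which always yields a finite estimate.
#'
#' @param case_scores,control_scores Integer score vectors (0/1/2).
#' @return `data.table` with `odds_ratio`, `ci_low`, `ci_high`, `n_cases`,
#'   `n_controls`, `method`.
#' @export
estimate_odds_ratio <- function(case_scores, control_scores) {
  stopifnot(length(case_scores) > 0, length(control_scores) > 0)
  if (all(c(case_scores, control_scores) == 0))
    stop("all collapsed scores are zero in both groups: odds ratio undefined")
  y <- c(rep(1L, length(case_scores)), rep(0L, length(control_scores)))
  x <- c(case_scores, control_scores)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(stats::vcov(fit)["x", "x"])
  method <- "logistic"
  if (!is.finite(beta) || !is.finite(se) || se > 50 || abs(beta) > 25) {
    firth <- .firth_logistic(x, y)
    beta <- firth$beta; se <- firth$se
    method <- "firth"
  }
  z <- stats::qnorm(0.975)
  data.table::data.table(odds_ratio = exp(beta),
                         ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                         n_cases = length(case_scores), n_controls = length(control_scores),
                         method = method)
}

# Firth-penalized logistic regression (Jeffreys prior), Newton iterations;
# single covariate with intercept.
.firth_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XtW <- t(X * w)
    info <- XtW %*% X
    inv <- solve(info)
    h <- rowSums((X %*% inv) * (X * w))   # hat diagonal
    U <- drop(t(X) %*% (y - mu + h * (0.5 - mu)))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(info)))
  list(beta = beta[2], se = se[2])
}

#' Replication permutation test
#'
#' Statistic: total qualifying alleles in cases. The null is built by
#' permuting case/control labels over the pooled individuals;
#' \eqn{p = (\#\{perm \ge observed\} + 1) / (n_{perm} + 1)}.
#'
#' @param case_counts,control_counts Per-individual qualifying-allele counts.
#' @param n_perm Number of permutations; default `1e5` (warns below 1000).
#' @param seed Optional seed.
#' @return List with `p`, `observed`, `n_perm`.
#' @export
replication_permutation_test <- function(case_counts, control_counts,
                                         n_perm = 1e5, seed = NULL) {
  if (n_perm < 1e3) warning("fewer than 1,000 permutations: p-value resolution is poor")
  if (!is.null(seed)) set.seed(seed)
  pooled <- c(case_counts, control_counts)
  n_case <- length(case_counts)
  obs <- sum(case_counts)
  if (sum(pooled) == 0) return(list(p = 1, observed = obs, n_perm = as.integer(n_perm)))
  perm <- vapply(seq_len(n_perm), function(i) sum(pooled[sample.int(length(pooled), n_case)]),
                 numeric(1))
  list(p = (sum(perm >= obs) + 1) / (n_perm + 1), observed = obs,
       n_perm = as.integer(n_perm))
}

#' Power by simulation for a carrier-frequency association
#'
#' Per replicate, case and control alt-allele counts are drawn binomially at
#' the baseline AF and the OR-shifted AF (large-population approximation for
#' controls), tested with a two-sided Fisher exact test on the allele 2x2
#' table; power is the rejection fraction at `alpha`. Reports the smallest
#' grid size reaching the target power.
#'
#' @param carrier_af Baseline allele frequency in controls, in (0, 1).
#' @param odds_ratio Allelic odds ratio in cases; > 0.
#' @param n_cases_grid Integer grid of case counts.
#' @param n_controls Control cohort size; default `1e5`.
#' @param alpha Significance threshold; default `2.5e-6` (exome-wide).
#' @param reps Replicates per grid point; default 200.
#' @param seed Optional seed.
#' @param target_power Default 0.8.
#' @return List with `power` (`data.table` of `n_cases`, `power`) and
#'   `n_required` (smallest grid n reaching `target_power`, `NA` if none).
#' @export
power_by_simulation <- function(carrier_af, odds_ratio, n_cases_grid,
                                n_controls = 1e5, alpha = 2.5e-6, reps = 200,
                                seed = NULL, target_power = 0.8) {
  stopifnot(carrier_af > 0, carrier_af < 1, odds_ratio > 0)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  odds_case <- odds_ratio * carrier_af / (1 - carrier_af)
  af_case <- odds_case / (1 + odds_case)
  pw <- vapply(n_cases_grid, function(n) {
    rej <- vapply(seq_len(reps), function(r) {
      x_case <- stats::rbinom(1, 2 * n, af_case)
      x_ctrl <- stats::rbinom(1, 2 * n_controls, carrier_af)
      tab <- matrix(c(x_case, 2 * n - x_case, x_ctrl, 2 * n_controls - x_ctrl), 2)
      stats::fisher.test(tab)$p.value < alpha
    }, logical(1))
    mean(rej)
  }, numeric(1))
  res <- data.table::data.table(n_cases = as.integer(n_cases_grid), power = pw)
  hit <- res[power >= target_power, n_cases]
  list(power = res, n_required = if (length(hit)) min(hit) else NA_integer_)
}
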