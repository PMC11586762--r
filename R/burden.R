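#' Observed burden of an aggregation unit
#'
#' Alternate-allele count over the unit's member variants, summed over the
#' samples of one ancestry group (a homozygote contributes 2; missing
#' genotypes contribute 0).
#'
#' @param cohort A `cohort_genotype_matrix`.
#' @param unit An [aggregation_unit()] (or character vector of packed keys).
#' @param ancestry Ancestry group to count over (`NULL` = whole cohort).
#' @return Integer allele count `B`.
#' @export
observed_burden <- function(cohort, unit, ancestry = NULL) {
  keys <- if (inherits(unit, "aggregation_unit")) unit$member_keys else as.character(unit)
  if (length(keys) == 0L) stop("empty aggregation unit")
  keys <- intersect(keys, colnames(cohort$dosage))
  rows <- if (is.null(ancestry)) rep(TRUE, nrow(cohort$samples)) else
    cohort$samples$ancestry == ancestry
  if (length(keys) == 0L) return(0L)
  as.integer(sum(cohort$dosage[rows, keys, drop = FALSE], na.rm = TRUE))
}

#' Simulate the null burden distribution by hypergeometric sampling
#'
#' Each iteration simulates a control cohort of `n_pop` individuals: for every
#' member variant, the cohort's alternate-allele count is drawn as
#' \eqn{X_v \sim \mathrm{Hypergeometric}(AN_{pop}, AC_{pop}, 2 N_{pop})}
#' (2N alleles drawn without replacement from the AN database alleles, of
#' which AC are alternate), and the per-iteration aggregate burden is
#' \eqn{X = \sum_v X_v}. Variants are treated as independent, which LD
#' pruning is there to license. Reproducible for a fixed seed.
#'
#' @param ac,an Integer vectors of per-variant AC and AN for one ancestry.
#' @param n_pop Number of individuals in the simulated cohort.
#' @param iterations Monte-Carlo iterations; default `1e6`.
#' @param seed Optional integer seed (otherwise the current RNG state is
#'   used).
#' @param unit_id,ancestry Labels carried on the result.
#' @param n_draws Optional explicit allele draw count (default `2 * n_pop`).
#' @return A `burden_distribution` list: `totals` (per-iteration aggregate
#'   burden), `counts` (histogram over 0..max), `iterations`, `n_pop`,
#'   `unit_id`, `ancestry`, `seed`, and `expected_mean` (the analytic mean
#'   \eqn{\sum AC \cdot 2N / AN}).
#' @export
simulate_burden_distribution <- function(ac, an, n_pop, iterations = 1e6,
                                         seed = NULL, unit_id = NA_character_,
                                         ancestry = NA_character_, n_draws = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ac <- as.integer(ac); an <- as.integer(an)
  if (is.null(n_draws)) n_draws <- 2L * as.integer(n_pop)
  n_draws <- as.integer(n_draws)
  totals <- .sim_burden_totals(ac, an, n_draws, as.integer(iterations))
  structure(list(
    totals = totals,
    counts = tabulate(totals + 1L, nbins = max(totals) + 1L),
    iterations = as.integer(iterations), n_pop = as.integer(n_pop),
    unit_id = unit_id, ancestry = ancestry, seed = seed,
    expected_mean = sum(ifelse(an > 0, ac * n_draws / an, 0))),
    class = "burden_distribution")
}

#' Exact null burden distribution (oracle scale)
#'
#' Exact probability vector of the aggregate burden under the engine's
#' independence assumption, by discrete convolution of the per-variant
#' hypergeometric PMFs. Guarded to small configurations; beyond the guard,
#' use [simulate_burden_distribution()].
#'
#' @inheritParams simulate_burden_distribution
#' @param max_variants Scale guard; default 20.
#' @return Numeric vector `p` with `p[i] = P(X = i - 1)`, summing to 1.
#' @export
exact_burden_distribution <- function(ac, an, n_pop, max_variants = 20, n_draws = NULL) {
  ac <- as.integer(ac); an <- as.integer(an)
  if (length(ac) > max_variants)
    stop("exact distribution guarded to <= ", max_variants,
         " variants; use the Monte Carlo engine")
  if (is.null(n_draws)) n_draws <- 2L * as.integer(n_pop)
  n_draws <- as.integer(n_draws)
  if (any(an < n_draws)) stop("AN smaller than 2*N: population smaller than simulated cohort")
  pmf <- 1
  for (v in seq_along(ac)) {
    kmax <- min(ac[v], n_draws)
    pv <- stats::dhyper(0:kmax, ac[v], an[v] - ac[v], n_draws)
    new <- numeric(length(pmf) + kmax)
    for (k in 0:kmax) new[(1 + k):(length(pmf) + k)] <-
        new[(1 + k):(length(pmf) + k)] + pmf * pv[k + 1]
    pmf <- new
  }
  pmf / sum(pmf)
}

#' Empirical p-value of an observed burden
#'
#' Add-one estimator \eqn{p = (\#\{X \ge B\} + 1) / (n + 1)}, never zero;
#' `p(B = 0) = 1` exactly. [format_pvalue()] renders values that exceed every
#' simulated burden as `"< 1e-06"` (at 1e6 iterations).
#'
#' @param dist A `burden_distribution`.
#' @param B Observed burden.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(dist, B) {
  if (B <= 0) return(1)
  (sum(dist$totals >= B) + 1) / (dist$iterations + 1)
}

#' @rdname empirical_pvalue
#' @param p Empirical p-value.
#' @param iterations Iteration count used to compute it.
#' @export
format_pvalue <- function(p, iterations) {
  ifelse(p <= 1 / (iterations + 1), sprintf("< %.0e", 1 / iterations),
         sprintf("%.3g", p))
}

#' Combine per-ancestry burden distributions
#'
#' The joint null burden is the per-iteration sum across ancestry-specific
#' simulations (shared iteration index), compared with the summed observed
#' burden: `combined p = P(sum_pop X_pop >= sum_pop B_pop)`.
#'
#' @param dists List of `burden_distribution`s with equal iteration counts.
#' @param B_pop Integer vector of observed per-ancestry burdens, same order.
#' @return List with `p`, `B_total`, and the joint `totals`.
#' @export
combine_ancestries <- function(dists, B_pop) {
  stopifnot(length(dists) >= 1L, length(B_pop) == length(dists))
  iters <- vapply(dists, `[[`, integer(1), "iterations")
  if (length(unique(iters)) != 1L) stop("mismatched iteration counts across ancestries")
  joint <- Reduce(`+`, lapply(dists, `[[`, "totals"))
  B_total <- sum(B_pop)
  p <- if (B_total <= 0) 1 else (sum(joint >= B_total) + 1) / (iters[1] + 1)
  list(p = p, B_total = as.integer(B_total), totals = joint)
}

#' Gene-level burden testing across ancestries
#'
#' Orchestrates the engine for a set of aggregation units: per-ancestry
#' hypergeometric simulation from (LD-pruned) summary statistics, empirical
#' per-ancestry p-values, the combined p over the joint distribution, and the
#' `var1` (signal driven by a single variant) and `af5` (cohort AF > 5%
#' versus database AF < 1%) result annotations.
#'
#' @param cohort A filtered, pruned `cohort_genotype_matrix`.
#' @param db A `population_variant_stats` table.
#' @param units List of [aggregation_unit()]s (or a named list of key
#'   vectors).
#' @param qualifying Character vector of qualifying packed keys (already
#'   harmonized/excluded); unit members are intersected with it.
#' @param iterations Iterations per ancestry; default `1e6`.
#' @param seed Optional seed for the whole run.
#' @param min_group_size Minimum ancestry group size tested; default 10.
#' @param ld_flags Optional `filter_flag_set` with `ld_<pop>` flags: a
#'   variant flagged for an ancestry is dropped from that ancestry's
#'   simulation only.
#' @param exome_wide_alpha Significance threshold annotated on results;
#'   default `2.5e-6`.
#' @param af5_cohort,af5_db Thresholds of the `af5` disparity flag; defaults
#'   0.05 and 0.01.
#' @return `data.table` with one row per unit: per-ancestry observed burdens
#'   and p-values (list columns `B_pop`, `p_pop`), `B_total`, `p_combined`,
#'   `n_gt`/`n_eq` (simulated joint burdens strictly above / equal to the
#'   observed total, for calibration diagnostics), `flags`,
#'   `n_variants_observed`, `n_variants_expected_mean`, `significant`.
#' @export
run_gene_burden <- function(cohort, db, units, qualifying = NULL,
                            iterations = 1e6, seed = NULL, min_group_size = 10,
                            ld_flags = NULL, exome_wide_alpha = 2.5e-6,
                            af5_cohort = 0.05, af5_db = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  groups <- table(cohort$samples$ancestry)
  tested <- intersect(ANCESTRIES, names(groups)[groups >= min_group_size])
  if (length(tested) == 0L) stop("no ancestry group reaches the minimum size of ", min_group_size)
  if (is.list(units) && !inherits(units[[1]], "aggregation_unit"))
    units <- mapply(aggregation_unit, names(units), "gene", units, SIMPLIFY = FALSE)

  af_db <- population_af(db)
  res <- lapply(units, function(unit) {
    keys <- unit$member_keys
    if (!is.null(qualifying)) keys <- intersect(keys, qualifying)
    keys_obs <- intersect(keys, colnames(cohort$dosage))
    dbu <- db[data.table::data.table(packed = keys), on = "packed", nomatch = 0L]
    if (length(keys) == 0L) {
      return(data.table::data.table(unit_id = unit$unit_id, level = unit$level,
                                    B_total = NA_integer_, p_combined = NA_real_,
                                    B_pop = list(NULL), p_pop = list(NULL),
                                    flags = "", n_variants_observed = 0L,
                                    n_variants_expected_mean = NA_real_,
                                    significant = NA))
    }
    dists <- list(); B <- integer(0)
    for (p in tested) {
      pk <- dbu$packed
      if (!is.null(ld_flags)) {
        drop <- ld_flags$packed[ld_flags$flag == paste0("ld_", tolower(p))]
        pk <- setdiff(pk, drop)
      }
      dpb <- dbu[packed %in% pk]
      np <- as.integer(groups[[p]])
      dists[[p]] <- simulate_burden_distribution(
        dpb[[paste0("AC_", p)]], dpb[[paste0("AN_", p)]], np,
        iterations = iterations, unit_id = unit$unit_id, ancestry = p)
      B[p] <- observed_burden(cohort, keys_obs, ancestry = p)
    }
    comb <- combine_ancestries(dists, B)
    n_gt <- sum(comb$totals > comb$B_total)
    n_eq <- sum(comb$totals == comb$B_total)
    p_pop <- vapply(tested, function(p) empirical_pvalue(dists[[p]], B[[p]]), numeric(1))

    # annotations: var1 when every observed alt allele comes from one variant
    ac_obs <- cohort_allele_counts(cohort)[keys_obs]
    ac_obs <- ac_obs[!is.na(ac_obs)]
    flags <- character(0)
    if (sum(ac_obs) > 0 && sum(ac_obs > 0) == 1L) flags <- c(flags, "var1")
    # af5: member common in the cohort (> af5_cohort) but rare in the db (< af5_db)
    n_called <- colSums(!is.na(cohort$dosage[, keys_obs, drop = FALSE]))
    af_cohort <- ifelse(n_called > 0, ac_obs[names(n_called)] / (2 * n_called), 0)
    afm <- af_db[data.table::data.table(packed = names(n_called)), on = "packed", nomatch = 0L]
    af_db_max <- apply(as.matrix(afm[, -1]), 1L,
                       function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
    disp <- af_cohort[afm$packed] > af5_cohort & af_db_max < af5_db
    if (any(disp, na.rm = TRUE)) flags <- c(flags, "af5")

    exp_mean <- sum(vapply(dists, `[[`, numeric(1), "expected_mean"))
    data.table::data.table(
      unit_id = unit$unit_id, level = unit$level,
      B_total = comb$B_total, p_combined = comb$p,
      n_gt = n_gt, n_eq = n_eq,
      B_pop = list(B), p_pop = list(p_pop),
      flags = paste(flags, collapse = ","),
      n_variants_observed = sum(ac_obs > 0),
      n_variants_expected_mean = exp_mean,
      significant = comb$p < exome_wide_alpha)
  })
  data.table::rbindlist(res, fill = TRUE)
}

#' Domain-level burden testing
#'
#' Restricts the engine to protein-domain member variants for a shortlist of
#' genes with suggestive gene-level burden. Matching the domain analysis
#' design, no CADD filter is applied (`cadd_min = 0` upstream in
#' [select_qualifying_variants()]). A domain with no mappable variants is
#' reported with `NA`, not dropped.
#'
#' @param cohort,db As in [run_gene_burden()].
#' @param domains `data.table` with `domain_id`, `gene`, and `packed` member
#'   keys (e.g. built by intersecting domain intervals with the annotation).
#' @param gene_results Output of [run_gene_burden()] used for the shortlist.
#' @param shortlist_p Gene-level p threshold; default 0.001.
#' @param ... Passed through to [run_gene_burden()].
#' @return As [run_gene_burden()], one row per (gene, domain).
#' @export
run_domain_burden <- function(cohort, db, domains, gene_results,
                              shortlist_p = 0.001, ...) {
  keep_genes <- gene_results[p_combined < shortlist_p, unit_id]
  dom <- data.table::as.data.table(domains)[gene %in% keep_genes]
  if (nrow(dom) == 0L)
    return(data.table::data.table(unit_id = character(), level = character(),
                                  B_total = integer(), p_combined = numeric()))
  units <- lapply(split(dom, by = c("gene", "domain_id"), sep = "::"), function(d) {
    if (nrow(d) == 0L || all(is.na(d$packed))) return(NULL)
    aggregation_unit(paste0(d$gene[1], "::", d$domain_id[1]), "domain",
                     d$packed[!is.na(d$packed)])
  })
  empty_ids <- names(units)[vapply(units, is.null, logical(1))]
  units <- units[!vapply(units, is.null, logical(1))]
  out <- if (length(units)) run_gene_burden(cohort, db, units, ...) else
    data.table::data.table()
  if (length(empty_ids)) {
    out <- data.table::rbindlist(list(out, data.table::data.table(
      unit_id = empty_ids, level = "domain", B_total = NA_integer_,
      p_combined = NA_real_)), fill = TRUE)
  }
  out
}
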