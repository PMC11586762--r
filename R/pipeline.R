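#' End-to-end gene burden pipeline
#'
#' Convenience orchestration of the full analysis on loaded objects:
#' population and cohort filters, reciprocal harmonization (with an optional
#' low-complexity mask), qualifying-variant selection, cohort LD pruning,
#' per-gene aggregation units from the annotation, and the Monte-Carlo burden
#' test.
#'
#' @param cohort A `cohort_genotype_matrix`.
#' @param db A `population_variant_stats` table.
#' @param annotations Table from [read_annotation_table()].
#' @param lcr Optional mask `GRanges`.
#' @param af_max,cadd_min,consequence_set Qualifying-variant thresholds (see
#'   [select_qualifying_variants()]).
#' @param iterations,seed,min_group_size,exome_wide_alpha Passed to
#'   [run_gene_burden()].
#' @param ld_flags Optional database LD flag set.
#' @param genes Optional subset of gene ids to test.
#' @return List with `results` (the burden table), `qualifying`, `excluded`,
#'   `soft_flags`, `pruned_cohort_ld`.
#' @export
run_burden_pipeline <- function(cohort, db, annotations, lcr = NULL,
                                af_max = 0.01, cadd_min = 20,
                                consequence_set = c("pLOF", "missense", "inframe_indel"),
                                iterations = 1e5, seed = NULL, min_group_size = 10,
                                exome_wide_alpha = 2.5e-6, ld_flags = NULL,
                                genes = NULL) {
  db_flags <- apply_population_filters(db)
  cohort_flags <- site_quality_filters(cohort)
  ac0 <- ac0_flag(cohort)
  if (any(ac0)) cohort_flags <- rbind_flags(
    cohort_flags, filter_flag_set(names(ac0)[ac0], rep("AC0", sum(ac0))))
  union_variants <- unique(data.table::rbindlist(list(
    cohort$variants[, .(chrom, pos, ref, packed)],
    db[, .(chrom, pos, ref, packed)])))
  harm <- reciprocal_harmonize(cohort_flags, db_flags, lcr = lcr,
                               variants = union_variants)
  qualifying <- select_qualifying_variants(annotations, af_max = af_max,
                                           cadd_min = cadd_min,
                                           consequence_set = consequence_set)
  qualifying <- setdiff(qualifying, harm$excluded)
  pruned <- prune_cohort_ld(cohort, keys = qualifying)
  qualifying <- setdiff(qualifying, pruned)
  ann <- annotations
  if (!is.null(genes)) ann <- ann[gene %in% genes]
  units <- split(ann$packed, ann$gene)
  units <- lapply(units, intersect, y = qualifying)
  units <- units[lengths(units) > 0L]
  results <- run_gene_burden(cohort, db, units, qualifying = qualifying,
                             iterations = iterations, seed = seed,
                             min_group_size = min_group_size,
                             ld_flags = ld_flags,
                             exome_wide_alpha = exome_wide_alpha)
  list(results = results, qualifying = qualifying, excluded = harm$excluded,
       soft_flags = harm$soft, pruned_cohort_ld = pruned)
}
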