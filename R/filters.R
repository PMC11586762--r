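#' Hard and soft filter flags
#'
#' A filter flag set is a `data.table` with columns `packed` (variant key),
#' `flag` (name) and `hard` (`TRUE` = exclude, `FALSE` = annotate). Hard
#' flags: `db_qc_fail`, `gnomadDP0`, `ns5000`, `lcr`, `sor`, `missing`, `AC0`.
#' Soft flags: `hwe`, `excesshet`, and the per-ancestry LD flags `ld_eur`,
#' `ld_afr`, `ld_amr`, `ld_sas`, `ld_eas`, `ld_cohort`. Assignment is
#' deterministic given the inputs, and exclusion is reciprocal between cohort
#' and database (see [reciprocal_harmonize()]).
#'
#' @param packed Variant keys.
#' @param flag Flag names.
#' @param hard Logical, hard (exclude) vs soft (annotate).
#' @return A `filter_flag_set` data.table.
#' @export
filter_flag_set <- function(packed = character(), flag = character(), hard = logical()) {
  known_hard <- c(db_qc_fail = TRUE, gnomadDP0 = TRUE, ns5000 = TRUE, lcr = TRUE,
                  sor = TRUE, missing = TRUE, AC0 = TRUE,
                  hwe = FALSE, excesshet = FALSE,
                  ld_eur = FALSE, ld_afr = FALSE, ld_amr = FALSE, ld_sas = FALSE,
                  ld_eas = FALSE, ld_cohort = FALSE)
  if (missing(hard) || length(hard) == 0L) hard <- unname(known_hard[flag])
  dt <- data.table::data.table(packed = as.character(packed),
                               flag = as.character(flag), hard = hard)
  bad <- setdiff(dt$flag, names(known_hard))
  if (length(bad)) stop("unknown filter flag(s): ", paste(bad, collapse = ", "))
  dt <- unique(dt)
  data.table::setattr(dt, "class", c("filter_flag_set", class(dt)))
  dt[]
}

#' Population-derived filters
#'
#' Flags from the control database: `db_qc_fail` (database's own
#' random-forest QC failed), `gnomadDP0` (variant outside the documented
#' exome calling regions, i.e. poorly covered in the database), and `ns5000`
#' (fewer than `min_called` individuals with genotype calls, so summarized
#' allele frequencies may miss rare variation). All three are hard.
#'
#' @param db A `population_variant_stats` table.
#' @param calling_regions Optional `GRanges` of calling regions; when given,
#'   coverage is recomputed by membership, otherwise the table's `covered`
#'   field is used.
#' @param min_called Threshold for `ns5000`; default 5000.
#' @return A `filter_flag_set`.
#' @export
apply_population_filters <- function(db, calling_regions = NULL, min_called = 5000) {
  covered <- if (!is.null(calling_regions)) {
    .in_track(db$chrom, db$pos, db$ref, calling_regions)
  } else db$covered
  rbind_flags(
    filter_flag_set(db$packed[!db$qc_pass], rep("db_qc_fail", sum(!db$qc_pass))),
    filter_flag_set(db$packed[!covered], rep("gnomadDP0", sum(!covered))),
    filter_flag_set(db$packed[db$n_called < min_called],
                    rep("ns5000", sum(db$n_called < min_called))))
}

#' Cohort-derived site quality filters
#'
#' `sor` (strand odds ratio above `sor_max`; hard), `excesshet` (Phred-scaled
#' excess heterozygosity above `excesshet_max`; soft), `hwe` (exact
#' Hardy-Weinberg p below `hwe_p_min`; soft), and `missing` (missing genotype
#' fraction above `missing_max`; hard). A site with no SOR value is skipped
#' for the SOR flag with a warning, never guessed.
#'
#' @param cohort A `cohort_genotype_matrix`.
#' @param sor_max SOR threshold; default 3.
#' @param excesshet_max Phred threshold; default 100.
#' @param hwe_p_min Exact-test p threshold; default 0.001.
#' @param missing_max Missing fraction threshold; default 0.01.
#' @return A `filter_flag_set`.
#' @export
site_quality_filters <- function(cohort, sor_max = 3, excesshet_max = 100,
                                 hwe_p_min = 0.001, missing_max = 0.01) {
  v <- cohort$variants
  if (anyNA(v$SOR))
    warning(sum(is.na(v$SOR)), " site(s) lack SOR and strand counts; sor flag skipped there")
  d <- cohort$dosage
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    hwe_exact_p(sum(d[, j] == 0L, na.rm = TRUE), sum(d[, j] == 1L, na.rm = TRUE),
                sum(d[, j] == 2L, na.rm = TRUE))
  }, numeric(1))
  sor_bad <- !is.na(v$SOR) & v$SOR > sor_max
  eh_bad <- !is.na(v$excess_het) & v$excess_het > excesshet_max
  hwe_bad <- hwe_p < hwe_p_min
  mis_bad <- v$missing_fraction > missing_max
  rbind_flags(
    filter_flag_set(v$packed[sor_bad], rep("sor", sum(sor_bad))),
    filter_flag_set(v$packed[eh_bad], rep("excesshet", sum(eh_bad))),
    filter_flag_set(v$packed[hwe_bad], rep("hwe", sum(hwe_bad))),
    filter_flag_set(v$packed[mis_bad], rep("missing", sum(mis_bad))))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact p-value: the summed probability of all heterozygote
#' configurations with the same allele counts whose conditional probability
#' does not exceed that of the observed configuration.
#'
#' @param hom_ref,het,hom_alt Genotype counts (vectorized).
#' @return Exact p-value(s) in (0, 1].
#' @export
hwe_exact_p <- function(hom_ref, het, hom_alt) {
  mapply(function(aa, ab, bb) {
    n <- aa + ab + bb
    stopifnot(aa >= 0, ab >= 0, bb >= 0, n >= 1)
    n1 <- 2L * min(aa, bb) + ab          # rare allele count
    hets <- seq.int(n1 %% 2L, min(n1, 2L * n - n1), by = 2L)
    logp <- hets * log(2) + lfactorial(n) -
      lfactorial(hets) - lfactorial((n1 - hets) / 2) - lfactorial(n - (n1 + hets) / 2) +
      lfactorial(n1) + lfactorial(2L * n - n1) - lfactorial(2L * n)
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    min(1, sum(p[p <= p[hets == ab] * (1 + 1e-9)]))
  }, hom_ref, het, hom_alt)
}

#' Phred-scaled excess heterozygosity
#'
#' One-sided exact-test evidence for heterozygote excess:
#' \eqn{-10 \log_{10} \Pr(\mathrm{het} \ge \mathrm{observed})} under the same
#' conditional distribution as [hwe_exact_p()]. Used when `ExcessHet` is
#' absent from the VCF INFO field.
#'
#' @inheritParams hwe_exact_p
#' @return Phred-scaled value(s), 0 for monomorphic sites.
#' @export
excess_het_phred <- function(hom_ref, het, hom_alt) {
  mapply(function(aa, ab, bb) {
    n <- aa + ab + bb
    if (n < 1) return(NA_real_)
    n1 <- 2L * min(aa, bb) + ab
    if (n1 == 0L) return(0)
    hets <- seq.int(n1 %% 2L, min(n1, 2L * n - n1), by = 2L)
    logp <- hets * log(2) + lfactorial(n) -
      lfactorial(hets) - lfactorial((n1 - hets) / 2) - lfactorial(n - (n1 + hets) / 2) +
      lfactorial(n1) + lfactorial(2L * n - n1) - lfactorial(2L * n)
    p <- exp(logp - max(logp))
    p <- p / sum(p)
    -10 * log10(max(sum(p[hets >= ab]), .Machine$double.xmin))
  }, hom_ref, het, hom_alt)
}

#' The AC0 genotype-confidence flag
#'
#' A carrier "passes" when its allele balance (het calls) lies in
#' `[ab_range[1], ab_range[2]]` and it is not simultaneously low-depth and
#' low-quality (`DP < dp_min` and `GQ < gq_min`). A site is flagged `AC0`
#' (hard) when it has at least one carrier and none passes: the only
#' genotypes without skewed strand support are the unconfident ones.
#' Homozygous-alt carriers have no defined het allele balance and are judged
#' on depth/quality alone; a carrier with absent AD is likewise not failed on
#' balance.
#'
#' @param cohort A `cohort_genotype_matrix`.
#' @param ab_range Allele-balance pass interval; default `c(0.2, 0.8)`.
#' @param dp_min,gq_min Depth/quality thresholds; defaults 10 and 20.
#' @return Logical vector named by packed key.
#' @export
ac0_flag <- function(cohort, ab_range = c(0.2, 0.8), dp_min = 10, gq_min = 20) {
  d <- cohort$dosage
  ab <- allele_balance(cohort)
  carrier <- !is.na(d) & d >= 1L
  ab_ok <- is.na(ab) | (ab >= ab_range[1] & ab <= ab_range[2])
  lowq <- !is.na(cohort$DP) & !is.na(cohort$GQ) & cohort$DP < dp_min & cohort$GQ < gq_min
  pass <- carrier & ab_ok & !lowq
  flagged <- colSums(carrier) > 0L & colSums(pass) == 0L
  stats::setNames(flagged, colnames(d))
}

#' Select qualifying variants
#'
#' Rarity, deleteriousness and consequence-class selection: allele frequency
#' below `af_max` in every tested ancestry (absent frequencies count as rare),
#' CADD at or above `cadd_min` (a variant without a CADD score is excluded
#' unless `cadd_min = 0`, the domain-analysis setting, where no CADD
#' requirement applies), and consequence in `consequence_set`.
#'
#' @param annotations Table from [read_annotation_table()].
#' @param af_max Per-ancestry AF ceiling; default 0.01.
#' @param cadd_min Phred-scaled CADD floor; default 20 (`0` disables).
#' @param consequence_set Qualifying consequence classes.
#' @return Character vector of packed variant keys.
#' @export
select_qualifying_variants <- function(annotations, af_max = 0.01, cadd_min = 20,
                                       consequence_set = c("pLOF", "missense", "inframe_indel")) {
  afc <- paste0("af_", tolower(ANCESTRIES))
  afm <- as.matrix(data.table::as.data.table(annotations)[, ..afc])
  rare <- rowSums(afm >= af_max, na.rm = TRUE) == 0L
  cadd_ok <- if (cadd_min > 0) {
    !is.na(annotations$cadd_phred) & annotations$cadd_phred >= cadd_min
  } else rep(TRUE, nrow(annotations))
  cons_ok <- annotations$consequence %in% consequence_set
  annotations$packed[rare & cadd_ok & cons_ok]
}

#' Reciprocal harmonization of cohort and database filters
#'
#' A variant hard-flagged in either dataset (or intersecting the
#' low-complexity mask) is excluded from both; soft flags are retained as
#' annotations attached to burden results.
#'
#' @param cohort_flags,db_flags `filter_flag_set`s computed over the union of
#'   variants.
#' @param lcr Optional low-complexity `GRanges` from [build_mask_track()].
#' @param variants Optional `data.table` with `chrom`, `pos`, `ref`, `packed`
#'   (required when `lcr` is given, to test mask membership).
#' @return List with `excluded` (character vector of packed keys), `soft`
#'   (soft-flag annotations), and `flags` (the combined flag set).
#' @export
reciprocal_harmonize <- function(cohort_flags, db_flags,
                                 lcr = NULL, variants = NULL) {
  flags <- rbind_flags(cohort_flags, db_flags)
  if (!is.null(lcr) && length(lcr) > 0L) {
    if (is.null(variants)) stop("variants table required to apply the lcr mask")
    inmask <- .in_track(variants$chrom, variants$pos, variants$ref, lcr)
    flags <- rbind_flags(flags, filter_flag_set(variants$packed[inmask],
                                                rep("lcr", sum(inmask))))
  }
  list(excluded = sort(unique(flags$packed[flags$hard])),
       soft = flags[hard == FALSE],
       flags = flags)
}

# internal: combine flag sets, dropping duplicates
rbind_flags <- function(...) {
  dt <- unique(data.table::rbindlist(list(...), use.names = TRUE))
  data.table::setattr(dt, "class", c("filter_flag_set", class(data.table::data.table())))
  dt[]
}
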