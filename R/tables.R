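#' Packaged worked-example tables
#'
#' The package ships two published tabulations as plain-text fixtures: the
#' rare non-synonymous BTNL8 coding variants observed across three pediatric
#' sequencing cohorts (a MIS-C discovery cohort, an external MIS-C cohort,
#' and a COVID-19 comparator), with protein domain, global allele frequency,
#' CADD score, functional-testing label and per-cohort genotype counts; and
#' the demographic/clinical characteristics of the MIS-C discovery cohort.
#' Multi-variant carriers are encoded in an explicit carrier-groups table so
#' that carrier counts can be derived exactly.
#'
#' @return `load_btnl8_variant_table()`: list with `variants` and
#'   `carrier_groups` data.tables. `load_misc_cohort_table()`: a data.table.
#' @export
load_btnl8_variant_table <- function() {
  list(variants = data.table::fread(system.file("extdata", "btnl8_variants.tsv",
                                                package = "burdenMC"), sep = "\t"),
       carrier_groups = data.table::fread(system.file("extdata", "btnl8_carrier_groups.tsv",
                                                      package = "burdenMC"), sep = "\t"))
}

#' @rdname load_btnl8_variant_table
#' @export
load_misc_cohort_table <- function() {
  data.table::fread(system.file("extdata", "misc_cohort_characteristics.tsv",
                                package = "burdenMC"), sep = "\t")
}

#' Summarize the variant worked-example table
#'
#' Derives the printed summary counts from the variant fixture: the variant
#' set observed in each cohort, their pairwise overlaps and unions, counts by
#' protein domain and by functional-testing label, and per-cohort carrier
#' counts honoring the multi-variant-carrier groups (an individual carrying
#' several variants appears once).
#'
#' @param tab List from [load_btnl8_variant_table()] (or an equivalently
#'   shaped list with `variants` and `carrier_groups`).
#' @return List with `sets` (per-cohort variant name sets), `n_variants`
#'   (per-cohort counts), `overlap` (pairwise overlap counts), `union_misc`
#'   (number of distinct variants across the two MIS-C cohorts), `by_domain`,
#'   `by_functional`, `impaired` (variants labelled Reduced or Loss),
#'   `carriers` (per-cohort individual counts), `carriers_misc_total`.
#' @export
summarize_variant_table <- function(tab = load_btnl8_variant_table()) {
  v <- data.table::as.data.table(tab$variants)
  grp <- data.table::as.data.table(tab$carrier_groups)
  allowed <- c("Normal", "Reduced", "Loss")
  bad <- setdiff(unique(v$functional), allowed)
  if (length(bad))
    stop("unknown functional-testing label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  cohorts <- c(misc_icl = "n_misc_icl", misc_hge = "n_misc_hge", covid19 = "n_covid19")
  sets <- lapply(cohorts, function(col) v$variant[v[[col]] > 0L])
  n_variants <- vapply(sets, length, integer(1))
  pairs <- utils::combn(names(cohorts), 2)
  overlap <- apply(pairs, 2L, function(pr) length(intersect(sets[[pr[1]]], sets[[pr[2]]])))
  names(overlap) <- apply(pairs, 2L, paste, collapse = "&")
  carriers <- vapply(names(cohorts), function(co) {
    total <- sum(v[[cohorts[[co]]]])
    g <- grp[cohort == co]
    dup <- if (nrow(g)) sum(lengths(strsplit(g$variants, "+", fixed = TRUE)) - 1L) else 0L
    as.integer(total - dup)
  }, integer(1))
  list(sets = sets,
       n_variants = n_variants,
       overlap = overlap,
       union_misc = length(union(sets$misc_icl, sets$misc_hge)),
       by_domain = table(v$domain),
       by_functional = table(v$functional),
       impaired = v$variant[v$functional %in% c("Reduced", "Loss")],
       carriers = carriers,
       carriers_misc_total = unname(carriers["misc_icl"] + carriers["misc_hge"]))
}

#' Symptom rate in a cohort-characteristics column
#'
#' Rate (%) of a presenting characteristic within one group of the cohort
#' table, computed from the group size row rather than read off the printed
#' percentage.
#'
#' @param tab Table from [load_misc_cohort_table()].
#' @param characteristic Row name, e.g. `"gastrointestinal"`.
#' @param group One of `"misc"`, `"btnl8"`, `"iei"`.
#' @return Percentage in \[0, 100\].
#' @export
symptom_rate <- function(tab = load_misc_cohort_table(),
                         characteristic = "gastrointestinal",
                         group = c("misc", "btnl8", "iei")) {
  group <- match.arg(group)
  col <- paste0("n_", group)
  sel <- tab[["characteristic"]] == characteristic
  n <- tab[[col]][sel]
  if (length(n) != 1L) stop("characteristic not found: ", characteristic)
  size <- tab[[col]][tab[["category"]] == "group_size"]
  100 * n / size
}
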