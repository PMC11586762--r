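#' Read a variant annotation table
#'
#' TSV with columns `chrom, pos, ref, alt, gene, consequence, cadd_phred,
#' af_eur, af_afr, af_amr, af_sas, af_eas[, domain]`. Consequences must be one
#' of `pLOF`, `missense`, `inframe_indel`, `synonymous`, `other`; `cadd_phred`
#' may be empty (absent score); `domain` is optional.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @param db Optional `population_variant_stats` table; when given, annotation
#'   allele frequencies are checked against `AC/AN` (tolerance `1e-9`).
#' @return `data.table` keyed by `packed` with the columns above.
#' @export
read_annotation_table <- function(path, db = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "cadd_phred",
            paste0("af_", tolower(ANCESTRIES)))
  ann <- data.table::fread(path, sep = "\t", colClasses = list(character = "chrom"))
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  ok <- c("pLOF", "missense", "inframe_indel", "synonymous", "other")
  bad <- setdiff(unique(ann$consequence), ok)
  if (length(bad)) stop("unknown consequence class(es): ", paste(bad, collapse = ", "),
                        " (allowed: ", paste(ok, collapse = ", "), ")")
  if (!"domain" %in% names(ann)) ann[, domain := NA_character_]
  ann[, chrom := sub("^chr", "", as.character(chrom))]
  ann <- .add_variant_keys(ann)
  if (!is.null(db)) {
    af <- population_af(db)
    j <- ann[af, on = "packed", nomatch = 0L]
    for (p in tolower(ANCESTRIES)) {
      a <- j[[paste0("af_", p)]]
      b <- j[[paste0("i.af_", p)]]
      off <- !is.na(a) & !is.na(b) & abs(a - b) > 1e-9
      if (any(off)) stop("annotation af_", p, " inconsistent with database AC/AN for ",
                         sum(off), " variant(s)")
    }
  }
  data.table::setkey(ann, packed)
  ann[]
}

#' Aggregation units for burden testing
#'
#' @param unit_id Unit identifier (gene, domain, pathway or custom name).
#' @param level One of `gene`, `domain`, `pathway`, `custom`.
#' @param member_keys Character vector of packed variant keys.
#' @return A list of class `aggregation_unit`.
#' @export
aggregation_unit <- function(unit_id, level = c("gene", "domain", "pathway", "custom"),
                             member_keys) {
  level <- match.arg(level)
  member_keys <- unique(as.character(member_keys))
  if (length(member_keys) == 0L) stop("aggregation unit '", unit_id, "' has no member variants")
  structure(list(unit_id = unit_id, level = level, member_keys = member_keys),
            class = "aggregation_unit")
}
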