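#' @export
ANCESTRIES <- c("EUR", "AFR", "AMR", "SAS", "EAS")

#' Ancestry labels
#'
#' The five continental ancestry groups used for burden testing, plus
#' `UNKNOWN` for individuals that cannot be assigned (excluded from testing).
#'
#' @param x Character vector of labels.
#' @return `x` validated and normalized to the canonical set.
#' @export
ancestry_label <- function(x) {
  x <- toupper(as.character(x))
  bad <- !x %in% c(ANCESTRIES, "UNKNOWN")
  if (any(bad)) stop("invalid ancestry label(s): ", paste(unique(x[bad]), collapse = ", "),
                     " (allowed: ", paste(c(ANCESTRIES, "UNKNOWN"), collapse = ", "), ")")
  x
}

#' Read an ancestry-stratified population variant table
#'
#' Long-format TSV with header columns
#' `chrom, pos, ref, alt, pop, AC, AN, nhomalt, qc_pass, covered, n_called`,
#' one row per (variant, ancestry). Rows for the same variant are folded into
#' one record with per-ancestry `AC_*`, `AN_*`, `nhomalt_*` columns.
#'
#' Validation: every mandatory column must be present (format error
#' otherwise); `AC > AN` or `2 * nhomalt > AC` is a validation error naming
#' the variant; malformed rows are rejected with their row numbers.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @return A `data.table` of class `population_variant_stats`, one row per
#'   variant, keyed by the packed variant key, with columns `chrom`, `pos`,
#'   `ref`, `alt`, `packed`, `AC_<pop>`, `AN_<pop>`, `nhomalt_<pop>` for each
#'   of the five ancestries, `qc_pass`, `covered`, `n_called`.
#' @export
read_population_table <- function(path) {
  need <- c("chrom", "pos", "ref", "alt", "pop", "AC", "AN", "nhomalt",
            "qc_pass", "covered", "n_called")
  dt <- data.table::fread(path, sep = "\t", colClasses = list(character = "chrom"))
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("population table is missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  dt[, row_nr := .I]
  dt[, chrom := sub("^chr", "", chrom)]
  dt[chrom %in% c("M", "chrM"), chrom := "MT"]
  dt[, pop := ancestry_label(pop)]
  malformed <- dt[is.na(pos) | is.na(AC) | is.na(AN) | AC < 0 | AN < 0 | !pop %in% ANCESTRIES]
  if (nrow(malformed))
    stop("malformed population-table row(s): ", paste(malformed$row_nr, collapse = ", "))
  bad <- dt[AC > AN | 2L * nhomalt > AC]
  if (nrow(bad))
    stop("AC/AN/nhomalt validation failed for variant(s): ",
         paste(unique(bad[, paste0(chrom, ":", pos, ":", ref, ">", alt)]), collapse = ", "))
  as_population_stats(dt)
}

#' Fold a long (variant, ancestry) table into the per-variant container
#'
#' @param dt Long-format `data.table` with the [read_population_table()]
#'   columns.
#' @return A `population_variant_stats` table.
#' @export
as_population_stats <- function(dt) {
  wide <- data.table::dcast(dt, chrom + pos + ref + alt + qc_pass + covered + n_called ~ pop,
                            value.var = c("AC", "AN", "nhomalt"), fill = 0L)
  for (p in ANCESTRIES) {
    for (pref in c("AC_", "AN_", "nhomalt_")) {
      col <- paste0(pref, p)
      if (!col %in% names(wide)) wide[, (col) := 0L]
    }
  }
  wide[, qc_pass := as.logical(qc_pass)]
  wide[, covered := as.logical(covered)]
  wide <- .add_variant_keys(wide)
  cols <- c("chrom", "pos", "ref", "alt", "packed",
            paste0("AC_", ANCESTRIES), paste0("AN_", ANCESTRIES),
            paste0("nhomalt_", ANCESTRIES), "qc_pass", "covered", "n_called")
  wide <- wide[, ..cols]
  data.table::setkey(wide, packed)
  data.table::setattr(wide, "class", c("population_variant_stats", class(wide)))
  wide[]
}

#' Write a population variant table
#'
#' Inverse of [read_population_table()]: unfolds the wide per-variant record
#' back into one row per (variant, ancestry). Ancestries with `AN = 0` are
#' skipped (they carry no information).
#'
#' @param db A `population_variant_stats` table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(db, path) {
  long <- data.table::rbindlist(lapply(ANCESTRIES, function(p) {
    data.table::data.table(
      chrom = db$chrom, pos = db$pos, ref = db$ref, alt = db$alt, pop = p,
      AC = db[[paste0("AC_", p)]], AN = db[[paste0("AN_", p)]],
      nhomalt = db[[paste0("nhomalt_", p)]],
      qc_pass = db$qc_pass, covered = db$covered, n_called = db$n_called)
  }))
  long <- long[AN > 0L]
  data.table::setorder(long, chrom, pos, ref, alt, pop)
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}

#' Per-ancestry allele frequencies from a population table
#'
#' @param db A `population_variant_stats` table.
#' @return `data.table` with `packed` and `af_<pop>` columns (`NA` where
#'   `AN = 0`).
#' @export
population_af <- function(db) {
  out <- db[, .(packed)]
  for (p in ANCESTRIES) {
    an <- db[[paste0("AN_", p)]]
    out[, (paste0("af_", tolower(p))) := ifelse(an > 0, db[[paste0("AC_", p)]] / an, NA_real_)]
  }
  out[]
}
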