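#' r-squared from haplotype co-occurrence counts
#'
#' \eqn{r^2 = (p_{AB} - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))} from the
#' four haplotype counts; a monomorphic margin returns 0 by convention.
#'
#' @param n_AB,n_Ab,n_aB,n_ab Haplotype counts (vectorized).
#' @return r-squared value(s) in \[0, 1\].
#' @export
r2_from_haplotype_counts <- function(n_AB, n_Ab, n_aB, n_ab) {
  tot <- n_AB + n_Ab + n_aB + n_ab
  stopifnot(all(tot >= 1))
  pA <- (n_AB + n_Ab) / tot
  pB <- (n_AB + n_aB) / tot
  D <- n_AB / tot - pA * pB
  den <- pA * (1 - pA) * pB * (1 - pB)
  ifelse(den > 0, D^2 / den, 0)
}

#' Read a pairwise co-occurrence table
#'
#' TSV with columns `chrom_a, pos_a, ref_a, alt_a, chrom_b, pos_b, ref_b,
#' alt_b, pop, n_AB, n_Ab, n_aB, n_ab` (one row per variant pair and
#' ancestry).
#'
#' @param path Path to the TSV.
#' @return `data.table` with packed keys `key_a`, `key_b` and the counts.
#' @export
read_cooccurrence_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("chrom_a", "chrom_b")))
  need <- c("chrom_a", "pos_a", "ref_a", "alt_a", "chrom_b", "pos_b", "ref_b", "alt_b",
            "pop", "n_AB", "n_Ab", "n_aB", "n_ab")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("co-occurrence table is missing column(s): ", paste(miss, collapse = ", "))
  dt[, key_a := encode_variant_key(chrom_a, pos_a, ref_a, alt_a)$packed]
  dt[, key_b := encode_variant_key(chrom_b, pos_b, ref_b, alt_b)$packed]
  dt[, pop := ancestry_label(pop)]
  dt[]
}

#' Flag database variants in high LD, per ancestry
#'
#' Every unordered pair on the same chromosome within `window` bases whose
#' co-occurrence r-squared reaches `r2_min` contributes a prune decision.
#' Within a linked pair the better-called variant (larger `AN` for that
#' ancestry) is retained; ties break toward the smaller packed key. Pruning
#' is selective: a flagged variant's summary statistics are removed only from
#' that ancestry's simulation, leaving other ancestries untouched.
#'
#' @param cooc Table from [read_cooccurrence_table()].
#' @param db A `population_variant_stats` table (for the AN tie-break).
#' @param window Maximum pair distance in bases (sliding); default 10000.
#' @param r2_min Flagging threshold (inclusive, `>=`); default 0.95.
#' @return A `filter_flag_set` of soft per-ancestry flags
#'   (`ld_eur`, ..., `ld_eas`) on the pruned variants.
#' @export
flag_database_ld <- function(cooc, db, window = 10000, r2_min = 0.95) {
  if (window <= 0) stop("window must be positive")
  a <- decode_variant_key(cooc$key_a)
  b <- decode_variant_key(cooc$key_b)
  same <- a$chrom == b$chrom & abs(a$pos - b$pos) <= window
  r2 <- r2_from_haplotype_counts(cooc$n_AB, cooc$n_Ab, cooc$n_aB, cooc$n_ab)
  linked <- cooc[same & r2 >= r2_min]
  if (nrow(linked) == 0L) return(filter_flag_set())
  out <- list()
  for (p in ANCESTRIES) {
    lp <- linked[pop == p]
    if (nrow(lp) == 0L) next
    ancol <- paste0("AN_", p)
    pruned <- .prune_pairs(lp$key_a, lp$key_b,
                           stats::setNames(db[[ancol]], db$packed))
    out[[p]] <- filter_flag_set(pruned, rep(paste0("ld_", tolower(p)), length(pruned)))
  }
  do.call(rbind_flags, out)
}

# greedy pruning over linked pairs: repeatedly drop the variant involved in
# the most unresolved pairs (preferring smaller AN; ties to larger packed key)
# until no pair remains. Removes at most k-1 variants from a k-clique.
.prune_pairs <- function(key_a, key_b, an_lookup) {
  pairs <- data.table::data.table(a = pmin(key_a, key_b), b = pmax(key_a, key_b))
  pairs <- unique(pairs[a != b])
  pruned <- character(0)
  while (nrow(pairs) > 0L) {
    deg <- sort(table(c(pairs$a, pairs$b)), decreasing = TRUE)
    top <- names(deg)[deg == max(deg)]
    an <- an_lookup[top]
    an[is.na(an)] <- 0L
    # drop the worst-called among the most-connected; ties -> larger key
    drop <- top[order(an, -rank(top))][1]
    pruned <- c(pruned, drop)
    pairs <- pairs[a != drop & b != drop]
  }
  sort(pruned)
}

#' Prune linked variants directly on the cohort
#'
#' Genotype-correlation r-squared (squared Pearson correlation of dosage
#' vectors over jointly non-missing samples) for every same-chromosome pair
#' within `window`; pairs with r-squared strictly above `r2_min` are linked
#' (this cohort round uses the strict inequality). Pairs with fewer than two
#' jointly observed samples, or with a monomorphic member, are skipped.
#'
#' @param cohort A `cohort_genotype_matrix`.
#' @param keys Optional subset of packed keys (e.g. qualifying variants only).
#' @param window Maximum pair distance in bases; default 10000.
#' @param r2_min Strict pruning threshold (`>`); default 0.95.
#' @return Character vector of pruned packed keys (flag `ld_cohort`).
#' @export
prune_cohort_ld <- function(cohort, keys = NULL, window = 10000, r2_min = 0.95) {
  if (window <= 0) stop("window must be positive")
  v <- cohort$variants
  if (!is.null(keys)) v <- v[packed %in% keys]
  if (nrow(v) < 2L) return(character(0))
  data.table::setorder(v, chrom, pos)
  link_a <- character(0); link_b <- character(0)
  for (i in seq_len(nrow(v) - 1L)) {
    for (j in (i + 1L):nrow(v)) {
      if (v$chrom[j] != v$chrom[i] || v$pos[j] - v$pos[i] > window) break
      x <- cohort$dosage[, v$packed[i]]
      y <- cohort$dosage[, v$packed[j]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2L) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      if (stats::cor(x[ok], y[ok])^2 > r2_min) {
        link_a <- c(link_a, v$packed[i]); link_b <- c(link_b, v$packed[j])
      }
    }
  }
  if (length(link_a) == 0L) return(character(0))
  # retain the better-genotyped variant of each pair (fewer missing calls)
  called <- colSums(!is.na(cohort$dosage[, v$packed, drop = FALSE]))
  names(called) <- v$packed
  .prune_pairs(link_a, link_b, called)
}
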