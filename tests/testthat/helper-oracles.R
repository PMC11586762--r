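# Independent oracles used across the suite. These deliberately take the
# slow, direct route (brute force / enumeration) and never call the code
# paths they check.

# x10-scaled DUST score of a sequence interval, by direct triplet counting
oracle_dust_score <- function(seq, i, j) {  # 1-based inclusive
  L <- j - i + 1
  if (L < 4) return(0)
  s <- substr(seq, i, j)
  trips <- substring(s, 1:(L - 2), 3:L)
  if (any(grepl("N", trips, fixed = TRUE))) return(NA_real_)
  ct <- table(trips)
  10 * sum(ct * (ct - 1) / 2) / (L - 3)
}

# per-base mask from brute force over all candidate intervals:
# union of "perfect" intervals (no proper subinterval scoring strictly higher)
oracle_dust_mask <- function(seq, threshold = 28, window = 64) {
  n <- nchar(seq)
  score <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in i:min(n, i + window - 1)) {
    if (j - i + 1 >= 4) score[i, j] <- oracle_dust_score(seq, i, j)
  }
  mask <- logical(n)
  for (i in 1:n) for (j in i:min(n, i + window - 1)) {
    s <- score[i, j]
    if (is.na(s) || s < threshold) next
    sub <- score[i:j, i:j, drop = FALSE]
    sub[lower.tri(sub)] <- NA
    sub[1, ncol(sub)] <- NA  # the interval itself
    if (all(is.na(sub) | sub <= s + 1e-12)) mask[i:j] <- TRUE
  }
  mask
}

# per-base boolean array from a 0-based half-open interval table
oracle_base_mask <- function(bed, len) {
  m <- logical(len)
  if (nrow(bed)) for (k in seq_len(nrow(bed))) m[(bed$start[k] + 1):bed$end[k]] <- TRUE
  m
}

# exact HWE het-count pmf by direct product-form computation (no logs)
oracle_hwe_pmf <- function(n1, n) {
  hets <- seq.int(n1 %% 2L, min(n1, 2L * n - n1), by = 2L)
  num <- vapply(hets, function(h) {
    aa <- (n1 - h) / 2
    bb <- n - (n1 + h) / 2
    choose(n, h) * choose(n - h, aa) * 2^h
  }, numeric(1))
  num / sum(num)
}

oracle_hwe_p <- function(aa, ab, bb) {
  n <- aa + ab + bb
  n1 <- 2 * min(aa, bb) + ab
  pmf <- oracle_hwe_pmf(n1, n)
  hets <- seq.int(n1 %% 2L, min(n1, 2L * n - n1), by = 2L)
  min(1, sum(pmf[pmf <= pmf[hets == ab] * (1 + 1e-9)]))
}

# total-variation distance between an empirical count vector (0-based) and an
# exact pmf vector (0-based)
oracle_tv <- function(counts, pmf) {
  len <- max(length(counts), length(pmf))
  c1 <- c(counts, rep(0, len - length(counts))) / sum(counts)
  p1 <- c(pmf, rep(0, len - length(pmf)))
  sum(abs(c1 - p1)) / 2
}

# small in-memory cohort builder for filter/burden toys
toy_cohort <- function(dosage, ancestry = NULL, chrom = "1", pos = NULL,
                       DP = NULL, GQ = NULL, AD_ref = NULL, AD_alt = NULL,
                       SOR = NA_real_) {
  nv <- ncol(dosage)
  ns <- nrow(dosage)
  if (is.null(pos)) pos <- seq(1000, by = 200, length.out = nv)
  if (is.null(ancestry)) ancestry <- rep("EUR", ns)
  ref <- rep("A", nv); alt <- rep("T", nv)
  variants <- data.table::data.table(
    chrom = rep(chrom, nv), pos = pos, ref = ref, alt = alt,
    packed = encode_variant_key(rep(chrom, nv), pos, ref, alt)$packed,
    SOR = rep_len(SOR, nv), excess_het = NA_real_)
  samples <- data.table::data.table(sample = sprintf("S%02d", seq_len(ns)),
                                    ancestry = ancestry)
  cohort_genotype_matrix(samples, variants, dosage, DP = DP, GQ = GQ,
                         AD_ref = AD_ref, AD_alt = AD_alt)
}

# flat population db for toys: same AC/AN in the given ancestries
toy_db <- function(keys_dt, ac, an, ancestries = "EUR", qc_pass = TRUE,
                   covered = TRUE, n_called = 1e5) {
  long <- data.table::rbindlist(lapply(ancestries, function(p) {
    data.table::data.table(chrom = keys_dt$chrom, pos = keys_dt$pos,
                           ref = keys_dt$ref, alt = keys_dt$alt, pop = p,
                           AC = rep_len(ac, nrow(keys_dt)),
                           AN = rep_len(an, nrow(keys_dt)),
                           nhomalt = 0L, qc_pass = qc_pass, covered = covered,
                           n_called = n_called)
  }))
  as_population_stats(long)
}
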