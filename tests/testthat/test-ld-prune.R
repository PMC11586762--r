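test_that("r2 from haplotype counts matches the closed form", {
  expect_equal(r2_from_haplotype_counts(50, 0, 0, 50), 1)
  expect_equal(r2_from_haplotype_counts(25, 25, 25, 25), 0)
  expect_equal(r2_from_haplotype_counts(40, 10, 10, 40), 0.36)
  expect_equal(r2_from_haplotype_counts(100, 0, 50, 0), 0)  # monomorphic margin
})

cooc_fixture <- function(pos_b = 1500L, counts = c(50L, 0L, 0L, 50L), pop = "EUR") {
  data.table::data.table(chrom_a = "1", pos_a = 1000L, ref_a = "A", alt_a = "T",
                         chrom_b = "1", pos_b = pos_b, ref_b = "G", alt_b = "C",
                         pop = pop, n_AB = counts[1], n_Ab = counts[2],
                         n_aB = counts[3], n_ab = counts[4])
}

test_that("database LD flags respect the window and threshold", {
  keys <- data.table::data.table(chrom = "1", pos = c(1000L, 1500L, 11002L),
                                 ref = c("A", "G", "G"), alt = c("T", "C", "C"))
  db <- toy_db(keys, ac = 5L, an = 10000L, ancestries = c("EUR", "AFR"))
  path_tbl <- rbind(
    cooc_fixture(),                                  # 500 bp, r2 = 1 -> flagged
    cooc_fixture(pos_b = 11002L))                    # 10,002 bp away -> outside window
  cooc <- path_tbl
  cooc[, key_a := encode_variant_key(chrom_a, pos_a, ref_a, alt_a)$packed]
  cooc[, key_b := encode_variant_key(chrom_b, pos_b, ref_b, alt_b)$packed]
  flags <- flag_database_ld(cooc, db)
  expect_identical(nrow(flags), 1L)
  expect_identical(flags$flag, "ld_eur")
  expect_false(any(flags$hard))
  # exactly at r2 = 0.95 the pair is flagged (inclusive threshold)
  cooc2 <- cooc_fixture(counts = c(59L, 2L, 1L, 38L))
  r2 <- r2_from_haplotype_counts(59, 2, 1, 38)
  cooc2[, key_a := encode_variant_key(chrom_a, pos_a, ref_a, alt_a)$packed]
  cooc2[, key_b := encode_variant_key(chrom_b, pos_b, ref_b, alt_b)$packed]
  f2 <- flag_database_ld(cooc2, db, r2_min = round(r2, 10))
  expect_identical(nrow(f2), 1L)
})

test_that("a fully linked clique keeps exactly one variant, per ancestry only", {
  keys <- data.table::data.table(chrom = "1", pos = c(1000L, 1200L, 1400L),
                                 ref = "A", alt = "T")
  db <- toy_db(keys, ac = 5L, an = c(8000L, 10000L, 9000L),
               ancestries = c("EUR", "AFR"))
  prs <- data.table::CJ(i = 1:3, j = 1:3)[i < j]
  cooc <- data.table::rbindlist(lapply(seq_len(nrow(prs)), function(r) {
    data.table::data.table(chrom_a = "1", pos_a = keys$pos[prs$i[r]], ref_a = "A",
                           alt_a = "T", chrom_b = "1", pos_b = keys$pos[prs$j[r]],
                           ref_b = "A", alt_b = "T", pop = "EUR",
                           n_AB = 50L, n_Ab = 0L, n_aB = 0L, n_ab = 50L)
  }))
  cooc[, key_a := encode_variant_key(chrom_a, pos_a, ref_a, alt_a)$packed]
  cooc[, key_b := encode_variant_key(chrom_b, pos_b, ref_b, alt_b)$packed]
  db_before <- data.table::copy(db)
  flags <- flag_database_ld(cooc, db)
  expect_identical(nrow(flags), 2L)  # k-1 pruned from a 3-clique
  # the best-called variant (largest AN_EUR == 10000 at pos 1200) is retained
  kept <- setdiff(db$packed, flags$packed)
  expect_true(db[packed == kept, pos] == 1200L)
  expect_true(all(flags$flag == "ld_eur"))  # AFR untouched
  # flagging never mutates the database summary statistics
  expect_identical(as.data.frame(db), as.data.frame(db_before))
})

test_that("cohort LD pruning uses genotype correlation with strict threshold", {
  set.seed(51)
  # v1 == v2 identical columns; v3 independent; v4 monomorphic
  v1 <- sample(0:2, 40, TRUE, prob = c(.7, .2, .1))
  v3 <- sample(0:2, 40, TRUE, prob = c(.7, .2, .1))
  dosage <- cbind(v1, v1, v3, rep(0L, 40))
  storage.mode(dosage) <- "integer"
  cohort <- toy_cohort(dosage, pos = c(1000L, 1100L, 1200L, 1300L))
  pruned <- prune_cohort_ld(cohort)
  expect_identical(length(pruned), 1L)
  expect_true(pruned %in% cohort$variants$packed[1:2])
  # after pruning no retained pair exceeds the threshold (exhaustive toy check)
  kept <- setdiff(cohort$variants$packed, pruned)
  keptd <- cohort$dosage[, kept]
  polym <- apply(keptd, 2, function(x) sd(x) > 0)
  cm <- cor(keptd[, polym])^2
  expect_true(all(cm[upper.tri(cm)] <= 0.95 + 1e-12))
})

test_that("hand-computed toy correlation decides pruning", {
  # two ultra-rare variants never co-carried in 6 samples: r = -1/5, r2 = 0.04
  dosage <- cbind(c(1L, 0L, 0L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L, 0L, 0L))
  cohort <- toy_cohort(dosage, pos = c(1000L, 1050L))
  expect_equal(cor(dosage[, 1], dosage[, 2])^2, 0.04)
  expect_length(prune_cohort_ld(cohort), 0L)
  # perfectly co-carried pair: r2 = 1 > 0.95 -> prune one
  dosage2 <- cbind(c(1L, 1L, 0L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L, 0L, 0L))
  cohort2 <- toy_cohort(dosage2, pos = c(1000L, 1050L))
  expect_length(prune_cohort_ld(cohort2), 1L)
})

test_that("parameter guards fire", {
  expect_error(prune_cohort_ld(toy_cohort(matrix(0L, 2, 2)), window = 0), "positive")
})
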