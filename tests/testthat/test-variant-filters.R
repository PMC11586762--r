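test_that("population filters flag QC failures, coverage and call-rate", {
  keys <- data.table::data.table(chrom = "1", pos = c(100L, 300L, 900L),
                                 ref = "A", alt = "T")
  db <- toy_db(keys, ac = 1L, an = 10000L)
  db[pos == 100L, n_called := 4999L]
  db[pos == 300L, qc_pass := FALSE]
  calling <- intervals("1", 0, 500)  # pos 900 falls outside
  flags <- apply_population_filters(db, calling_regions = calling)
  expect_setequal(flags[flag == "ns5000", packed], db[pos == 100L, packed])
  expect_setequal(flags[flag == "db_qc_fail", packed], db[pos == 300L, packed])
  expect_setequal(flags[flag == "gnomadDP0", packed], db[pos == 900L, packed])
  expect_true(all(flags$hard))
  clean <- toy_db(keys[1], ac = 1L, an = 10000L)
  expect_identical(nrow(apply_population_filters(clean)), 0L)
})

test_that("site quality filters follow the SOR/missing/HWE thresholds", {
  set.seed(41)
  # variant 1: SOR 3.5; variant 2: 2 of 150 missing; variant 3: clean HWE
  dosage <- matrix(0L, 150, 3)
  dosage[1:75, 3] <- c(rep(0L, 25), rep(1L, 50))  # 25/50/25 in first 100 rows
  dosage[76:100, 3] <- 2L
  dosage[1:2, 2] <- NA_integer_
  cohort <- toy_cohort(dosage, SOR = c(3.5, 1.0, 1.0))
  flags <- site_quality_filters(cohort)
  keys <- cohort$variants$packed
  expect_true(keys[1] %in% flags[flag == "sor" & hard == TRUE, packed])
  expect_true(keys[2] %in% flags[flag == "missing" & hard == TRUE, packed])
  expect_false(keys[3] %in% flags[flag == "hwe", packed])  # exact HWE proportions
})

test_that("HWE exact test matches enumeration for all configurations n <= 20", {
  for (n in 1:20) {
    cfg <- data.table::CJ(aa = 0:n, ab = 0:n)[aa + ab <= n][, bb := n - aa - ab]
    got <- hwe_exact_p(cfg$aa, cfg$ab, cfg$bb)
    want <- mapply(oracle_hwe_p, cfg$aa, cfg$ab, cfg$bb)
    expect_equal(got, want, tolerance = 1e-10, info = paste("n =", n))
  }
})

test_that("HWE spec examples hold", {
  expect_equal(hwe_exact_p(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_p(10, 0, 0), 1)
  expect_equal(hwe_exact_p(25, 50, 25), 1)
  # all-het extreme: equals the mass of the most extreme configurations
  expect_equal(hwe_exact_p(0, 50, 0), oracle_hwe_p(0, 50, 0))
  expect_lt(hwe_exact_p(0, 50, 0), 1e-3)
})

test_that("excess heterozygosity is a one-sided Phred-scaled tail", {
  # strong het excess scores high; deficit scores ~0
  expect_gt(excess_het_phred(0, 60, 0), 100)
  expect_equal(excess_het_phred(30, 0, 30), 0)  # P(het >= 0) = 1
  expect_equal(excess_het_phred(10, 0, 0), 0)
})

test_that("AC0 follows the carrier pass-predicate", {
  base <- function(dosage, dp, gq, ad_alt) {
    ad_ref <- dp - ad_alt
    toy_cohort(dosage, DP = dp, GQ = gq, AD_ref = ad_ref, AD_alt = ad_alt)
  }
  # single skewed high-quality carrier -> AC0
  c1 <- base(matrix(c(1L, 0L), 2, 1), matrix(c(50L, 40L), 2, 1),
             matrix(c(99L, 99L), 2, 1), matrix(c(5L, 0L), 2, 1))  # AB = 0.10
  expect_true(unname(ac0_flag(c1)))
  # one skewed + one low-quality balanced carrier -> AC0
  c2 <- base(matrix(c(1L, 1L), 2, 1), matrix(c(40L, 8L), 2, 1),
             matrix(c(99L, 15L), 2, 1), matrix(c(6L, 4L), 2, 1))  # ABs 0.15, 0.5
  expect_true(unname(ac0_flag(c2)))
  # one clean carrier -> no flag
  c3 <- base(matrix(c(1L, 0L), 2, 1), matrix(c(30L, 30L), 2, 1),
             matrix(c(60L, 60L), 2, 1), matrix(c(15L, 0L), 2, 1))
  expect_false(unname(ac0_flag(c3)))
  # no carriers -> nothing to assess
  c4 <- base(matrix(0L, 2, 1), matrix(30L, 2, 1), matrix(60L, 2, 1), matrix(0L, 2, 1))
  expect_false(unname(ac0_flag(c4)))
})

ann_fixture <- function() {
  data.table::data.table(
    packed = sprintf("k%02d", 1:6),
    consequence = c("missense", "missense", "synonymous", "pLOF", "missense", "missense"),
    cadd_phred = c(25, 19.9, 25, 30, NA, 22),
    af_eur = c(0.005, 0.001, 0.001, 0.0001, 0.002, 0.005),
    af_afr = c(0.02, 0.001, 0.001, 0.0001, 0.002, NA),
    af_amr = 0.001, af_sas = 0.001, af_eas = 0.001)
}

test_that("qualifying-variant selection applies AF, CADD and consequence rules", {
  ann <- ann_fixture()
  q <- select_qualifying_variants(ann)
  expect_false("k01" %in% q)  # AF_AFR = 2% fails the every-ancestry rule
  expect_false("k02" %in% q)  # CADD 19.9 below 20
  expect_false("k03" %in% q)  # synonymous
  expect_false("k05" %in% q)  # absent CADD at cadd_min = 20
  expect_setequal(q, c("k04", "k06"))  # absent AF counts as rare
  q0 <- select_qualifying_variants(ann, cadd_min = 0)
  expect_true(all(c("k02", "k04", "k05", "k06") %in% q0))
})

test_that("qualifying set is monotone in cadd_min and af_max", {
  set.seed(43)
  ann <- data.table::data.table(
    packed = sprintf("k%03d", 1:200),
    consequence = sample(c("missense", "pLOF", "synonymous"), 200, TRUE),
    cadd_phred = ifelse(runif(200) < 0.1, NA, runif(200, 0, 40)),
    af_eur = runif(200, 0, 0.03), af_afr = runif(200, 0, 0.03),
    af_amr = runif(200, 0, 0.03), af_sas = runif(200, 0, 0.03),
    af_eas = runif(200, 0, 0.03))
  for (pair in list(c(10, 20), c(20, 30))) {
    lo <- select_qualifying_variants(ann, cadd_min = pair[1])
    hi <- select_qualifying_variants(ann, cadd_min = pair[2])
    expect_true(all(hi %in% lo))
  }
  for (pair in list(c(0.005, 0.01), c(0.01, 0.02))) {
    sm <- select_qualifying_variants(ann, af_max = pair[1])
    lg <- select_qualifying_variants(ann, af_max = pair[2])
    expect_true(all(sm %in% lg))
  }
})

test_that("harmonization is reciprocal, order-independent and honors soft flags", {
  vs <- data.table::data.table(chrom = "1", pos = c(100L, 200L, 300L), ref = "A",
                               packed = c("kA", "kB", "kC"))
  cohort_flags <- filter_flag_set(c("kA", "kB"), c("hwe", "missing"))
  db_flags <- filter_flag_set("kC", "db_qc_fail")
  h <- reciprocal_harmonize(cohort_flags, db_flags)
  # db-hard-only variant excluded everywhere; soft hwe retained as annotation
  expect_setequal(h$excluded, c("kB", "kC"))
  expect_identical(h$soft$packed, "kA")
  h2 <- reciprocal_harmonize(db_flags, cohort_flags)
  expect_identical(h2$excluded, h$excluded)
  # permuting the flag rows never changes the exclusion set
  set.seed(44)
  all_flags <- rbind(cohort_flags, db_flags)
  for (r in 1:5) {
    perm <- all_flags[sample.int(nrow(all_flags))]
    hp <- reciprocal_harmonize(perm[1:2], perm[3])
    expect_identical(hp$excluded, h$excluded)
  }
  # clean variant: retained, unannotated
  expect_false("kD" %in% c(h$excluded, h$soft$packed))
})

test_that("masked positions are excluded reciprocally via the lcr flag", {
  vs <- data.table::data.table(chrom = "1", pos = c(55L, 400L), ref = c("A", "A"),
                               packed = c("kIn", "kOut"))
  lcr <- build_mask_track(dust = intervals("1", 50, 60), pad = 10,
                          chrom_lengths = c(`1` = 1000L))
  h <- reciprocal_harmonize(filter_flag_set(), filter_flag_set(),
                            lcr = lcr, variants = vs)
  expect_identical(h$excluded, "kIn")
  expect_true(all(h$flags[packed == "kIn", flag] == "lcr"))
})
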