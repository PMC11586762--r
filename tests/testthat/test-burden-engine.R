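test_that("observed burden counts alleles with the dosage convention", {
  # 12 het carriers, one of whom carries 3 distinct variants -> 14 alleles
  dosage <- matrix(0L, 20, 3)
  dosage[1:12, 1] <- 1L
  dosage[1, 2] <- 1L
  dosage[1, 3] <- 1L
  cohort <- toy_cohort(dosage)
  expect_identical(observed_burden(cohort, cohort$variants$packed, "EUR"), 14L)
  expect_identical(observed_burden(toy_cohort(matrix(0L, 5, 1)),
                                   "anything"), 0L)
  hom <- toy_cohort(matrix(c(2L, rep(0L, 4)), 5, 1))
  expect_identical(observed_burden(hom, hom$variants$packed), 2L)
  expect_error(observed_burden(cohort, character(0)), "empty")
})

test_that("simulated distribution is a point mass when AC = 0, and deterministic", {
  d <- simulate_burden_distribution(c(0, 0), c(1000, 1000), 10, iterations = 1000,
                                    seed = 61)
  expect_true(all(d$totals == 0L))
  expect_equal(empirical_pvalue(d, 1), 1 / 1001)
  d1 <- simulate_burden_distribution(3, 500, 20, iterations = 5000, seed = 62)
  d2 <- simulate_burden_distribution(3, 500, 20, iterations = 5000, seed = 62)
  expect_identical(d1$totals, d2$totals)
})

test_that("empirical mean tracks the analytic hypergeometric mean", {
  set.seed(63)
  ac <- c(5L, 12L, 40L); an <- c(2000L, 5000L, 10000L)
  d <- simulate_burden_distribution(ac, an, 50, iterations = 1e5)
  expect_equal(d$expected_mean, sum(ac * 100 / an), tolerance = 1e-12)
  expect_lt(abs(mean(d$totals) - d$expected_mean) / d$expected_mean, 0.01)
})

test_that("exact distribution normalizes, convolves and matches hand enumeration", {
  pmf <- exact_burden_distribution(2, 10, 5)
  expect_equal(sum(pmf), 1)
  # draws = 5 alleles: P(X >= 1) = 1 - C(8,5)/C(10,5) = 7/9
  pmf5 <- exact_burden_distribution(2, 10, NULL, n_draws = 5)
  expect_equal(1 - pmf5[1], 7 / 9)
  # two iid variants: pmf equals the self-convolution of one variant's pmf
  one <- exact_burden_distribution(3, 100, 10)
  two <- exact_burden_distribution(c(3, 3), c(100, 100), 10)
  expect_equal(two, convolve(one, rev(one), type = "open"), tolerance = 1e-12)
  expect_error(exact_burden_distribution(rep(1, 25), rep(100, 25), 5), "guarded")
  expect_error(simulate_burden_distribution(5, 10, 10, iterations = 10),
               "population smaller")
})

test_that("Monte Carlo matches the exact oracle on toy grids", {
  set.seed(64)
  configs <- list(list(ac = 2, an = 10, n = 5), list(ac = 20, an = 200, n = 20),
                  list(ac = c(4, 9), an = c(150, 200), n = 12))
  for (cf in configs) {
    d <- simulate_burden_distribution(cf$ac, cf$an, cf$n, iterations = 2e4)
    pmf <- exact_burden_distribution(cf$ac, cf$an, cf$n)
    expect_lt(oracle_tv(d$counts, pmf), 0.02)
  }
})

test_that("empirical p-values follow the add-one rule and monotonicity", {
  d <- simulate_burden_distribution(10, 1000, 20, iterations = 1e4, seed = 65)
  expect_identical(empirical_pvalue(d, 0), 1)
  ps <- vapply(0:10, empirical_pvalue, numeric(1), dist = d)
  expect_true(all(diff(ps) <= 0))
  expect_identical(format_pvalue(1 / (1e6 + 1), 1e6), "< 1e-06")
  expect_identical(format_pvalue(0.5, 1e6), "0.5")
})

test_that("ancestry combination sums iteration-wise and matches the convolution oracle", {
  dA <- simulate_burden_distribution(6, 400, 15, iterations = 1e4, seed = 66)
  expect_equal(combine_ancestries(list(dA), 3)$p, empirical_pvalue(dA, 3))
  dB <- simulate_burden_distribution(9, 700, 25, iterations = 1e4, seed = 67)
  comb <- combine_ancestries(list(dA, dB), c(1, 2))
  pmfA <- exact_burden_distribution(6, 400, 15)
  pmfB <- exact_burden_distribution(9, 700, 25)
  joint <- convolve(pmfA, rev(pmfB), type = "open")
  counts <- tabulate(comb$totals + 1L, nbins = length(joint))
  expect_lt(oracle_tv(counts, joint), 0.02)
  expect_equal(comb$p, (sum(comb$totals >= 3) + 1) / (1e4 + 1))
  dC <- simulate_burden_distribution(1, 100, 10, iterations = 5e3)
  expect_error(combine_ancestries(list(dA, dC), c(1, 1)), "mismatched iteration")
  # point masses at zero: combined p hits the add-one floor
  z1 <- simulate_burden_distribution(0, 100, 5, iterations = 100)
  z2 <- simulate_burden_distribution(0, 100, 5, iterations = 100)
  expect_equal(combine_ancestries(list(z1, z2), c(2, 1))$p, 1 / 101)
})

test_that("run_gene_burden attaches var1 and af5 annotations", {
  set.seed(68)
  keys <- data.table::data.table(chrom = "1", pos = c(1000L, 1200L), ref = "A", alt = "T")
  db <- toy_db(keys, ac = c(2L, 1L), an = 10000L,
               ancestries = c("EUR", "AFR"))
  # 12 EUR + 12 AFR samples; only variant 1 carried, by 3 EUR samples (AF 12.5%)
  dosage <- matrix(0L, 24, 2)
  dosage[1:3, 1] <- 1L
  cohort <- toy_cohort(dosage, ancestry = rep(c("EUR", "AFR"), each = 12),
                       pos = keys$pos)
  units <- list(G1 = cohort$variants$packed)
  res <- run_gene_burden(cohort, db, units, iterations = 2000, seed = 69)
  expect_identical(res$B_total, 3L)
  flags <- strsplit(res$flags, ",")[[1]]
  expect_true("var1" %in% flags)
  expect_true("af5" %in% flags)
  expect_identical(res$n_variants_observed, 1L)
  expect_error(run_gene_burden(cohort, db, units, min_group_size = 50),
               "minimum size")
})

test_that("domain burden equals gene burden when the domain spans the gene", {
  set.seed(70)
  keys <- data.table::data.table(chrom = "2", pos = c(500L, 700L, 900L),
                                 ref = "A", alt = "T")
  db <- toy_db(keys, ac = 3L, an = 8000L)
  dosage <- matrix(0L, 15, 3)
  dosage[1:4, 2] <- 1L
  cohort <- toy_cohort(dosage, chrom = "2", pos = keys$pos)
  units <- list(G2 = cohort$variants$packed)
  gene <- run_gene_burden(cohort, db, units, iterations = 5000, seed = 71,
                          exome_wide_alpha = 0.9)  # force shortlist inclusion
  domains <- data.table::data.table(domain_id = "D1", gene = "G2",
                                    packed = cohort$variants$packed)
  gene_for_shortlist <- data.table::copy(gene)
  gene_for_shortlist[, p_combined := 1e-6]  # make the gene eligible
  dom <- run_domain_burden(cohort, db, domains, gene_for_shortlist,
                           iterations = 5000, seed = 71)
  expect_identical(dom$B_total, gene$B_total)
  expect_equal(dom$p_combined, gene$p_combined)
  # empty domain -> NA row, not dropped
  domains_na <- data.table::data.table(domain_id = "D2", gene = "G2",
                                       packed = NA_character_)
  dom_na <- run_domain_burden(cohort, db, domains_na, gene_for_shortlist,
                              iterations = 1000, seed = 72)
  expect_true(is.na(dom_na$p_combined))
})
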