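pop_tsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("chrom\tpos\tref\talt\tpop\tAC\tAN\tnhomalt\tqc_pass\tcovered\tn_called",
               rows), path)
  path
}

test_that("population table parses and folds per-ancestry rows", {
  path <- pop_tsv(c("1\t100\tA\tT\tEUR\t3\t10000\t0\tTRUE\tTRUE\t5000",
                    "1\t100\tA\tT\tAFR\t5\t8000\t1\tTRUE\tTRUE\t5000",
                    "2\t200\tG\tC\tSAS\t1\t9000\t0\tFALSE\tFALSE\t4000"))
  db <- read_population_table(path)
  expect_s3_class(db, "population_variant_stats")
  expect_identical(nrow(db), 2L)
  v1 <- db[chrom == "1"]
  expect_identical(v1$AC_EUR, 3L)
  expect_identical(v1$AN_EUR, 10000L)
  expect_identical(v1$AC_AFR, 5L)
  expect_identical(v1$nhomalt_AFR, 1L)
  expect_identical(v1$AC_SAS, 0L)  # unseen ancestry folded as 0
  expect_false(db[chrom == "2"]$qc_pass)
})

test_that("population table validation rejects bad rows", {
  expect_error(read_population_table(pop_tsv("1\t100\tA\tT\tEUR\t11\t10\t0\tTRUE\tTRUE\t5000")),
               "1:100:A>T")
  expect_error(read_population_table(pop_tsv("1\t100\tA\tT\tEUR\t4\t10\t3\tTRUE\tTRUE\t5000")),
               "nhomalt")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tAC", "1\t1\tA\tT\t1"), path)
  expect_error(read_population_table(path), "missing mandatory column")
})

test_that("population table round-trips through write/read", {
  cfg <- simulation_config(seed = 11, n_genes = 5, variants_per_gene = 4)
  db <- generate_population_db(cfg)$db
  path <- withr::local_tempfile(fileext = ".tsv")
  write_population_table(db, path)
  back <- read_population_table(path)
  expect_equal(as.data.frame(back), as.data.frame(db))
})

vcf_lines <- function(body, samples = c("S1", "S2", "S3")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"x\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t"),
    body)
}

test_that("cohort VCF reader extracts dosage, AB, DP, GQ and site metrics", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    paste("1", 100, ".", "A", "T", ".", "PASS", "SOR=3.5", "GT:AD:DP:GQ",
          "0/1:5,5:10:99", "0/0:12,0:12:60", "1/1:0,20:20:80", sep = "\t"),
    paste("1", 200, ".", "G", "C", ".", "PASS", ".", "GT:AD:DP:GQ",
          "./.:.:.:.", "0/1:6,2:8:30", "0/0:9,0:9:45", sep = "\t"))), path)
  cohort <- read_cohort_vcf(path, ancestry_map = c(S1 = "EUR", S2 = "AFR"))
  expect_identical(unname(cohort$dosage[, 1]), c(1L, 0L, 2L))
  expect_identical(unname(cohort$dosage[, 2]), c(NA_integer_, 1L, 0L))
  ab <- allele_balance(cohort)
  expect_equal(unname(ab[1, 1]), 0.5)
  expect_equal(unname(ab[2, 2]), 0.25)
  expect_true(is.na(ab[3, 1]))  # hom call: no het allele balance
  expect_identical(unname(cohort$DP[1, 1]), 10L)
  expect_identical(unname(cohort$GQ[1, 1]), 99L)
  expect_equal(cohort$variants$SOR, c(3.5, NA))
  # site 1: 3 alt alleles of 6; ExcessHet recomputed for site 2 only
  expect_identical(unname(cohort_allele_counts(cohort))[1], 3L)
  expect_equal(cohort$variants$missing_fraction, c(0, 1 / 3))
  expect_false(is.na(cohort$variants$excess_het[2]))
  expect_identical(cohort$samples$ancestry, c("EUR", "AFR", "UNKNOWN"))
})

test_that("multiallelic records are refused with normalization advice", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(paste("1", 100, ".", "A", "T,G", ".", "PASS", ".", "GT",
                             "0/1", "0/0", "0/2", sep = "\t")), path)
  expect_error(read_cohort_vcf(path), "multiallelic")
})

test_that("cohort VCF writer round-trips the genotype matrix", {
  cfg <- simulation_config(seed = 12, n_genes = 3, variants_per_gene = 3,
                           ancestries = c(EUR = 12, AFR = 12))
  sim <- generate_population_db(cfg)
  cohort <- generate_cohort(sim, cfg)$cohort
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(cohort, path)
  amap <- stats::setNames(cohort$samples$ancestry, cohort$samples$sample)
  back <- read_cohort_vcf(path, ancestry_map = amap)
  expect_identical(back$dosage, cohort$dosage)
  expect_identical(back$DP, cohort$DP)
  expect_identical(back$GQ, cohort$GQ)
  expect_identical(back$AD_alt, cohort$AD_alt)
  expect_equal(back$variants$SOR, cohort$variants$SOR, tolerance = 1e-8)
  expect_identical(back$samples, cohort$samples)
})

test_that("interval tracks merge, complement and normalize idempotently", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t10\t20", "1\t15\t30", "2\t5\t3"), path)
  expect_warning(track <- read_interval_track(path), "rejected")
  bed <- intervals_to_bed(track)
  expect_equal(bed, data.table::data.table(chrom = "1", start = 10L, end = 30L))
  comp <- complement_intervals(intervals("1", 0, 50), c(`1` = 100L))
  expect_equal(intervals_to_bed(comp),
               data.table::data.table(chrom = "1", start = 50L, end = 100L))
  adj <- normalize_intervals(intervals(c("1", "1"), c(0, 5), c(5, 9)))
  expect_equal(intervals_to_bed(adj),
               data.table::data.table(chrom = "1", start = 0L, end = 9L))
  # idempotence + per-base oracle on fuzzed tracks
  set.seed(7)
  for (rep in 1:20) {
    st <- sample.int(80, 12, replace = TRUE)
    tr <- intervals("1", st, st + sample.int(15, 12, replace = TRUE))
    n1 <- normalize_intervals(tr)
    expect_identical(intervals_to_bed(normalize_intervals(n1)), intervals_to_bed(n1))
    expect_identical(oracle_base_mask(intervals_to_bed(n1), 120),
                     oracle_base_mask(intervals_to_bed(tr), 120))
  }
})

test_that("interval round trip through BED preserves the track", {
  tr <- normalize_intervals(intervals(c("1", "1", "X"), c(0, 50, 7), c(10, 70, 20)))
  path <- withr::local_tempfile(fileext = ".bed")
  write_interval_track(tr, path)
  expect_identical(intervals_to_bed(read_interval_track(path)), intervals_to_bed(tr))
})

test_that("aggregation units validate their member sets", {
  expect_error(aggregation_unit("g1", "gene", character(0)), "no member")
  u <- aggregation_unit("g1", "gene", c("k1", "k2", "k1"))
  expect_identical(u$member_keys, c("k1", "k2"))
})
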