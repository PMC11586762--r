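#' Cohort genotype matrix
#'
#' Container for a joint-genotyped cohort: per-sample ancestry labels, the
#' variant table with site-level metrics, and samples x variants matrices of
#' alternate-allele dosage (0/1/2, `NA` = missing), read depth, genotype
#' quality, and per-allele read depths (from which allele balance is derived
#' for heterozygous calls).
#'
#' @param samples `data.table` with columns `sample`, `ancestry`.
#' @param variants `data.table` with `chrom`, `pos`, `ref`, `alt`, `packed`,
#'   `SOR`, `excess_het`, `missing_fraction`.
#' @param dosage,DP,GQ,AD_ref,AD_alt Samples x variants matrices (rows =
#'   samples, columns = packed variant keys).
#' @return An object of class `cohort_genotype_matrix`.
#' @export
cohort_genotype_matrix <- function(samples, variants, dosage, DP = NULL, GQ = NULL,
                                   AD_ref = NULL, AD_alt = NULL) {
  samples <- data.table::as.data.table(samples)
  variants <- data.table::as.data.table(variants)
  stopifnot(nrow(dosage) == nrow(samples), ncol(dosage) == nrow(variants))
  dimn <- list(samples$sample, variants$packed)
  dimnames(dosage) <- dimn
  blank <- function(m) {
    if (is.null(m)) m <- matrix(NA_integer_, nrow(dosage), ncol(dosage))
    dimnames(m) <- dimn
    m
  }
  variants[, missing_fraction := colMeans(is.na(dosage))]
  obj <- structure(list(samples = samples, variants = variants, dosage = dosage,
                        DP = blank(DP), GQ = blank(GQ),
                        AD_ref = blank(AD_ref), AD_alt = blank(AD_alt)),
                   class = "cohort_genotype_matrix")
  obj
}

#' @export
print.cohort_genotype_matrix <- function(x, ...) {
  cat("cohort_genotype_matrix:", nrow(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  tab <- table(x$samples$ancestry)
  cat("  ancestry:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Allele balance matrix
#'
#' Fraction of alt-supporting reads, `AD_alt / (AD_ref + AD_alt)`, defined for
#' heterozygous calls only (`NA` elsewhere, including where AD is absent).
#'
#' @param cohort A `cohort_genotype_matrix`.
#' @return Numeric samples x variants matrix.
#' @export
allele_balance <- function(cohort) {
  tot <- cohort$AD_ref + cohort$AD_alt
  ab <- ifelse(cohort$dosage == 1L & tot > 0, cohort$AD_alt / tot, NA_real_)
  dimnames(ab) <- dimnames(cohort$dosage)
  ab
}

#' Read a cohort VCF into a genotype matrix
#'
#' Expects VCF v4.2/4.3 with FORMAT `GT:AD:DP:GQ` (missing FORMAT fields give
#' `NA` metrics, never silent zeros) and biallelic records; a multiallelic
#' record raises an error instructing upstream normalization
#' (`bcftools norm -m -`). Site `SOR` and `ExcessHet` are taken from INFO when
#' present; `ExcessHet` is otherwise recomputed from the cohort genotype
#' counts ([excess_het_phred()]), while `SOR` cannot be recomputed without
#' strand counts and stays `NA`.
#'
#' @param path VCF path (optionally bgzipped).
#' @param ancestry_map Named character vector, sample id to ancestry label;
#'   samples absent from the map are labelled `UNKNOWN`.
#' @return A `cohort_genotype_matrix`.
#' @export
read_cohort_vcf <- function(path, ancestry_map = character()) {
  vcf <- VariantAnnotation::readVcf(path)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  if (any(n_alt != 1L))
    stop("multiallelic record(s) at row(s) ",
         paste(head(which(n_alt != 1L), 5L), collapse = ", "),
         ": split multiallelics upstream (e.g. 'bcftools norm -m -') before loading")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- sub("^chr", "", as.character(GenomeInfoDb::seqnames(rr)))
  chrom[chrom %in% c("M", "chrM")] <- "MT"
  variants <- data.table::data.table(
    chrom = chrom, pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt_list)))
  variants <- .add_variant_keys(variants)

  g <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(g)) stop("VCF FORMAT field GT is mandatory")
  gt <- t(g$GT)  # samples x variants
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dosage[gt %in% c("0/0", "0|0")] <- 0L
  dosage[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gt %in% c("1/1", "1|1")] <- 2L

  pick_int <- function(field) {
    if (!field %in% names(g)) return(NULL)
    m <- t(g[[field]])
    storage.mode(m) <- "integer"
    m
  }
  DP <- pick_int("DP")
  GQ <- pick_int("GQ")
  AD_ref <- AD_alt <- NULL
  if ("AD" %in% names(g)) {
    ad <- g$AD  # variants x samples array/list
    if (is.list(ad)) {
      AD_ref <- t(apply(ad, c(1, 2), function(x) if (length(x[[1]]) >= 1) x[[1]][1] else NA_integer_))
      AD_alt <- t(apply(ad, c(1, 2), function(x) if (length(x[[1]]) >= 2) x[[1]][2] else NA_integer_))
    } else if (length(dim(ad)) == 3L) {
      AD_ref <- t(ad[, , 1])
      AD_alt <- t(ad[, , 2])
    }
    if (!is.null(AD_ref)) storage.mode(AD_ref) <- "integer"
    if (!is.null(AD_alt)) storage.mode(AD_alt) <- "integer"
  }

  info <- VariantAnnotation::info(vcf)
  getinfo <- function(field) {
    if (field %in% names(info)) as.numeric(info[[field]]) else rep(NA_real_, nrow(variants))
  }
  variants[, SOR := getinfo("SOR")]
  variants[, excess_het := getinfo("ExcessHet")]
  if (anyNA(variants$excess_het)) {
    # recompute from genotype counts where absent (Phred-scaled one-sided exact test)
    for (j in which(is.na(variants$excess_het))) {
      d <- dosage[, j]
      data.table::set(variants, i = j, j = "excess_het",
                      value = excess_het_phred(sum(d == 0L, na.rm = TRUE),
                                               sum(d == 1L, na.rm = TRUE),
                                               sum(d == 2L, na.rm = TRUE)))
    }
  }

  samp <- colnames(vcf)
  anc <- rep("UNKNOWN", length(samp))
  hit <- samp %in% names(ancestry_map)
  anc[hit] <- ancestry_label(ancestry_map[samp[hit]])
  cohort_genotype_matrix(
    samples = data.table::data.table(sample = samp, ancestry = anc),
    variants = variants, dosage = dosage, DP = DP, GQ = GQ,
    AD_ref = AD_ref, AD_alt = AD_alt)
}

#' Write a cohort genotype matrix as VCF v4.2
#'
#' Emits `GT:AD:DP:GQ` genotypes and `SOR`/`ExcessHet` INFO fields; the
#' round trip through [read_cohort_vcf()] reproduces dosages, depths and
#' qualities exactly.
#'
#' @param cohort A `cohort_genotype_matrix`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=ExcessHet,Number=1,Type=Float,Description=\"Phred-scaled excess heterozygosity\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            cohort$samples$sample), collapse = "\t")), con)
  gt_str <- matrix("./.", nrow(cohort$dosage), ncol(cohort$dosage))
  gt_str[which(cohort$dosage == 0L)] <- "0/0"
  gt_str[which(cohort$dosage == 1L)] <- "0/1"
  gt_str[which(cohort$dosage == 2L)] <- "1/1"
  fmt_int <- function(m) ifelse(is.na(m), ".", as.character(m))
  ad <- paste0(fmt_int(cohort$AD_ref), ",", fmt_int(cohort$AD_alt))
  ad[is.na(cohort$AD_ref) & is.na(cohort$AD_alt)] <- "."
  cell <- matrix(paste(gt_str, ad, fmt_int(cohort$DP), fmt_int(cohort$GQ), sep = ":"),
                 nrow(cohort$dosage))
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, digits = 10, trim = TRUE, scientific = FALSE))
  info <- paste0("SOR=", fmt_num(v$SOR), ";ExcessHet=", fmt_num(v$excess_het))
  info <- gsub("SOR=\\.;", "", info)
  info <- sub(";ExcessHet=\\.$", "", info)
  info[info == ""] <- "."
  lines <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], ".", v$ref[j], v$alt[j], ".", "PASS", info[j],
            "GT:AD:DP:GQ", cell[, j]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Per-site alternate allele counts in the cohort
#'
#' @param cohort A `cohort_genotype_matrix`.
#' @param samples Optional subset of sample ids.
#' @return Integer vector named by packed key: sum of dosages over non-missing
#'   genotypes.
#' @export
cohort_allele_counts <- function(cohort, samples = NULL) {
  d <- cohort$dosage
  if (!is.null(samples)) d <- d[rownames(d) %in% samples, , drop = FALSE]
  cnt <- colSums(d, na.rm = TRUE)
  stats::setNames(as.integer(cnt), names(cnt))
}
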