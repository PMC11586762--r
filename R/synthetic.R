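#' Simulation configuration
#'
#' The stated world of the synthetic generator, at desk scale: four ancestry
#' groups of 40 samples each (a diverse ~160-sample cohort), 2,000 genes of 8
#' variants, allele frequencies log-uniform in `[1e-5, 5e-3]` (all below the
#' 1% rarity ceiling), half the variants with Phred CADD above 20, and
#' realistic gnomAD-v2-exome-like per-ancestry allele numbers. Genotype noise
#' defaults: 0.1% missing genotypes, 2% low-quality genotypes, mild
#' allele-balance noise.
#'
#' @param seed Integer seed.
#' @param ancestries Named integer vector of cohort group sizes.
#' @param an Named integer vector of database allele numbers per ancestry.
#' @param n_genes,variants_per_gene Gene grid dimensions.
#' @param af_range Log-uniform allele-frequency range.
#' @param cadd_hi_fraction Fraction of variants with CADD >= 20.
#' @param spike Optional list: `gene_id`, `odds_ratio` (carrier-level) to
#'   plant an enriched gene.
#' @param missing_rate,lowq_fraction,ab_noise_sd Genotype-noise parameters.
#' @param n_called Database individuals with genotype calls per variant.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              ancestries = c(EUR = 40, AFR = 40, AMR = 40, SAS = 40),
                              an = c(EUR = 113000, AFR = 16000, AMR = 35000,
                                     SAS = 30000, EAS = 18000),
                              n_genes = 2000, variants_per_gene = 8,
                              af_range = c(1e-5, 5e-3), cadd_hi_fraction = 0.5,
                              spike = NULL, missing_rate = 0.001,
                              lowq_fraction = 0.02, ab_noise_sd = 0.05,
                              n_called = 120000) {
  stopifnot(all(ancestries > 0), all(an > 0),
            af_range[1] > 0, af_range[2] < 1, af_range[1] < af_range[2],
            missing_rate >= 0, missing_rate <= 1,
            lowq_fraction >= 0, lowq_fraction <= 1,
            cadd_hi_fraction >= 0, cadd_hi_fraction <= 1)
  structure(list(seed = seed, ancestries = ancestries, an = an,
                 n_genes = n_genes, variants_per_gene = variants_per_gene,
                 af_range = af_range, cadd_hi_fraction = cadd_hi_fraction,
                 spike = spike, missing_rate = missing_rate,
                 lowq_fraction = lowq_fraction, ab_noise_sd = ab_noise_sd,
                 n_called = n_called),
            class = "simulation_config")
}

#' Generate a synthetic population database and annotation table
#'
#' Per-gene variant sets with per-ancestry allele counts drawn binomially at
#' log-uniform base frequencies (with mild per-ancestry jitter), CADD scores
#' with a configurable fraction above 20, consequence classes at exome-like
#' proportions, and annotation AFs exactly equal to `AC/AN`. Deterministic
#' under the config seed.
#'
#' @param config A [simulation_config()].
#' @return List with `db` (`population_variant_stats`) and `annotations`.
#' @export
generate_population_db <- function(config) {
  set.seed(config$seed)
  nv <- config$n_genes * config$variants_per_gene
  gene <- rep(sprintf("GENE%04d", seq_len(config$n_genes)),
              each = config$variants_per_gene)
  chrom <- as.character(rep_len(1:22, config$n_genes))[match(gene, unique(gene))]
  gene_start <- (match(gene, unique(gene)) %/% 22L + 1L) * 100000L
  pos <- gene_start + (seq_len(nv) - 1L) %% config$variants_per_gene * 150L + 1L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  base_af <- exp(stats::runif(nv, log(config$af_range[1]), log(config$af_range[2])))
  long <- data.table::rbindlist(lapply(names(config$an), function(p) {
    af_p <- pmin(base_af * exp(stats::rnorm(nv, 0, 0.3)), 0.009)
    AN <- as.integer(config$an[[p]])
    AC <- stats::rbinom(nv, AN, af_p)
    nhom <- stats::rbinom(nv, AC %/% 2L, pmin(af_p * 2, 1))
    data.table::data.table(chrom = chrom, pos = pos, ref = ref, alt = alt, pop = p,
                           AC = AC, AN = AN, nhomalt = pmin(nhom, AC %/% 2L),
                           qc_pass = TRUE, covered = TRUE,
                           n_called = as.integer(config$n_called))
  }))
  db <- as_population_stats(long)
  af <- population_af(db)
  keyed <- data.table::data.table(packed = encode_variant_key(chrom, pos, ref, alt)$packed,
                                  gene = gene, idx = seq_len(nv))
  cadd_hi <- stats::runif(nv) < config$cadd_hi_fraction
  cadd <- ifelse(cadd_hi, stats::runif(nv, 20, 40), stats::runif(nv, 0, 19.9))
  consequence <- sample(c("missense", "pLOF", "synonymous", "other"), nv,
                        replace = TRUE, prob = c(0.70, 0.10, 0.15, 0.05))
  ann <- data.table::data.table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                                gene = gene, consequence = consequence,
                                cadd_phred = round(cadd, 2), domain = NA_character_,
                                packed = keyed$packed)
  ann <- af[ann, on = "packed"]
  data.table::setcolorder(ann, c("chrom", "pos", "ref", "alt", "gene", "consequence",
                                 "cadd_phred", paste0("af_", tolower(ANCESTRIES)),
                                 "domain", "packed"))
  data.table::setkey(ann, packed)
  list(db = db, annotations = ann)
}

#' Generate a synthetic cohort from the population database
#'
#' Null genes are sampled exactly under the burden engine's assumptions: per
#' variant and ancestry group of `N` individuals, the cohort alternate-allele
#' count is drawn as `Hypergeometric(AN, AC, 2N)` and the alleles are placed
#' uniformly into the group's `2N` allele slots. A spiked gene instead draws
#' per-individual genotypes at an OR-inflated carrier frequency. Genotype
#' noise (missing calls, low-quality DP/GQ, allele-balance jitter) is applied
#' afterwards. The truth manifest records the spiked gene, target odds ratio
#' and carrier ids.
#'
#' @param sim Output of [generate_population_db()].
#' @param config The same [simulation_config()].
#' @param genes Optional subset of gene ids to include (default: all; use a
#'   subset to keep cohort matrices small).
#' @return List with `cohort` (a `cohort_genotype_matrix`) and `truth`
#'   (manifest list).
#' @export
generate_cohort <- function(sim, config, genes = NULL) {
  set.seed(config$seed + 1L)
  db <- sim$db
  ann <- sim$annotations
  if (!is.null(genes)) ann <- ann[gene %in% genes]
  v <- db[data.table::data.table(packed = ann$packed), on = "packed", nomatch = 0L]
  v <- v[match(ann$packed, v$packed)]
  nv <- nrow(v)
  sizes <- config$ancestries
  samples <- data.table::data.table(
    sample = sprintf("S%03d", seq_len(sum(sizes))),
    ancestry = rep(names(sizes), sizes))
  N <- nrow(samples)
  dosage <- matrix(0L, N, nv)

  spike_gene <- if (!is.null(config$spike)) config$spike$gene_id else NA_character_
  is_spike <- !is.na(spike_gene) & ann$gene == spike_gene
  for (p in names(sizes)) {
    rows <- which(samples$ancestry == p)
    np <- length(rows)
    ACp <- v[[paste0("AC_", p)]]
    ANp <- v[[paste0("AN_", p)]]
    for (j in seq_len(nv)) {
      if (is_spike[j] || ACp[j] == 0L) next
      x <- stats::rhyper(1, ACp[j], ANp[j] - ACp[j], 2L * np)
      if (x == 0L) next
      slots <- sample.int(2L * np, x)
      idx <- table((slots - 1L) %/% 2L + 1L)
      dosage[rows[as.integer(names(idx))], j] <-
        dosage[rows[as.integer(names(idx))], j] + as.integer(idx)
    }
  }

  truth <- list(spiked_gene = spike_gene, target_or = NA_real_, carriers = character(0))
  if (!is.na(spike_gene)) {
    jset <- which(ann$gene == spike_gene)
    if (length(jset) == 0L) stop("spiked gene not present in the annotation")
    or <- config$spike$odds_ratio
    for (j in jset) {
      afm <- max(population_af(db[packed == ann$packed[j]])[, -1], na.rm = TRUE)
      if (!is.finite(afm) || afm <= 0) next
      odds <- or * afm / (1 - afm)
      af_case <- odds / (1 + odds)
      if (af_case >= 1) stop("target odds ratio unreachable; attainable bound < ",
                             format((1 / afm - 1), digits = 3))
      dosage[, j] <- stats::rbinom(N, 2L, af_case)
    }
    truth$target_or <- or
    truth$carriers <- samples$sample[rowSums(dosage[, jset, drop = FALSE]) > 0]
  }

  # genotype-quality noise
  DP <- matrix(as.integer(pmax(2, round(stats::rnorm(N * nv, 35, 8)))), N, nv)
  GQ <- matrix(99L, N, nv)
  lowq <- matrix(stats::runif(N * nv) < config$lowq_fraction, N, nv)
  DP[lowq] <- as.integer(sample(2:9, sum(lowq), replace = TRUE))
  GQ[lowq] <- as.integer(sample(3:19, sum(lowq), replace = TRUE))
  ab <- matrix(pmin(0.95, pmax(0.05, stats::rnorm(N * nv, 0.5, config$ab_noise_sd))), N, nv)
  AD_alt <- matrix(0L, N, nv)
  het <- dosage == 1L
  hom <- dosage == 2L
  AD_alt[het] <- as.integer(round(DP[het] * ab[het]))
  AD_alt[hom] <- DP[hom]
  AD_ref <- DP - AD_alt
  miss <- matrix(stats::runif(N * nv) < config$missing_rate, N, nv)
  dosage[miss] <- NA_integer_

  variants <- data.table::data.table(chrom = v$chrom, pos = v$pos, ref = v$ref,
                                     alt = v$alt, packed = v$packed,
                                     SOR = stats::runif(nv, 0.3, 1.5),
                                     excess_het = NA_real_)
  for (j in seq_len(nv)) {
    d <- dosage[, j]
    data.table::set(variants, i = j, j = "excess_het",
                    value = excess_het_phred(sum(d == 0L, na.rm = TRUE),
                                             sum(d == 1L, na.rm = TRUE),
                                             sum(d == 2L, na.rm = TRUE)))
  }
  cohort <- cohort_genotype_matrix(samples, variants, dosage, DP = DP, GQ = GQ,
                                   AD_ref = AD_ref, AD_alt = AD_alt)
  list(cohort = cohort, truth = truth)
}

#' Generate sequence fixtures with planted low-complexity features
#'
#' A GC-balanced random background with planted homopolymer runs and
#' dinucleotide repeats, plus the truth table of planted features.
#'
#' @param seed Integer seed.
#' @param n_neutral Length of each neutral segment; default 300.
#' @param homopolymer_lens Planted homopolymer lengths; default `c(12, 8)`.
#' @param dinucleotide_reps Planted dinucleotide repeat unit counts; default
#'   `c(20, 15)`.
#' @return List with `sequence` (string) and `truth` (`data.table` of
#'   `start`, `end` (0-based half-open), `feature`).
#' @export
generate_sequences <- function(seed = 1, n_neutral = 300,
                               homopolymer_lens = c(12, 8),
                               dinucleotide_reps = c(20, 15)) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  neutral <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  feats <- list()
  for (L in homopolymer_lens)
    feats[[length(feats) + 1L]] <- list(seq = strrep(sample(bases, 1), L),
                                        feature = "homopolymer")
  for (k in dinucleotide_reps) {
    unit <- paste(sample(bases, 2), collapse = "")
    feats[[length(feats) + 1L]] <- list(seq = strrep(unit, k), feature = "dinucleotide")
  }
  seqparts <- character(0); truth <- list(); at <- 0L
  for (f in feats) {
    ns <- neutral(n_neutral)
    seqparts <- c(seqparts, ns, f$seq)
    at <- at + nchar(ns)
    truth[[length(truth) + 1L]] <- data.table::data.table(
      start = at, end = at + nchar(f$seq), feature = f$feature)
    at <- at + nchar(f$seq)
  }
  seqparts <- c(seqparts, neutral(n_neutral))
  list(sequence = paste(seqparts, collapse = ""),
       truth = data.table::rbindlist(truth))
}

#' Generate a labelled ancestry reference in PC space
#'
#' Gaussian clusters per continental ancestry for classifier fitting/tests.
#'
#' @param n_per_class Samples per ancestry; default 60.
#' @param k Number of PCs; default 10.
#' @param separation Distance between cluster centers in units of the
#'   within-cluster standard deviation; default 10.
#' @param seed Integer seed.
#' @param classes Ancestry labels to include.
#' @return `data.table` with `sample`, `label`, `PC1..PCk`.
#' @export
generate_pc_reference <- function(n_per_class = 60, k = 10, separation = 10,
                                  seed = 1, classes = c("EUR", "AFR", "AMR", "SAS")) {
  set.seed(seed)
  classes <- ancestry_label(classes)
  centers <- matrix(0, length(classes), k)
  # anchor each ancestry to its canonical axis so subsets stay compatible
  for (i in seq_along(classes)) {
    dim <- ((match(classes[i], ANCESTRIES) - 1) %% k) + 1
    centers[i, dim] <- separation
  }
  out <- data.table::rbindlist(lapply(seq_along(classes), function(i) {
    m <- matrix(stats::rnorm(n_per_class * k), n_per_class, k) +
      matrix(centers[i, ], n_per_class, k, byrow = TRUE)
    dt <- data.table::data.table(sample = sprintf("%s%03d", classes[i], seq_len(n_per_class)),
                                 label = classes[i])
    for (j in seq_len(k)) dt[, (paste0("PC", j)) := m[, j]]
    dt
  }))
  out[]
}
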