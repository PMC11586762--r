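#' Symmetric DUST low-complexity intervals
#'
#' Finds low-complexity regions of a nucleotide sequence with the symmetric
#' DUST algorithm. The score of an interval of length \eqn{L \ge 4} is
#' \deqn{10 \sum_t c_t (c_t - 1) / 2 / (L - 3)}
#' over its 64 trinucleotide counts \eqn{c_t}. Maximal "perfect" intervals
#' (score at or above `score_threshold`, no proper subinterval scoring
#' strictly higher, length at most `window`) are reported merged. Runs of `N`
#' break candidate windows and are never masked.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N` (case-insensitive), or a
#'   `Biostrings::DNAString`.
#' @param score_threshold Minimum (x10-scaled) DUST score; default 28.
#' @param window Maximum interval length in bases; default 64.
#' @param chrom Chromosome name for the returned intervals.
#' @return `GRanges` of masked intervals (0-based half-open convention on
#'   ingest/egress via [intervals_to_bed()]).
#' @export
sdust_intervals <- function(sequence, score_threshold = 28, window = 64, chrom = "seq") {
  if (window < 4) stop("window must be >= 4")
  res <- .sdust_intervals(as.character(sequence), score_threshold, as.integer(window))
  if (nrow(res) == 0L) return(GenomicRanges::GRanges())
  intervals(chrom, res$start, res$end)
}

#' Homopolymer run intervals
#'
#' Maximal single-nucleotide runs of at least `min_len` bases; `N` runs are
#' never reported.
#'
#' @inheritParams sdust_intervals
#' @param min_len Minimum run length; default 7.
#' @return `GRanges` of runs.
#' @export
homopolymer_intervals <- function(sequence, min_len = 7, chrom = "seq") {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  r <- rle(s)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len & r$values %in% c("A", "C", "G", "T")
  if (!any(keep)) return(GenomicRanges::GRanges())
  intervals(chrom, ends[keep] - r$lengths[keep], ends[keep])
}

#' Build the merged low-complexity mask track
#'
#' Union of DUST intervals, homopolymer runs and satellite intervals, each
#' extended by `pad` bases on both sides, clipped to chromosome bounds and
#' re-merged. This is the `lcr` filter track: any variant whose reference
#' span intersects it is excluded reciprocally from cohort and database.
#'
#' @param dust,homopolymers,satellites `GRanges` from the three sources (any
#'   may be empty).
#' @param pad Extension in bases on either side; default 10.
#' @param chrom_lengths Named integer vector covering every chromosome
#'   present.
#' @return Normalized `GRanges` with a `provenance` metadata column giving the
#'   contributing source(s) per merged interval.
#' @export
build_mask_track <- function(dust = GenomicRanges::GRanges(),
                             homopolymers = GenomicRanges::GRanges(),
                             satellites = GenomicRanges::GRanges(),
                             pad = 10, chrom_lengths) {
  tag <- function(g, src) {
    if (length(g) == 0L) return(GenomicRanges::GRanges())
    g$source <- src
    g
  }
  all <- c(tag(dust, "dust"), tag(homopolymers, "homopolymer"),
           tag(satellites, "satellite"))
  if (length(all) == 0L) return(GenomicRanges::GRanges())
  chr <- as.character(GenomeInfoDb::seqnames(all))
  unknown <- setdiff(chr, names(chrom_lengths))
  if (length(unknown)) stop("mask interval(s) on unknown chromosome(s): ",
                            paste(unknown, collapse = ", "))
  ext <- GenomicRanges::GRanges(
    chr,
    IRanges::IRanges(pmax(1L, GenomicRanges::start(all) - as.integer(pad)),
                     pmin(as.integer(chrom_lengths[chr]),
                          GenomicRanges::end(all) + as.integer(pad))))
  ext$source <- all$source
  merged <- normalize_intervals(ext)
  hits <- GenomicRanges::findOverlaps(merged, ext)
  prov <- vapply(split(ext$source[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits)),
                 function(s) paste(sort(unique(s)), collapse = ","), character(1))
  merged$provenance <- unname(prov[as.character(seq_along(merged))])
  merged
}
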