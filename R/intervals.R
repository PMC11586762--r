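#' Genomic interval tracks (BED convention)
#'
#' All interval work in the package is 0-based half-open internally, matching
#' BED. Tracks are held as `GRanges` (1-based closed internally to the Ranges
#' infrastructure; converted on ingest/egress).
#'
#' `read_interval_track()` reads a BED3+ file (optionally gzipped), rejects
#' rows with `start >= end` (with a warning counting them), and returns the
#' normalized (sorted, merged) track.
#'
#' @param path Path to a BED file.
#' @return A `GRanges` of normalized intervals.
#' @export
read_interval_track <- function(path) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(bed) < 3L) stop("BED file must have >= 3 columns: ", path)
  data.table::setnames(bed, 1:3, c("chrom", "start", "end"))
  bed[, chrom := sub("^chr", "", as.character(chrom))]
  bed[chrom %in% c("M", "chrM"), chrom := "MT"]
  bad <- bed$start >= bed$end
  if (any(bad)) {
    warning(sum(bad), " BED row(s) rejected (start >= end)")
    bed <- bed[!bad]
  }
  normalize_intervals(intervals(bed$chrom, bed$start, bed$end))
}

#' Build an interval track from vectors
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates (`start < end`).
#' @return A `GRanges` (not normalized; see [normalize_intervals()]).
#' @export
intervals <- function(chrom, start, end) {
  stopifnot(all(start < end))
  GenomicRanges::GRanges(as.character(chrom),
                         IRanges::IRanges(start = as.integer(start) + 1L,
                                          end = as.integer(end)))
}

#' Normalize an interval track
#'
#' Sorts and merges overlapping or adjacent intervals. Idempotent.
#'
#' @param track A `GRanges`.
#' @return A normalized `GRanges`.
#' @export
normalize_intervals <- function(track) {
  GenomicRanges::reduce(GenomicRanges::sort(track))
}

#' Complement of a track given chromosome lengths
#'
#' @param track A `GRanges`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return Normalized `GRanges` covering every base not in `track`.
#' @export
complement_intervals <- function(track, chrom_lengths) {
  seqs <- names(chrom_lengths)
  track <- normalize_intervals(track)
  missing_chr <- setdiff(as.character(GenomeInfoDb::seqnames(track)), seqs)
  if (length(missing_chr))
    stop("intervals on chromosome(s) without a stated length: ",
         paste(unique(missing_chr), collapse = ", "))
  full <- GenomicRanges::GRanges(seqs, IRanges::IRanges(1L, as.integer(chrom_lengths)))
  normalize_intervals(GenomicRanges::setdiff(full, track, ignore.strand = TRUE))
}

#' Convert a track to a BED-convention data.table
#'
#' @param track A `GRanges`.
#' @return `data.table` with `chrom`, `start` (0-based), `end` (exclusive).
#' @export
intervals_to_bed <- function(track) {
  data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end = GenomicRanges::end(track))
}

#' Write a track as BED3
#'
#' @param track A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_track <- function(track, path) {
  data.table::fwrite(intervals_to_bed(track), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# internal: TRUE for each (chrom, pos, ref) whose reference span [pos, pos+nchar(ref))
# intersects the track (conservative rule for indels)
.in_track <- function(chrom, pos, ref, track) {
  if (length(chrom) == 0L) return(logical(0))
  q <- GenomicRanges::GRanges(as.character(chrom),
                              IRanges::IRanges(as.integer(pos),
                                               width = nchar(as.character(ref))))
  IRanges::overlapsAny(q, track, ignore.strand = TRUE)
}
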