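#' Reversible 64-bit variant keys
#'
#' Packs (chrom, pos, ref, alt) into an unsigned 64-bit key: 5 bits of
#' chromosome code (1-22, X = 23, Y = 24, MT = 25), 28 bits of 0-based
#' position, and a 31-bit allele block. The allele block is fully reversible
#' when `nchar(ref) + nchar(alt) <= 11`; longer alleles fall back to a 30-bit
#' hash bucket whose low bit marks the key as non-reversible. Because base R
#' has no unsigned 64-bit integer type, the packed value is returned as a
#' 16-character lowercase hex string; lexicographic order on these strings
#' equals numeric order on the underlying keys, so keys sort by
#' (chromosome, position) for same-length alleles.
#'
#' @param chrom Chromosome identifiers (`"chr"` prefixes are stripped;
#'   `"M"`/`"chrM"` unify to `"MT"`).
#' @param pos 1-based positions.
#' @param ref,alt Allele strings over `A`, `C`, `G`, `T`.
#' @return `encode_variant_key()`: a `data.table` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `packed`, `reversible`. `decode_variant_key()`: a
#'   `data.table` with columns `chrom`, `pos`, `ref`, `alt`, `reversible`
#'   (`ref`/`alt` are `NA` for hash-bucket keys).
#' @examples
#' k <- encode_variant_key("7", 117559590, "G", "A")
#' decode_variant_key(k$packed)
#' @export
encode_variant_key <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  enc <- .vk_encode(as.character(rep_len(chrom, n)), as.numeric(rep_len(pos, n)),
                    as.character(rep_len(ref, n)), as.character(rep_len(alt, n)))
  data.table::data.table(
    chrom = sub("^chr", "", as.character(rep_len(chrom, n))),
    pos = as.integer(rep_len(pos, n)),
    ref = toupper(as.character(rep_len(ref, n))),
    alt = toupper(as.character(rep_len(alt, n))),
    packed = enc$packed, reversible = enc$reversible)
}

#' @rdname encode_variant_key
#' @param packed 16-character hex keys produced by `encode_variant_key()`.
#' @export
decode_variant_key <- function(packed) {
  dec <- .vk_decode(as.character(packed))
  data.table::data.table(chrom = dec$chrom, pos = as.integer(dec$pos),
                         ref = dec$ref, alt = dec$alt,
                         reversible = dec$reversible)
}

# internal: packed keys for a table already carrying chrom/pos/ref/alt
.add_variant_keys <- function(dt) {
  dt[, packed := encode_variant_key(chrom, pos, ref, alt)$packed]
  dt
}
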