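#' Possible single-base substitution classes along a coding sequence
#'
#' Enumerates all 9 single-base substitutions of every codon and classifies
#' each as missense, synonymous or nonsense under the standard genetic code.
#'
#' @param cds Coding sequence (string or `Biostrings::DNAString`), length
#'   divisible by 3.
#' @return `data.table` with `codon` (1-based index), `poss_mis`, `poss_syn`,
#'   `poss_non`.
#' @export
codon_substitution_classes <- function(cds) {
  s <- toupper(as.character(cds))
  if (nchar(s) %% 3 != 0) stop("coding sequence length must be divisible by 3")
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  aa <- gc[codons]
  if (anyNA(aa)) stop("coding sequence contains non-ACGT codons")
  stops <- which(aa == "*")
  if (any(stops != length(codons)))
    stop("in-frame stop codon at codon ", paste(setdiff(stops, length(codons)), collapse = ", "))
  bases <- c("A", "C", "G", "T")
  per_codon <- function(cod) {
    ref_aa <- gc[[cod]]
    mis <- syn <- non <- 0L
    for (pos in 1:3) for (b in setdiff(bases, substr(cod, pos, pos))) {
      mut <- cod
      substr(mut, pos, pos) <- b
      mut_aa <- gc[[mut]]
      if (mut_aa == "*") non <- non + 1L
      else if (mut_aa == ref_aa) syn <- syn + 1L
      else mis <- mis + 1L
    }
    c(mis, syn, non)
  }
  m <- vapply(codons, per_codon, integer(3))
  data.table::data.table(codon = seq_along(codons), poss_mis = m[1, ],
                         poss_syn = m[2, ], poss_non = m[3, ])
}

#' Missense tolerance ratio profile
#'
#' Sliding-window ratio of the observed missense proportion to the possible
#' missense proportion:
#' \deqn{MTR = \frac{obs_{mis} / (obs_{mis} + obs_{syn})}
#'                 {poss_{mis} / (poss_{mis} + poss_{syn})}}
#' computed per codon over a centered window of `window` codons (edge windows
#' truncated, not dropped). 1 corresponds to selective neutrality; lower
#' values indicate intolerance to missense variation. Windows with no
#' observed variants give `NA` (undefined, not 0). Per-ancestry tracks are
#' obtained by restricting `observed` to variants seen in that ancestry
#' (`AC_pop > 0`) before calling.
#'
#' @param cds Coding sequence, length divisible by 3.
#' @param observed `data.table` with columns `codon` (1-based) and
#'   `consequence` (`"missense"` or `"synonymous"`; other classes are
#'   ignored), one row per distinct observed variant.
#' @param window Window size in codons; default 31.
#' @return `data.table` of class `mtr_track`: `codon`, `mtr`, `obs_mis`,
#'   `obs_syn`, `poss_mis`, `poss_syn`.
#' @export
compute_mtr <- function(cds, observed, window = 31) {
  if (window < 1 || window %% 2 == 0) stop("window must be a positive odd codon count")
  poss <- codon_substitution_classes(cds)
  n <- nrow(poss)
  observed <- data.table::as.data.table(observed)
  if (nrow(observed) && (any(observed$codon < 1) || any(observed$codon > n)))
    stop("observed variant codon index outside the coding sequence")
  obs_mis_c <- tabulate(observed[consequence == "missense", codon], nbins = n)
  obs_syn_c <- tabulate(observed[consequence == "synonymous", codon], nbins = n)
  half <- (window - 1) / 2
  wsum <- function(x) {
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    cs[hi + 1L] - cs[lo]
  }
  om <- wsum(obs_mis_c); os <- wsum(obs_syn_c)
  pm <- wsum(poss$poss_mis); ps <- wsum(poss$poss_syn)
  denom_ok <- (om + os) > 0 & (pm + ps) > 0 & pm > 0
  mtr <- ifelse(denom_ok, (om / (om + os)) / (pm / (pm + ps)), NA_real_)
  out <- data.table::data.table(codon = seq_len(n), mtr = mtr,
                                obs_mis = om, obs_syn = os,
                                poss_mis = pm, poss_syn = ps)
  data.table::setattr(out, "class", c("mtr_track", class(out)))
  data.table::setattr(out, "window", as.integer(window))
  out[]
}
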