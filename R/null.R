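#' Composition-preserving sequence shuffle
#'
#' Uniform random permutation of the characters of an ungapped sequence: the
#' nucleotide multiset is preserved exactly, the arrangement destroyed.
#'
#' @param seq ungapped nucleotide string.
#' @param seed optional integer; when given the shuffle is drawn from a
#'   temporary RNG stream seeded with it, leaving the caller's RNG state
#'   untouched.
#' @return shuffled sequence string.
#' @export
shuffleSequence <- function(seq, seed = NULL) {
  cs <- chars(seq)
  perm <- if (is.null(seed)) sample(cs) else withSeed(seed, sample(cs))
  paste(perm, collapse = "")
}

#' Empirical P-value for the best ancestral RFC
#'
#' Estimates how likely the observed best RFC score of an ancestral sequence
#' is to arise by chance, given only its length and nucleotide composition:
#' the ancestral sequence is shuffled `nReps` times; for each shuffle the
#' STOP-STOP ORFs are extracted, each is scored by RFC against the extant
#' focal ORF, and the maximum is kept, yielding an empirical null
#' distribution of best RFC values. The P-value is the fraction of null
#' values strictly greater than the observed best RFC (so a P-value of 0 is
#' possible; set `pseudocount = TRUE` for the `(k + 1) / (n + 1)` variant).
#'
#' The null distribution depends only on the composition and length of
#' `ancSeq`, the reference ORF, the parameters and the seed — not on the
#' arrangement of `ancSeq`.
#'
#' @param ancSeq ungapped ancestral sequence.
#' @param refOrf ungapped extant focal ORF.
#' @param nReps number of randomizations (1000 in the published procedure).
#' @param seed integer seed for the shuffle stream (required, for
#'   reproducibility).
#' @param minLen strict minimum ORF span ([findOrfs()]).
#' @param params alignment parameters ([alignParams()]).
#' @param pseudocount use `(k + 1) / (nReps + 1)` instead of `k / nReps`.
#' @param nodeLabel optional label stored in the result.
#' @return list of class `empiricalNull`: `nodeLabel`, `nReps`,
#'   `nullBestRfc` (numeric vector of length `nReps`), `observedBestRfc`,
#'   `pValue` and `seed`.
#' @export
empiricalPvalue <- function(ancSeq, refOrf, nReps = 1000L, seed,
                            minLen = 30L, params = alignParams(),
                            pseudocount = FALSE, nodeLabel = NA_character_) {
  if (nReps < 1L) stop("nReps must be >= 1")
  ancSeq <- normalizeNuc(ancSeq, allowGap = FALSE, context = "ancestral sequence")
  if (!nchar(ancSeq)) stop("empty ancestral sequence")
  observed <- bestRfcForNode(ancSeq, refOrf, "noATG", minLen = minLen,
                             params = params)$bestRfc
  ## canonicalize so the null stream depends only on the composition of
  ## ancSeq (not its arrangement), given the seed
  cs <- sort(chars(ancSeq))
  nullBest <- withSeed(seed, {
    vapply(seq_len(nReps), function(i) {
      shuf <- paste(sample(cs), collapse = "")
      bestRfcForNode(shuf, refOrf, "noATG", minLen = minLen,
                     params = params)$bestRfc
    }, numeric(1))
  })
  k <- sum(nullBest > observed)
  p <- if (pseudocount) (k + 1) / (nReps + 1) else k / nReps
  structure(list(nodeLabel = nodeLabel, nReps = as.integer(nReps),
                 nullBestRfc = nullBest, observedBestRfc = observed,
                 pValue = p, seed = seed),
            class = "empiricalNull")
}
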