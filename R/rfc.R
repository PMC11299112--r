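#' Alignment scoring parameters
#'
#' Parameters for the global pairwise alignment of the extant focal ORF
#' against a full ancestral sequence. Gap penalties follow the published
#' procedure (open -3, extend -0.1, with a gap run of length L costing
#' `open + (L - 1) * extend`); the nucleotide substitution scores default to
#' the common match +5 / mismatch -4 scheme and are configurable. N scores
#' as a mismatch against every base.
#'
#' @param match match score.
#' @param mismatch mismatch score.
#' @param gapOpen penalty charged at the first position of a gap run.
#' @param gapExtend penalty charged at each subsequent gap position.
#' @return a named list of class `alignParams`.
#' @export
alignParams <- function(match = 5, mismatch = -4, gapOpen = -3, gapExtend = -0.1) {
  structure(list(match = match, mismatch = mismatch,
                 gapOpen = gapOpen, gapExtend = gapExtend),
            class = "alignParams")
}

#' Global pairwise alignment of the focal ORF to an ancestral sequence
#'
#' Needleman-Wunsch global alignment with affine-style gap penalties and a
#' fixed traceback preference (diagonal > up > left; match-state
#' predecessors first) so a single canonical optimum is returned,
#' deterministically, even when several alignments tie.
#'
#' @param ref ungapped reference sequence (the extant focal ORF).
#' @param anc ungapped ancestral sequence.
#' @param params an [alignParams()] list.
#' @return list of class `pairwiseAln` with equal-length gapped `refRow` and
#'   `ancRow`, the optimal `score`, and the `params` used. Removing gaps
#'   from the rows recovers the inputs exactly.
#' @examples
#' alignGlobal("ACGTACGT", "ACGACGT")
#' @export
alignGlobal <- function(ref, anc, params = alignParams()) {
  ref <- normalizeNuc(ref, allowGap = FALSE, context = "reference ORF")
  anc <- normalizeNuc(anc, allowGap = FALSE, context = "ancestral sequence")
  if (!nchar(ref) || !nchar(anc)) stop("alignGlobal: empty input sequence")
  res <- nw_align_cpp(ref, anc, params$match, params$mismatch,
                      params$gapOpen, params$gapExtend)
  structure(list(refRow = res$refRow, ancRow = res$ancRow,
                 score = res$score, params = params),
            class = "pairwiseAln")
}

## per-column coordinate bookkeeping shared by computeRfc/bestRfcForNode:
## for each alignment column, the 1-based index of the ungapped character in
## each row (valid only where the row is non-gap)
alnIndex <- function(aln) {
  rr <- chars(aln$refRow)
  ar <- chars(aln$ancRow)
  refCh <- rr != "-"
  ancCh <- ar != "-"
  list(refCh = refCh, ancCh = ancCh,
       refIdx = cumsum(refCh), ancIdx = cumsum(ancCh))
}

#' Reading frame conservation (RFC) of an ancestral ORF
#'
#' Transposes an ancestral ORF's ungapped coordinates into the pairwise
#' alignment and counts alignment columns where (i) both rows are non-gap,
#' (ii) the column falls inside the reference ORF on the reference row and
#' inside the ancestral ORF on the ancestral row, and (iii) the two reading
#' frames agree. The frame of a row at a column is the count of its non-gap
#' characters before that column, mod 3, taken relative to the respective
#' ORF start — so gaps in one row advance only the other row's frame. The
#' RFC score is the count divided by the reference ORF length, hence in
#' \[0, 1\]: an RFC of 1 means an ancestral ORF at least as long as the
#' reference aligns to it in frame without frameshifts.
#'
#' @param aln a `pairwiseAln` from [alignGlobal()] (reference ORF vs full
#'   ancestral sequence).
#' @param refOrfLen length of the reference ORF in nt; the ORF occupies
#'   ungapped reference positions `[0, refOrfLen)`.
#' @param ancOrf the ancestral ORF: a single row of [findOrfs()] output, or
#'   any list/vector with 0-based half-open `start` and `end`.
#' @return the RFC score, a number in \[0, 1\].
#' @export
computeRfc <- function(aln, refOrfLen, ancOrf) {
  ix <- alnIndex(aln)
  s <- as.integer(ancOrf[["start"]])
  e <- as.integer(ancOrf[["end"]])
  if (s < 0L || e > max(ix$ancIdx) || s >= e)
    stop("ancestral ORF coordinates out of bounds of the aligned sequence")
  counted <- ix$refCh & ix$ancCh &
    (ix$refIdx <= refOrfLen) &
    (ix$ancIdx - 1L >= s) & (ix$ancIdx - 1L < e) &
    ((ix$refIdx - ix$ancIdx + s) %% 3L == 0L)
  sum(counted) / refOrfLen
}

#' Best-scoring ancestral ORF for one ancestor
#'
#' Runs the ORF scan on the ancestral sequence, aligns the extant reference
#' ORF once against the full ancestral sequence, computes the RFC of every
#' candidate ORF on that single alignment, and returns the maximum. Ties are
#' broken by longer ORF, then smaller start. With no qualifying ORF the best
#' RFC is 0 and the best ORF absent.
#'
#' @param ancSeq ungapped ancestral sequence.
#' @param refOrf ungapped extant focal ORF.
#' @param definition ORF definition, `"noATG"` or `"ATG"`.
#' @param minLen strict minimum ORF span in nt (see [findOrfs()]).
#' @param params alignment parameters ([alignParams()]).
#' @param aln optionally, a precomputed [alignGlobal()] result to reuse.
#' @return list of class `rfcResult`: `bestRfc`, `bestOrf` (one-row
#'   data.frame or `NULL`), `nOrfs`, and `definition`.
#' @export
bestRfcForNode <- function(ancSeq, refOrf, definition = c("noATG", "ATG"),
                           minLen = 30L, params = alignParams(), aln = NULL) {
  definition <- match.arg(definition)
  orfs <- findOrfs(ancSeq, definition, minLen = minLen)
  if (nrow(orfs) == 0L)
    return(structure(list(bestRfc = 0, bestOrf = NULL, nOrfs = 0L,
                          definition = definition), class = "rfcResult"))
  if (is.null(aln)) aln <- alignGlobal(refOrf, ancSeq, params)
  ix <- alnIndex(aln)
  refOrfLen <- nchar(refOrf)
  base <- ix$refCh & ix$ancCh & (ix$refIdx <= refOrfLen)
  d <- ix$refIdx - ix$ancIdx
  anc0 <- ix$ancIdx - 1L
  rfc <- vapply(seq_len(nrow(orfs)), function(i) {
    s <- orfs$start[i]; e <- orfs$end[i]
    sum(base & (anc0 >= s) & (anc0 < e) & ((d + s) %% 3L == 0L)) / refOrfLen
  }, numeric(1))
  best <- order(-rfc, -orfs$length, orfs$start)[1L]
  structure(list(bestRfc = rfc[best], bestOrf = orfs[best, , drop = FALSE],
                 nOrfs = nrow(orfs), definition = definition),
            class = "rfcResult")
}
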