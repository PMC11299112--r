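#' Enumerate open reading frames on the forward strand
#'
#' Scans all three forward-strand frames of an ungapped nucleotide sequence
#' for ORFs under either definition used for ancestral ORF detection:
#'
#' * `"noATG"` (STOP-STOP): maximal in-frame spans between consecutive stop
#'   codons, with the sequence edges acting as open boundaries (an ORF may
#'   begin at position 0 without a preceding stop and end at the last
#'   complete codon without a terminal stop).
#' * `"ATG"`: the maximal span from the first ATG of each stop-free in-frame
#'   segment to that segment's stop codon (or the open sequence edge).
#'
#' The 3' stop codon, when present, is included in the reported span. Stops
#' are TAA, TAG, TGA (standard code); a codon containing N is neither a stop
#' nor an ATG. Only hits strictly longer than `minLen` nucleotides are
#' reported ("longer than 30 nt"), sorted by start then frame.
#'
#' @param seq ungapped uppercase nucleotide string (A,C,G,T,N).
#' @param definition `"noATG"` (STOP-STOP) or `"ATG"` (ATG-STOP).
#' @param minLen minimum span in nt, strict: hits satisfy
#'   `end - start > minLen`.
#' @return data.frame with 0-based half-open `start`, `end`, plus `frame`
#'   (0, 1 or 2), `definition` and `length`; zero rows when nothing
#'   qualifies. No in-frame stop occurs strictly inside `[start, end - 3)`.
#' @examples
#' findOrfs("ATGAAATGA", "ATG", minLen = 6)
#' findOrfs("TAAATGAAATAGCCC", "noATG", minLen = 3)
#' @export
findOrfs <- function(seq, definition = c("noATG", "ATG"), minLen = 30L) {
  definition <- match.arg(definition)
  seq <- normalizeNuc(seq, allowGap = FALSE, context = "ORF scan input")
  n <- nchar(seq)
  hits <- list()
  for (f in 0:2) {
    k <- (n - f) %/% 3L
    if (k < 1L) next
    cstart <- f + 3L * (0:(k - 1L))            # 0-based codon starts
    codons <- substring(seq, cstart + 1L, cstart + 3L)
    isStop <- codons %in% STOP_CODONS
    stopIdx <- which(isStop)                   # 1-based codon indices
    bounds <- c(0L, stopIdx, if (length(stopIdx) == 0L || stopIdx[length(stopIdx)] < k) k)
    for (i in seq_len(length(bounds) - 1L)) {
      a <- bounds[i] + 1L                      # first codon of segment
      b <- bounds[i + 1L]                      # last codon (stop or seq edge)
      if (b < a) next
      if (definition == "ATG") {
        seg <- which(codons[a:b] == "ATG")
        if (!length(seg)) next
        a <- a + seg[1L] - 1L
      }
      start <- f + 3L * (a - 1L)
      end <- f + 3L * b
      if (end - start > minLen)
        hits[[length(hits) + 1L]] <- c(start, end, f)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0), frame = integer(0),
                      definition = character(0), length = integer(0)))
  m <- do.call(rbind, hits)
  df <- data.frame(start = m[, 1L], end = m[, 2L], frame = m[, 3L],
                   definition = definition, length = m[, 2L] - m[, 1L])
  df <- df[order(df$start, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}
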