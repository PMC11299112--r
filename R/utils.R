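#' @useDynLib orfancestry, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

## run expr under a temporary RNG state so library calls never disturb the
## caller's stream
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a per-label random stream seed from a master seed
#'
#' Deterministic hash of a character label folded into a master seed, so that
#' per-node or per-gene computations are reproducible independently of
#' evaluation order. Result is a non-negative integer below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param label character scalar (for example an internal node label).
#' @return integer seed.
#' @export
deriveSeed <- function(master, label) {
  stopifnot(length(label) == 1L, is.character(label))
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 131 + cp) %% 2147483629
  as.integer((abs(as.numeric(master)) + h * 7919) %% 2147483629)
}

## uppercase, U -> T, validate alphabet
normalizeNuc <- function(x, allowGap = TRUE, context = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  allowed <- if (allowGap) "ACGTN-" else "ACGTN"
  bad <- grepl(sprintf("[^%s]", allowed), x)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub(sprintf("[%s]", allowed), "", x[bad]), "")))
    stop(sprintf("invalid character(s) in %s: %s (only A,C,G,T,N%s allowed; other ambiguity codes are rejected)",
                 context, paste(ch, collapse = ","), if (allowGap) ",-" else ""))
  }
  x
}

stripGaps <- function(x) gsub("-", "", x, fixed = TRUE)

## split a sequence string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
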