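#' OrthologAlignment: a focal ORF and its orthologous regions, aligned
#'
#' Holds a nucleotide multiple sequence alignment of a focal (reference) ORF
#' locus and its orthologous genomic regions in related species, together with
#' the identity of the focal taxon and the coordinates of the focal ORF on the
#' ungapped focal sequence.
#'
#' All intervals in this package are 0-based half-open, so `focalOrfSpan`
#' `c(0, 300)` denotes the first 300 nt of the ungapped focal sequence.
#'
#' @slot records named character vector of equal-length aligned sequences over
#'   A,C,G,T,N,-; names are taxon identifiers.
#' @slot focalTaxon name of the focal (reference) sequence; present exactly
#'   once among the records.
#' @slot focalOrfSpan integer(2), 0-based half-open interval of the focal ORF
#'   in ungapped focal coordinates; length divisible by 3 and >= 30.
#' @slot alignmentMode `"orf_only"` (the ungapped focal sequence is exactly
#'   the ORF) or `"extended"` (the locus includes flanking sequence).
#' @slot flankLen integer, nominal flank length in nt (0 for `orf_only`).
#'
#' @export
setClass("OrthologAlignment",
  representation(records = "character", focalTaxon = "character",
                 focalOrfSpan = "integer", alignmentMode = "character",
                 flankLen = "integer"))

setValidity("OrthologAlignment", function(object) {
  r <- object@records
  if (length(r) < 1L) return("alignment has no records")
  if (is.null(names(r)) || any(!nzchar(names(r)))) return("records must be named by taxon")
  if (length(unique(nchar(r))) != 1L) return("ragged alignment: sequences have unequal lengths")
  if (nchar(r[[1L]]) < 1L) return("alignment width must be >= 1")
  if (sum(names(r) == object@focalTaxon) != 1L)
    return(sprintf("focal taxon '%s' must be present exactly once", object@focalTaxon))
  if (any(grepl("[^ACGTN-]", r))) return("sequences may only contain A,C,G,T,N,-")
  sp <- object@focalOrfSpan
  if (length(sp) != 2L || anyNA(sp)) return("focalOrfSpan must be integer(2)")
  len <- sp[2L] - sp[1L]
  if (len %% 3L != 0L) return("focal ORF length must be divisible by 3")
  if (len < 30L) return("focal ORF must be >= 30 nt")
  foc <- stripGaps(r[[object@focalTaxon]])
  if (sp[1L] < 0L || sp[2L] > nchar(foc))
    return("focalOrfSpan outside the ungapped focal sequence")
  if (!object@alignmentMode %in% c("orf_only", "extended"))
    return("alignmentMode must be 'orf_only' or 'extended'")
  if (object@alignmentMode == "orf_only" &&
      !(sp[1L] == 0L && sp[2L] == nchar(foc)))
    return("in orf_only mode the ungapped focal sequence must equal the focal ORF exactly")
  TRUE
})

#' Construct an OrthologAlignment
#'
#' @param records named character vector of aligned sequences (taxon -> row).
#' @param focalTaxon name of the focal sequence.
#' @param focalOrfSpan integer(2), 0-based half-open ORF interval on the
#'   ungapped focal sequence. Defaults to the whole focal sequence
#'   (orf_only mode).
#' @param alignmentMode `"orf_only"` or `"extended"`.
#' @param flankLen nominal flank length in nt.
#' @return an [OrthologAlignment-class] object.
#' @export
OrthologAlignment <- function(records, focalTaxon,
                              focalOrfSpan = NULL,
                              alignmentMode = c("orf_only", "extended"),
                              flankLen = 0L) {
  alignmentMode <- match.arg(alignmentMode)
  records <- vapply(records, normalizeNuc, character(1), context = "alignment")
  if (is.null(focalOrfSpan)) {
    if (!focalTaxon %in% names(records))
      stop(sprintf("focal taxon '%s' not found among records", focalTaxon))
    focalOrfSpan <- c(0L, nchar(stripGaps(records[[focalTaxon]])))
  }
  new("OrthologAlignment", records = records, focalTaxon = focalTaxon,
      focalOrfSpan = as.integer(focalOrfSpan), alignmentMode = alignmentMode,
      flankLen = as.integer(flankLen))
}

#' PhyloTree: a rooted phylogeny with labelled internal nodes
#'
#' Thin wrapper around an [ape::phylo] object guaranteeing a rooted binary
#' topology, strictly positive branch lengths and unique internal node labels.
#' The root node carries a label but is excluded from origin calls when
#' `rootExcluded` is `TRUE` (the default), because the placement of the root
#' along the root branch is uncertain and its reconstruction cannot be
#' trusted without further outgroups.
#'
#' @slot phy an `ape::phylo`, rooted, with edge lengths and node labels.
#' @slot rootExcluded logical; exclude the root from downstream origin calls.
#' @export
setClass("PhyloTree", representation(phy = "ANY", rootExcluded = "logical"))

setValidity("PhyloTree", function(object) {
  phy <- object@phy
  if (!inherits(phy, "phylo")) return("phy must be an ape 'phylo' object")
  if (!ape::is.rooted(phy)) return("tree must be rooted")
  if (is.null(phy$edge.length)) return("tree must have branch lengths")
  if (any(phy$edge.length <= 0)) return("branch lengths must be strictly positive")
  lab <- phy$node.label
  if (is.null(lab) || any(!nzchar(lab))) return("all internal nodes must be labelled")
  if (anyDuplicated(lab)) return("internal node labels must be unique")
  if (anyDuplicated(phy$tip.label)) return("leaf names must be unique")
  TRUE
})

#' AncestralSet: reconstructed sequences at internal nodes
#'
#' One reconstructed (ungapped) nucleotide sequence per non-root internal
#' node, with optional per-position posterior probabilities of the chosen
#' state, and a provenance tag recording the methodological variant
#' (tool/engine x topology x alignment mode x ORF definition) that produced
#' it. External imports (for example FastML, PRANK or PREQUEL output files)
#' may lack posteriors; these are recorded as absent, never fabricated.
#'
#' @slot sequences named character vector, internal node label -> ungapped
#'   sequence.
#' @slot posteriors named list, node label -> numeric vector of per-position
#'   posteriors in \[0,1\], or `NULL` entries when unavailable.
#' @slot provenance character scalar describing the methodology variant.
#' @export
setClass("AncestralSet",
  representation(sequences = "character", posteriors = "list",
                 provenance = "character"))

setValidity("AncestralSet", function(object) {
  s <- object@sequences
  if (is.null(names(s))) return("sequences must be named by internal node label")
  if (any(grepl("[^ACGTN]", s))) return("ancestral sequences must be ungapped A,C,G,T,N")
  p <- object@posteriors
  if (length(p) && !all(names(p) %in% names(s)))
    return("posterior entries must correspond to sequence entries")
  for (nm in names(p)) {
    v <- p[[nm]]
    if (is.null(v)) next
    if (any(v < 0 | v > 1, na.rm = TRUE)) return("posteriors must lie in [0,1]")
    if (length(v) != nchar(s[[nm]]))
      return(sprintf("posterior length for node '%s' does not match its sequence", nm))
  }
  TRUE
})

AncestralSet <- function(sequences, posteriors = list(), provenance = "unknown") {
  new("AncestralSet", sequences = sequences, posteriors = posteriors,
      provenance = provenance)
}

#' SubstitutionModel: GTR nucleotide model (optional discrete gamma)
#'
#' General time-reversible model parameterized by six symmetric
#' exchangeabilities (order AC, AG, AT, CG, CT, GT), stationary base
#' frequencies, and an optional discrete-gamma rate heterogeneity with
#' `nCategories` categories and shape `gammaShape`. The rate matrix is scaled
#' so the mean substitution rate at stationarity is 1, making branch lengths
#' expected substitutions per site.
#'
#' @slot rates numeric(6), GTR exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @slot baseFreqs numeric(4) named A,C,G,T, summing to 1.
#' @slot gammaShape positive shape of the gamma rate distribution, or `NA`
#'   for rate homogeneity.
#' @slot nCategories integer >= 1, number of discrete rate categories.
#' @export
setClass("SubstitutionModel",
  representation(rates = "numeric", baseFreqs = "numeric",
                 gammaShape = "numeric", nCategories = "integer"))

setValidity("SubstitutionModel", function(object) {
  if (length(object@rates) != 6L || any(object@rates <= 0))
    return("rates must be 6 positive exchangeabilities")
  f <- object@baseFreqs
  if (length(f) != 4L || abs(sum(f) - 1) > 1e-9 || any(f <= 0))
    return("baseFreqs must be 4 positive probabilities summing to 1 (1e-9)")
  if (object@nCategories < 1L) return("nCategories must be >= 1")
  if (object@nCategories > 1L && (is.na(object@gammaShape) || object@gammaShape <= 0))
    return("gammaShape must be positive when nCategories > 1")
  TRUE
})

#' Construct a SubstitutionModel
#'
#' @param baseFreqs numeric(4) of A,C,G,T frequencies (normalized internally).
#' @param rates numeric(6) GTR exchangeabilities, order AC, AG, AT, CG, CT,
#'   GT; the default (all 1) is the symmetric F81-like special case.
#' @param gammaShape gamma shape parameter or `NA` (no rate variation).
#' @param nCategories number of discrete gamma categories (1 = homogeneous).
#' @return a [SubstitutionModel-class].
#' @export
SubstitutionModel <- function(baseFreqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                              rates = rep(1, 6), gammaShape = NA_real_,
                              nCategories = 1L) {
  baseFreqs <- baseFreqs / sum(baseFreqs)
  names(baseFreqs) <- BASES
  new("SubstitutionModel", rates = as.numeric(rates),
      baseFreqs = baseFreqs, gammaShape = as.numeric(gammaShape),
      nCategories = as.integer(nCategories))
}

## ---- show methods ----

setMethod("show", "OrthologAlignment", function(object) {
  cat(sprintf("OrthologAlignment: %d sequences x %d columns (%s)\n",
              length(object@records), nchar(object@records[[1L]]),
              object@alignmentMode))
  cat(sprintf("  focal: %s, ORF span [%d, %d) (%d nt)\n", object@focalTaxon,
              object@focalOrfSpan[1L], object@focalOrfSpan[2L],
              diff(object@focalOrfSpan)))
  cat("  taxa:", paste(names(object@records), collapse = ", "), "\n")
})

setMethod("show", "PhyloTree", function(object) {
  phy <- object@phy
  cat(sprintf("PhyloTree: %d leaves, %d internal nodes (root '%s'%s)\n",
              length(phy$tip.label), phy$Nnode, rootLabel(object),
              if (object@rootExcluded) ", excluded from origin calls" else ""))
  cat("  internal labels:", paste(phy$node.label, collapse = ", "), "\n")
})

setMethod("show", "AncestralSet", function(object) {
  cat(sprintf("AncestralSet: %d nodes [%s]\n", length(object@sequences),
              object@provenance))
  for (nm in names(object@sequences))
    cat(sprintf("  %s: %d nt%s\n", nm, nchar(object@sequences[[nm]]),
                if (!is.null(object@posteriors[[nm]])) " (+posteriors)" else ""))
})

setMethod("show", "SubstitutionModel", function(object) {
  cat("SubstitutionModel (GTR",
      if (object@nCategories > 1L)
        sprintf("+G, shape %.3g, %d categories", object@gammaShape, object@nCategories)
      else "",
      ")\n", sep = "")
  cat("  baseFreqs:", paste(sprintf("%s=%.4f", BASES, object@baseFreqs), collapse = " "), "\n")
  cat("  rates (AC,AG,AT,CG,CT,GT):", paste(sprintf("%.3g", object@rates), collapse = ", "), "\n")
})

## ---- accessors ----

#' @describeIn OrthologAlignment-class aligned sequences as a named character
#'   vector (rows of the alignment).
#' @param x an object.
#' @export
alignedSeqs <- function(x) x@records

#' @describeIn OrthologAlignment-class name of the focal taxon.
#' @export
focalTaxon <- function(x) x@focalTaxon

#' @describeIn OrthologAlignment-class 0-based half-open interval of the
#'   focal ORF on the ungapped focal sequence.
#' @export
focalOrfSpan <- function(x) x@focalOrfSpan

#' @describeIn OrthologAlignment-class ungapped focal ORF sequence.
#' @export
focalOrfSeq <- function(x) {
  foc <- stripGaps(x@records[[x@focalTaxon]])
  substr(foc, x@focalOrfSpan[1L] + 1L, x@focalOrfSpan[2L])
}

#' @describeIn PhyloTree-class underlying `ape::phylo` object.
#' @export
treePhylo <- function(x) x@phy

#' @describeIn PhyloTree-class label of the root node.
#' @export
rootLabel <- function(x) {
  phy <- x@phy
  labelOfNode(phy, rootNodeNumber(phy))
}

#' @describeIn PhyloTree-class labels of all internal nodes except the root.
#' @export
internalNodeLabels <- function(x, includeRoot = FALSE) {
  lab <- x@phy$node.label
  if (includeRoot) lab else setdiff(lab, rootLabel(x))
}

#' @describeIn AncestralSet-class named vector of ungapped ancestral
#'   sequences.
#' @export
ancSequences <- function(x) x@sequences

#' @describeIn AncestralSet-class list of per-position posterior vectors
#'   (NULL when absent).
#' @export
ancPosteriors <- function(x) x@posteriors

#' @describeIn AncestralSet-class methodology descriptor string.
#' @export
provenance <- function(x) x@provenance
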