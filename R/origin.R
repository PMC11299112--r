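#' Branch of origin by RFC cutoff
#'
#' Walks the ancestors on the root-to-focal-leaf path from the most ancient
#' (the root itself being excluded) toward the leaf and returns the first
#' node whose best ancestral RFC strictly exceeds the cutoff; when none
#' does, the ORF is called `"extant_only"` (focal-species specific).
#'
#' @param perNodeRfc named numeric vector, internal node label -> best RFC;
#'   must cover every ancestor on the focal path.
#' @param tree a [PhyloTree-class].
#' @param cutoff RFC cutoff (strict inequality; the published analyses used
#'   0.5, 0.6, 0.7 and 0.9).
#' @param focalTaxon focal leaf name.
#' @return list of class `originCall` with `criterion`, `threshold`,
#'   `branch`, `perNode` (RFC along the path, ancient to recent) and
#'   `downstreamConsistency` (fraction of ancestors strictly more recent
#'   than the called branch that also exceed the cutoff; `NA` when
#'   undefined).
#' @export
assignBranchCutoff <- function(perNodeRfc, tree, cutoff, focalTaxon) {
  path <- focalPathAncestors(tree, focalTaxon)
  vals <- lookupPath(perNodeRfc, path, "RFC")
  hit <- which(vals > cutoff)
  makeOriginCall("rfc_cutoff", cutoff, path, vals, hit, vals > cutoff)
}

#' Branch of origin by empirical P-value
#'
#' Returns the most ancient ancestor on the root-to-focal-leaf path whose
#' empirical P-value is strictly below `alpha`; with none, `"extant_only"`.
#' `downstreamConsistency` is the fraction of ancestors strictly more recent
#' than the called branch that are also significant — near 1 when the ORF's
#' presence is consistent all the way down to the focal species.
#'
#' @param perNodeP named numeric vector, node label -> empirical P-value.
#' @param tree a [PhyloTree-class].
#' @param alpha significance threshold (default 0.01).
#' @param focalTaxon focal leaf name.
#' @return an `originCall` list, as for [assignBranchCutoff()].
#' @export
assignBranchPvalue <- function(perNodeP, tree, alpha = 0.01, focalTaxon) {
  path <- focalPathAncestors(tree, focalTaxon)
  vals <- lookupPath(perNodeP, path, "P-value")
  hit <- which(vals < alpha)
  makeOriginCall("pvalue", alpha, path, vals, hit, vals < alpha)
}

lookupPath <- function(perNode, path, what) {
  miss <- setdiff(path, names(perNode))
  if (length(miss))
    stop(sprintf("missing %s for path ancestor(s): %s", what,
                 paste(miss, collapse = ", ")))
  perNode[path]
}

makeOriginCall <- function(criterion, threshold, path, vals, hit, sig) {
  if (length(hit)) {
    i <- hit[1L]
    branch <- path[i]
    downstream <- if (i < length(path)) mean(sig[(i + 1L):length(path)]) else NA_real_
  } else {
    branch <- "extant_only"
    downstream <- NA_real_
  }
  structure(list(criterion = criterion, threshold = threshold, branch = branch,
                 perNode = vals, downstreamConsistency = downstream),
            class = "originCall")
}

#' Is an ORF robustly ancient?
#'
#' `TRUE` iff the most ancient non-root ancestor *and every ancestor below
#' it* on the focal path have a best RFC strictly above `cutoff` — the
#' criterion under which an intact ORF is present throughout the tree and
#' the gene can safely be considered ancient.
#'
#' @param perNodeRfc named numeric vector of best RFC per ancestor.
#' @param tree a [PhyloTree-class].
#' @param cutoff strict RFC threshold (default 0.9).
#' @param focalTaxon focal leaf name.
#' @return logical scalar.
#' @export
robustAncient <- function(perNodeRfc, tree, cutoff = 0.9, focalTaxon) {
  path <- focalPathAncestors(tree, focalTaxon)
  vals <- lookupPath(perNodeRfc, path, "RFC")
  all(vals > cutoff)
}

#' Ensemble confidence classification across methodology variants
#'
#' Groups a gene by the agreement of its per-variant branch-of-origin calls:
#'
#' * `high_confidence_ancient`: every variant calls the most ancient
#'   ancestor (`mostAncientLabel`).
#' * `high_confidence_de_novo`: every variant calls a branch more recent
#'   than the genus ancestor set (`genusInternalLabels`), including
#'   `"extant_only"` — the gene emerged de novo after the split of the
#'   genus; when all calls are `"extant_only"` it is focal-species
#'   specific.
#' * `low_confidence_ancient`: one or two variants (but not all) call the
#'   most ancient ancestor.
#' * `other`: anything else.
#'
#' @param calls named list of `originCall` objects (one per methodology
#'   variant; names are provenance descriptors). At least 2 variants.
#' @param mostAncientLabel label counted as "ancient" (the most ancient
#'   non-root ancestor; `Anc5` in the species-topology fixture). Under a
#'   free topology where that node does not exist, supply the appropriate
#'   label.
#' @param genusInternalLabels labels at or above the genus split; a branch
#'   outside this set counts as "after the split of the genus". Defaults to
#'   `mostAncientLabel`.
#' @return list of class `ensembleCall`: `category`, `nAgreeing` (size of
#'   the largest set of variants agreeing on one branch), and
#'   `variantBranches` (named character vector).
#' @export
classifyEnsemble <- function(calls, mostAncientLabel,
                             genusInternalLabels = mostAncientLabel) {
  if (length(calls) < 2L) stop("ensemble classification requires >= 2 variants")
  branches <- vapply(calls, function(cl) cl$branch, character(1))
  nAncient <- sum(branches == mostAncientLabel)
  category <-
    if (nAncient == length(branches)) "high_confidence_ancient"
    else if (all(!branches %in% genusInternalLabels)) "high_confidence_de_novo"
    else if (nAncient >= 1L && nAncient <= 2L) "low_confidence_ancient"
    else "other"
  structure(list(category = category,
                 nAgreeing = max(table(branches)),
                 variantBranches = branches),
            class = "ensembleCall")
}

#' Alignment difficulty statistics: gaps and Kimura distance
#'
#' Summary statistics of an input alignment that track how hard a locus is
#' for ancestral reconstruction: the average gap count per sequence, and the
#' mean pairwise Kimura 2-parameter distance
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` (P, Q the transition and
#' transversion proportions over columns where both sequences have an
#' unambiguous base). Pairs whose log arguments are non-positive (distance
#' undefined, saturation) are excluded from the mean with a warning; a pair
#' with no shared non-gap columns is an error.
#'
#' @param msa an [OrthologAlignment-class] with >= 2 sequences.
#' @return list with `gapsPerSeq` and `meanKimura`.
#' @export
msaStats <- function(msa) {
  recs <- alignedSeqs(msa)
  n <- length(recs)
  if (n < 2L) stop("msaStats requires at least 2 sequences")
  mat <- do.call(rbind, lapply(recs, chars))
  gapsPerSeq <- sum(mat == "-") / n
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  ds <- c()
  nUndef <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- mat[i, ]; b <- mat[j, ]
    ok <- a %in% BASES & b %in% BASES
    if (!any(a != "-" & b != "-"))
      stop(sprintf("pair (%s, %s) has no shared non-gap columns",
                   rownames(mat)[i], rownames(mat)[j]))
    m <- sum(ok)
    if (m == 0L) { nUndef <- nUndef + 1L; next }
    diff <- ok & (a != b)
    P <- sum(diff & transitions[a] == b) / m
    Q <- sum(diff & transitions[a] != b) / m
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    if (a1 <= 0 || a2 <= 0) { nUndef <- nUndef + 1L; next }
    ds <- c(ds, -0.5 * log(a1) - 0.25 * log(a2))
  }
  if (nUndef > 0L)
    warning(sprintf("%d pair(s) with undefined Kimura distance excluded", nUndef))
  list(gapsPerSeq = gapsPerSeq,
       meanKimura = if (length(ds)) mean(ds) else NA_real_)
}
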