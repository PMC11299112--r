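#' Read a nucleotide multiple sequence alignment from FASTA
#'
#' Reads an aligned FASTA (one orthologous locus per file), normalizes
#' characters (uppercase, U mapped to T), and returns a validated
#' [OrthologAlignment-class]. Ambiguity codes other than N are rejected.
#'
#' @param path path to an aligned FASTA file.
#' @param focalTaxon header of the focal (reference) sequence.
#' @param mode `"orf_only"` if the ungapped focal sequence is exactly the
#'   focal ORF, `"extended"` if it includes flanking sequence.
#' @param focalOrfSpan integer(2) 0-based half-open ORF interval on the
#'   ungapped focal sequence; required for `"extended"`, defaults to the
#'   full sequence for `"orf_only"`.
#' @param flankLen nominal flank length in nt (extended mode).
#' @return an [OrthologAlignment-class].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">Scer", "ATGAAATTTCCCGGGAAATTTCCCGGGTAA",
#'              ">Spar", "ATGAAATTTCCCGGGAAATTTCCCGGCTAA"), f)
#' readMsa(f, "Scer", mode = "orf_only")
#' @export
readMsa <- function(path, focalTaxon, mode = c("orf_only", "extended"),
                    focalOrfSpan = NULL, flankLen = 0L) {
  mode <- match.arg(mode)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  recs <- as.character(ss)
  names(recs) <- sub("\\s.*$", "", names(ss))  # first token of header
  if (!focalTaxon %in% names(recs))
    stop(sprintf("focal taxon '%s' not found among FASTA headers", focalTaxon))
  if (length(unique(nchar(recs))) != 1L)
    stop("ragged alignment: FASTA records have unequal aligned lengths")
  OrthologAlignment(recs, focalTaxon, focalOrfSpan = focalOrfSpan,
                    alignmentMode = mode, flankLen = flankLen)
}

#' Write an OrthologAlignment to FASTA
#'
#' Sequences and record order round-trip exactly through
#' `readMsa(writeMsa(x))`.
#'
#' @param x an [OrthologAlignment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMsa <- function(x, path) {
  ss <- Biostrings::BStringSet(alignedSeqs(x))
  Biostrings::writeXStringSet(ss, path, width = 20000L)
  invisible(path)
}

#' Read a rooted phylogenetic tree from newick
#'
#' Requires a rooted topology with strictly positive branch lengths.
#' Internal nodes without labels are auto-labelled deterministically:
#' unlabelled non-root nodes receive `Anc1`, `Anc2`, ... in postorder
#' traversal order and an unlabelled root receives `Root` (falling back to
#' the next free `AncN` if `Root` is taken). The rule is fixed so that
#' ensemble joins across methodology variants are stable across re-reads.
#'
#' @param path path to a newick file (or a newick string).
#' @param rootExcluded exclude the root node from downstream origin calls
#'   (default `TRUE`: the root placement along the root branch is uncertain).
#' @param allowZeroBl if `TRUE`, zero-length branches are replaced by
#'   `epsilonBl` instead of raising an error.
#' @param epsilonBl replacement branch length for zero-length branches.
#' @return a [PhyloTree-class].
#' @examples
#' tr <- readTree(system.file("extdata", "saccharomyces_species.nwk",
#'                            package = "orfancestry"))
#' internalNodeLabels(tr)
#' @export
readTree <- function(path, rootExcluded = TRUE, allowZeroBl = FALSE,
                     epsilonBl = 1e-8) {
  phy <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(phy)) stop("could not parse newick from ", path)
  if (!ape::is.rooted(phy))
    stop("tree is unrooted (root has >2 children); supply a rooted newick")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (any(phy$edge.length == 0)) {
    if (!allowZeroBl)
      stop("zero-length branches found; set allowZeroBl = TRUE to replace them by epsilonBl")
    phy$edge.length[phy$edge.length == 0] <- epsilonBl
  }
  phy <- autoLabelInternal(phy)
  new("PhyloTree", phy = phy, rootExcluded = rootExcluded)
}

#' Write a PhyloTree to newick
#'
#' Reading a written tree yields identical topology, labels and branch
#' lengths (to numerical precision).
#'
#' @param x a [PhyloTree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTree <- function(x, path) {
  ape::write.tree(treePhylo(x), file = path)
  invisible(path)
}

## deterministic auto-labelling of unlabelled internal nodes (see readTree)
autoLabelInternal <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", nnode)
  lab[is.na(lab)] <- ""
  rootNode <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  po <- ape::reorder.phylo(phy, "postorder")
  internalPO <- unique(po$edge[, 1L])  # parents in postorder completion order
  counter <- 0L
  nextLab <- function() {
    repeat {
      counter <<- counter + 1L
      cand <- paste0("Anc", counter)
      if (!cand %in% lab) return(cand)
    }
  }
  for (nd in setdiff(internalPO, rootNode)) {
    i <- nd - ntip
    if (!nzchar(lab[i])) lab[i] <- nextLab()
  }
  ri <- rootNode - ntip
  if (!nzchar(lab[ri])) lab[ri] <- if ("Root" %in% lab) nextLab() else "Root"
  if (anyDuplicated(lab)) stop("internal node labels are not unique")
  phy$node.label <- lab
  phy
}

## ape node number of the root
rootNodeNumber <- function(phy) setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]

nodeNumberOf <- function(phy, label) {
  i <- match(label, phy$node.label)
  if (is.na(i)) stop(sprintf("no internal node labelled '%s'", label))
  i + length(phy$tip.label)
}

labelOfNode <- function(phy, node) phy$node.label[node - length(phy$tip.label)]

#' Ancestors on the root-to-focal-leaf path
#'
#' Internal node labels on the path from the root to the focal leaf, ordered
#' from most ancient to most recent, excluding the root itself when the tree
#' is flagged root-excluded. These are the ancestors traversed by the branch
#' of origin rules; off-path internal nodes (for example outgroup ancestors)
#' are ignored.
#'
#' @param tree a [PhyloTree-class].
#' @param focalTaxon a leaf name.
#' @return character vector of internal node labels, ancient to recent.
#' @export
focalPathAncestors <- function(tree, focalTaxon) {
  phy <- treePhylo(tree)
  tip <- match(focalTaxon, phy$tip.label)
  if (is.na(tip)) stop(sprintf("focal taxon '%s' is not a leaf of the tree", focalTaxon))
  root <- rootNodeNumber(phy)
  parent <- integer(max(phy$edge))
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  path <- integer(0)
  nd <- parent[tip]
  while (nd != 0L) {
    path <- c(nd, path)
    nd <- if (nd == root) 0L else parent[nd]
  }
  labs <- vapply(path, function(n) labelOfNode(phy, n), character(1))
  if (tree@rootExcluded) labs <- setdiff(labs, rootLabel(tree))
  labs
}

#' Import ancestral sequences produced by an external ASR tool
#'
#' Parses a FASTA of ancestral sequences whose headers are internal node
#' labels of `tree` (a label mapping can be supplied when an external tool
#' uses its own node names). Alignment gaps are stripped so stored ancestors
#' are ungapped; posterior probabilities are recorded as absent, never
#' fabricated. A record for the root is accepted but dropped (the root is
#' excluded downstream); every non-root internal node must be covered by a
#' non-empty sequence.
#'
#' @param path FASTA file of ancestral sequences keyed by node label.
#' @param tree the [PhyloTree-class] the node labels refer to.
#' @param provenance descriptor of the external methodology variant, for
#'   example `"FastML_marginal|species|orf_only"`.
#' @param labelMap optional named character vector mapping FASTA headers to
#'   internal node labels.
#' @return an [AncestralSet-class] with empty posteriors.
#' @export
readExternalAncestors <- function(path, tree, provenance, labelMap = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (!is.null(labelMap)) {
    hit <- names(seqs) %in% names(labelMap)
    names(seqs)[hit] <- unname(labelMap[names(seqs)[hit]])
  }
  known <- internalNodeLabels(tree, includeRoot = TRUE)
  bad <- setdiff(names(seqs), known)
  if (length(bad))
    stop(sprintf("FASTA header(s) not matching any internal node: %s",
                 paste(bad, collapse = ", ")))
  seqs <- vapply(seqs, function(s) stripGaps(normalizeNuc(s, context = "ancestral sequence")),
                 character(1))
  seqs <- seqs[setdiff(names(seqs), rootLabel(tree))]
  required <- internalNodeLabels(tree, includeRoot = FALSE)
  missing <- setdiff(required, names(seqs))
  if (length(missing))
    stop(sprintf("no ancestral sequence for required node(s): %s",
                 paste(missing, collapse = ", ")))
  empty <- names(seqs)[!nzchar(seqs)]
  if (length(empty))
    stop(sprintf("empty ancestral sequence for node(s): %s",
                 paste(empty, collapse = ", ")))
  AncestralSet(seqs[required], posteriors = list(), provenance = provenance)
}
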