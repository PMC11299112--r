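#' Estimate base frequencies empirically from an alignment
#'
#' Stationary base frequencies are the observed nucleotide proportions over
#' all non-gap, non-N characters of the alignment, shrunk by a small
#' pseudocount floor (`p <- p * (1 - 4 * eps) + eps`) so no state has zero
#' probability even for degenerate compositions. Exchangeabilities and the
#' gamma settings are taken from the arguments, not fitted: full ML fitting
#' of GTR rates is delegated to dedicated phylogenetic software and out of
#' scope here.
#'
#' @param msa an [OrthologAlignment-class].
#' @param rates numeric(6) GTR exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param gammaShape gamma shape or `NA` for rate homogeneity.
#' @param nCategories number of discrete gamma categories.
#' @param eps pseudocount floor applied to each frequency.
#' @return a [SubstitutionModel-class].
#' @export
fitBaseFreqs <- function(msa, rates = rep(1, 6), gammaShape = NA_real_,
                         nCategories = 1L, eps = 1e-4) {
  all <- paste(alignedSeqs(msa), collapse = "")
  counts <- vapply(BASES, function(b)
    lengths(regmatches(all, gregexpr(b, all, fixed = TRUE))), numeric(1))
  if (sum(counts) == 0) stop("alignment contains no non-gap A,C,G,T characters")
  p <- counts / sum(counts)
  p <- p * (1 - 4 * eps) + eps
  SubstitutionModel(baseFreqs = p, rates = rates, gammaShape = gammaShape,
                    nCategories = nCategories)
}

#' GTR instantaneous rate matrix
#'
#' Builds the 4x4 GTR rate matrix `Q[i, j] = r_ij * pi_j` (rows A,C,G,T),
#' with diagonal set so rows sum to zero, scaled so the mean substitution
#' rate at stationarity `-sum(pi_i Q_ii)` equals 1.
#'
#' @param model a [SubstitutionModel-class].
#' @return 4x4 numeric matrix with dimnames A,C,G,T.
#' @export
gtrRateMatrix <- function(model) {
  r <- model@rates
  pi <- model@baseFreqs
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  # order AC, AG, AT, CG, CT, GT
  Q["A", "C"] <- r[1] * pi["C"]; Q["C", "A"] <- r[1] * pi["A"]
  Q["A", "G"] <- r[2] * pi["G"]; Q["G", "A"] <- r[2] * pi["A"]
  Q["A", "T"] <- r[3] * pi["T"]; Q["T", "A"] <- r[3] * pi["A"]
  Q["C", "G"] <- r[4] * pi["G"]; Q["G", "C"] <- r[4] * pi["C"]
  Q["C", "T"] <- r[5] * pi["T"]; Q["T", "C"] <- r[5] * pi["C"]
  Q["G", "T"] <- r[6] * pi["T"]; Q["T", "G"] <- r[6] * pi["G"]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

## eigen-decomposition of the (reversible) GTR generator via symmetrization,
## returning a fast P(t) evaluator
transitionFun <- function(model) {
  Q <- gtrRateMatrix(model)
  pi <- model@baseFreqs
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2  # enforce symmetry against rounding
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors
  A <- diag(1 / d) %*% V
  B <- t(V) %*% diag(d)
  function(t) {
    P <- A %*% (exp(e$values * t) * B)
    P[P < 0] <- 0
    dimnames(P) <- list(BASES, BASES)
    P
  }
}

## discrete gamma category rates (median method, normalized to mean 1)
gammaCategoryRates <- function(shape, k) {
  if (k == 1L || is.na(shape)) return(1)
  r <- stats::qgamma((2 * seq_len(k) - 1) / (2 * k), shape = shape, rate = shape)
  r / mean(r)
}

## leaf conditional likelihood matrix: 4 x ncol indicator; gap/N/missing -> 1s
leafLikelihood <- function(seqChars, ncol) {
  L <- matrix(1, 4, ncol, dimnames = list(BASES, NULL))
  if (is.null(seqChars)) return(L)  # taxon absent from alignment: all missing
  obs <- seqChars %in% BASES
  idx <- which(obs)
  if (length(idx)) {
    L[, idx] <- 0
    L[cbind(match(seqChars[idx], BASES), idx)] <- 1
  }
  L
}

#' Marginal ancestral character states by the pruning algorithm
#'
#' Computes, for every internal node and every alignment column, the marginal
#' posterior distribution over A,C,G,T by Felsenstein's pruning algorithm
#' (postorder conditional likelihoods followed by a preorder "outside" pass),
#' under the given GTR(+gamma) model with branch lengths taken from the tree
#' as-is (never re-optimized). Leaf gaps and Ns are treated as missing data;
#' tree leaves absent from the alignment contribute no information. The
#' reported state per column is the posterior argmax, ties broken by the
#' fixed base order A < C < G < T.
#'
#' @param msa an [OrthologAlignment-class].
#' @param tree a [PhyloTree-class]; its leaves must cover the alignment taxa.
#' @param model a [SubstitutionModel-class].
#' @return named list over internal node labels (root included); each element
#'   has `state` (character vector, length = alignment width), `posterior`
#'   (posterior probability of the chosen state), and `postMatrix`
#'   (4 x width matrix of full posteriors, columns summing to 1). A
#'   `logLik` attribute carries the total log-likelihood of the alignment.
#' @export
marginalStates <- function(msa, tree, model) {
  phy <- treePhylo(tree)
  recs <- alignedSeqs(msa)
  extra <- setdiff(names(recs), phy$tip.label)
  if (length(extra))
    stop(sprintf("alignment taxa not in tree: %s", paste(extra, collapse = ", ")))
  ncolA <- nchar(recs[[1L]])
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  Pfun <- transitionFun(model)
  catRates <- gammaCategoryRates(model@gammaShape, model@nCategories)
  K <- length(catRates)
  w <- rep(1 / K, K)
  pi <- model@baseFreqs

  po <- ape::reorder.phylo(phy, "postorder")$edge
  root <- rootNodeNumber(phy)
  childrenOf <- split(po[, 2L], po[, 1L])
  edgeLen <- numeric(nnode)
  edgeLen[phy$edge[, 2L]] <- phy$edge.length

  leafChars <- lapply(phy$tip.label, function(tx)
    if (tx %in% names(recs)) chars(recs[[tx]]) else NULL)

  postSum <- vector("list", nnode)       # accumulated w * U * L per internal node
  for (ct in seq_len(K)) {
    Pedge <- vector("list", nnode)       # P(t * rate) for the edge above each node
    for (nd in seq_len(nnode)) if (nd != root) Pedge[[nd]] <- Pfun(edgeLen[nd] * catRates[ct])
    L <- vector("list", nnode)           # conditional likelihood below node
    PL <- vector("list", nnode)          # Pedge[[child]] %*% L[[child]]
    for (tp in seq_len(ntip)) L[[tp]] <- leafLikelihood(leafChars[[tp]], ncolA)
    internalPO <- unique(po[, 1L])
    for (nd in internalPO) {
      acc <- matrix(1, 4, ncolA)
      for (ch in childrenOf[[as.character(nd)]]) {
        PL[[ch]] <- Pedge[[ch]] %*% L[[ch]]
        acc <- acc * PL[[ch]]
      }
      L[[nd]] <- acc
    }
    # outside pass (preorder): U[[root]] = pi
    U <- vector("list", nnode)
    U[[root]] <- matrix(pi, 4, ncolA)
    for (nd in rev(internalPO)) {
      kids <- childrenOf[[as.character(nd)]]
      for (ch in kids) {
        sib <- matrix(1, 4, ncolA)
        for (s in setdiff(kids, ch)) sib <- sib * PL[[s]]
        U[[ch]] <- crossprod(Pedge[[ch]], U[[nd]] * sib)
      }
    }
    for (nd in c(internalPO)) {
      contrib <- w[ct] * (U[[nd]] * L[[nd]])
      postSum[[nd]] <- if (is.null(postSum[[nd]])) contrib else postSum[[nd]] + contrib
    }
    if (ct == 1L) colLikAcc <- w[ct] * colSums(pi * L[[root]])
    else colLikAcc <- colLikAcc + w[ct] * colSums(pi * L[[root]])
  }

  out <- list()
  for (nd in unique(po[, 1L])) {
    pm <- postSum[[nd]]
    pm <- sweep(pm, 2, colSums(pm), "/")
    amax <- max.col(t(pm), ties.method = "first")  # fixed order A<C<G<T
    out[[labelOfNode(phy, nd)]] <- list(
      state = BASES[amax],
      posterior = pm[cbind(amax, seq_len(ncolA))],
      postMatrix = pm)
  }
  attr(out, "logLik") <- sum(log(colLikAcc))
  out
}

#' Parsimony reconstruction of indels (gap/presence) at internal nodes
#'
#' Each alignment column is reduced to a binary gap/present character and
#' reconstructed on the rooted tree by Fitch parsimony (set intersection,
#' else union, over children). Columns whose Fitch state set at a node
#' contains both states are ambiguous there; they are resolved by
#' `deletionBias`:
#'
#' * `deletionBias = TRUE`: ambiguity resolves to *present* — deletions are
#'   preferred when insertions and deletions cannot be distinguished,
#'   yielding longer ancestral sequences toward the root (the behavior
#'   attributed to PREQUEL-style and joint-FastML-style reconstructions).
#' * `deletionBias = FALSE` (default): ambiguity resolves to *absent* —
#'   insertions are preferred, yielding shorter, conservative ancestors.
#'
#' Unambiguous columns are identical under both settings.
#'
#' @param msa an [OrthologAlignment-class].
#' @param tree a [PhyloTree-class].
#' @param deletionBias resolve parsimony ties to presence (`TRUE`) or
#'   absence (`FALSE`).
#' @return list with `nodePresence` (logical matrix, internal node labels x
#'   alignment columns; `TRUE` = character present) and `ambiguityFraction`
#'   (named numeric, per-node fraction of columns with a parsimony tie).
#' @export
reconstructIndels <- function(msa, tree, deletionBias = FALSE) {
  phy <- treePhylo(tree)
  recs <- alignedSeqs(msa)
  ncolA <- nchar(recs[[1L]])
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")$edge
  childrenOf <- split(po[, 2L], po[, 1L])

  # Fitch sets coded bitwise: 1 = {absent}, 2 = {present}, 3 = both
  sets <- matrix(0L, nnode, ncolA)
  for (tp in seq_len(ntip)) {
    tx <- phy$tip.label[tp]
    if (tx %in% names(recs)) {
      g <- chars(recs[[tx]]) == "-"
      sets[tp, ] <- ifelse(g, 1L, 2L)
    } else {
      sets[tp, ] <- 3L  # taxon missing from alignment: uninformative
    }
  }
  internalPO <- unique(po[, 1L])
  for (nd in internalPO) {
    kids <- childrenOf[[as.character(nd)]]
    inter <- rep(3L, ncolA)
    uni <- rep(0L, ncolA)
    for (ch in kids) {
      inter <- bitwAnd(inter, sets[ch, ])
      uni <- bitwOr(uni, sets[ch, ])
    }
    sets[nd, ] <- ifelse(inter > 0L, inter, uni)
  }
  labs <- vapply(internalPO, function(n) labelOfNode(phy, n), character(1))
  amb <- sets[internalPO, , drop = FALSE] == 3L
  pres <- sets[internalPO, , drop = FALSE] == 2L | (amb & deletionBias)
  rownames(pres) <- labs
  af <- rowMeans(amb)
  names(af) <- labs
  list(nodePresence = pres, ambiguityFraction = af)
}

#' Reconstruct ancestral sequences at all non-root internal nodes
#'
#' Composes [marginalStates()] (character posteriors) with
#' [reconstructIndels()] (gap/presence): the ancestral ungapped sequence at a
#' node is the concatenation of argmax states over the columns reconstructed
#' as present there, with the per-position posterior of the chosen state
#' carried along. The root is reconstructed internally but omitted from the
#' returned set, mirroring its exclusion from origin calls.
#'
#' @param msa an [OrthologAlignment-class].
#' @param tree a [PhyloTree-class].
#' @param model a [SubstitutionModel-class] (for example from
#'   [fitBaseFreqs()]).
#' @param deletionBias passed to [reconstructIndels()].
#' @param provenance optional descriptor; a default recording engine, gamma
#'   settings, indel policy and alignment mode is built when `NULL`.
#' @return an [AncestralSet-class] covering every non-root internal node,
#'   with an `indels` attribute holding the [reconstructIndels()] result.
#' @examples
#' tr <- readTree("((A:0.05,B:0.05)AncAB:0.05,(C:0.05,D:0.05)AncCD:0.05)Root;")
#' msa <- OrthologAlignment(
#'   c(A = "ATGAAACCCGGGTTTAAACCCGGGTTTTAA",
#'     B = "ATGAAACCCGGGTTTAAACCCGGGTTTTAA",
#'     C = "ATGAAACCCGGCTTTAAACCCGGGTTTTAA",
#'     D = "ATGAAACCCGGGTTTAAACCCGGGTTTTAA"), "A")
#' anc <- reconstructAncestors(msa, tr, fitBaseFreqs(msa))
#' ancSequences(anc)
#' @export
reconstructAncestors <- function(msa, tree, model, deletionBias = FALSE,
                                 provenance = NULL) {
  marg <- marginalStates(msa, tree, model)
  ind <- reconstructIndels(msa, tree, deletionBias = deletionBias)
  if (is.null(provenance))
    provenance <- sprintf("internal_marginal|gamma%d|delbias=%s|%s",
                          model@nCategories, deletionBias,
                          msa@alignmentMode)
  nodes <- internalNodeLabels(tree, includeRoot = FALSE)
  seqs <- character(0)
  posts <- list()
  for (nd in nodes) {
    keep <- ind$nodePresence[nd, ]
    seqs[[nd]] <- paste(marg[[nd]]$state[keep], collapse = "")
    posts[[nd]] <- marg[[nd]]$posterior[keep]
  }
  out <- AncestralSet(seqs, posteriors = posts, provenance = provenance)
  attr(out, "indels") <- ind
  out
}
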