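#' Define a sequence evolution scenario
#'
#' Bundles and validates the parameters of a simulated locus: a tree, locus
#' length and GC content, substitution and indel rates, and optionally an
#' ORF of a given length planted on a chosen branch and conserved (stop-free
#' in frame) from there down to the focal leaf. The simulator provides the
#' ground truth — true ancestors, true alignment, true branch of origin —
#' against which the reconstruction pipeline is evaluated.
#'
#' @param tree a [PhyloTree-class].
#' @param locusLen locus length at the root, nt.
#' @param gcContent stationary GC content in (0, 1).
#' @param subRateScale multiplier applied to branch lengths for the
#'   substitution process.
#' @param indelRate indel events per site per unit branch length.
#' @param indelLenGeomP geometric length parameter in (0, 1]; event length
#'   is `1 + rgeom(indelLenGeomP)` nt.
#' @param orfOriginBranch where the ORF originates: an internal node label
#'   (the ORF exists from that node down), `"root"`, a leaf name (terminal
#'   branch; only that leaf carries it), or `"none"`.
#' @param orfLen planted ORF length, nt; divisible by 3 and >= 30 when an
#'   origin is given.
#' @param focalTaxon focal leaf (defaults to the first tip).
#' @param purifyingStrength probability that an in-frame stop codon arising
#'   inside the planted ORF below the origin is reverted to the parental
#'   codon (1 = strict conservation; lower values let the ORF decay,
#'   mimicking the rapid-evolution-vs-recent-origin ambiguity).
#' @param orfRateScale substitution-rate multiplier applied inside an
#'   inherited ORF window, modelling purifying selection on conserved
#'   coding sequence relative to the neutral rate of the surrounding locus
#'   (yeast coding sequence evolves at roughly 0.2-0.4x the intergenic
#'   rate; default 0.3).
#' @param plantAtg also set the first codon of the planted ORF to ATG.
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the scenario.
#' @return list of class `SimScenario`.
#' @export
simScenario <- function(tree, locusLen, gcContent = 0.4, subRateScale = 1,
                        indelRate = 0, indelLenGeomP = 0.5,
                        orfOriginBranch = "none", orfLen = 0L,
                        focalTaxon = NULL, purifyingStrength = 1,
                        orfRateScale = 0.3, plantAtg = FALSE, seed = 1L) {
  phy <- treePhylo(tree)
  focalTaxon <- focalTaxon %||% phy$tip.label[1L]
  stopifnot(locusLen >= 1L, gcContent > 0, gcContent < 1,
            indelLenGeomP > 0, indelLenGeomP <= 1,
            purifyingStrength >= 0, purifyingStrength <= 1,
            orfRateScale > 0)
  if (!focalTaxon %in% phy$tip.label) stop("focalTaxon must be a leaf of the tree")
  if (orfOriginBranch != "none") {
    known <- c("root", phy$node.label, phy$tip.label)
    if (!orfOriginBranch %in% known)
      stop(sprintf("unknown orfOriginBranch '%s'", orfOriginBranch))
    if (orfLen %% 3L != 0L || orfLen < 30L)
      stop("orfLen must be divisible by 3 and >= 30")
    if (orfLen > locusLen) stop("cannot place ORF: locus too short")
  }
  structure(list(tree = tree, locusLen = as.integer(locusLen),
                 gcContent = gcContent, subRateScale = subRateScale,
                 indelRate = indelRate, indelLenGeomP = indelLenGeomP,
                 orfOriginBranch = orfOriginBranch, orfLen = as.integer(orfLen),
                 focalTaxon = focalTaxon, purifyingStrength = purifyingStrength,
                 orfRateScale = orfRateScale, plantAtg = plantAtg,
                 seed = as.integer(seed)),
            class = "SimScenario")
}

## break every in-frame stop codon in the window (stops all start with T;
## T -> C turns TAA/TAG/TGA into the non-stop CAA/CAG/CGA) and optionally
## create a start codon
plantOrfEdits <- function(bases, wpos, plantAtg) {
  k <- length(wpos) %/% 3L
  for (j in seq_len(k)) {
    cp <- wpos[(3L * j - 2L):(3L * j)]
    if (paste(bases[cp], collapse = "") %in% STOP_CODONS) bases[cp[1L]] <- "C"
  }
  if (plantAtg) bases[wpos[1:3]] <- c("A", "T", "G")
  bases
}

#' Simulate a locus along a tree with substitutions and indels
#'
#' Draws a root sequence i.i.d. at the scenario's GC content and evolves it
#' along every branch: substitutions through the GTR transition matrix for
#' that branch length (times `subRateScale`), indel events as a Poisson
#' process (`indelRate` per site per unit branch length) with geometric
#' lengths, insertions copying stationary-frequency bases at uniform
#' positions. The true multiple alignment, including ancestors, is tracked
#' event-by-event through a global column registry. On `orfOriginBranch`,
#' the descendant node's sequence is minimally edited so a stop-free
#' in-frame ORF of `orfLen` nt exists (centered in the locus); below the
#' origin, in-frame stops arising inside the ORF are reverted with
#' probability `purifyingStrength` and indels never disrupt the ORF window.
#'
#' @param scn a [simScenario()] object.
#' @return list of class `SimTruth`: `leafSeqs` and `trueAncestors` (named
#'   ungapped sequences; ancestors include the root), `trueAlignment`
#'   (named character vector of gapped rows over all nodes),
#'   `originBranch`, `focalOrfSpan` (0-based half-open on the ungapped
#'   focal leaf, or `NULL`), and the `scenario`.
#' @export
simulateLocus <- function(scn) {
  stopifnot(inherits(scn, "SimScenario"))
  phy <- treePhylo(scn$tree)
  ntip <- length(phy$tip.label)
  pi <- c(A = (1 - scn$gcContent) / 2, C = scn$gcContent / 2,
          G = scn$gcContent / 2, T = (1 - scn$gcContent) / 2)
  model <- SubstitutionModel(baseFreqs = pi)
  Pfun <- transitionFun(model)
  root <- rootNodeNumber(phy)
  childrenOf <- split(phy$edge[, 2L], phy$edge[, 1L])
  edgeLen <- numeric(ntip + phy$Nnode)
  edgeLen[phy$edge[, 2L]] <- phy$edge.length
  nodeName <- function(nd) if (nd <= ntip) phy$tip.label[nd] else labelOfNode(phy, nd)

  withSeed(scn$seed, {
    reg <- new.env()
    reg$ord <- seq_len(scn$locusLen)   # global column order (ids)
    reg$counter <- scn$locusLen

    plantWindow <- function(state) {
      L <- length(state$ids)
      if (L < scn$orfLen) stop("cannot place ORF: locus too short at origin node")
      s <- (L - scn$orfLen) %/% 2L
      wpos <- (s + 1L):(s + scn$orfLen)
      state$bases <- plantOrfEdits(state$bases, wpos, scn$plantAtg)
      state$orfIds <- state$ids[wpos]
      state
    }

    evolveBranch <- function(parent, t) {
      ids <- parent$ids
      bases <- parent$bases
      # substitutions: neutral rate outside, reduced rate (purifying
      # selection) inside an inherited ORF window
      P <- Pfun(t * scn$subRateScale)
      inOrf <- if (is.null(parent$orfIds)) rep(FALSE, length(ids))
               else ids %in% parent$orfIds
      Porf <- if (any(inOrf)) Pfun(t * scn$subRateScale * scn$orfRateScale) else NULL
      for (b in BASES) {
        idx <- which(parent$bases == b & !inOrf)
        if (length(idx))
          bases[idx] <- sample(BASES, length(idx), replace = TRUE, prob = P[b, ])
        idx <- which(parent$bases == b & inOrf)
        if (length(idx))
          bases[idx] <- sample(BASES, length(idx), replace = TRUE, prob = Porf[b, ])
      }
      # purifying maintenance of an inherited ORF
      if (!is.null(parent$orfIds)) {
        wpos <- match(parent$orfIds, ids)
        k <- length(wpos) %/% 3L
        for (j in seq_len(k)) {
          cp <- wpos[(3L * j - 2L):(3L * j)]
          if (paste(bases[cp], collapse = "") %in% STOP_CODONS &&
              stats::runif(1) < scn$purifyingStrength)
            bases[cp] <- parent$bases[cp]
        }
      }
      # indels
      nEv <- stats::rpois(1, scn$indelRate * t * length(ids))
      for (ev in seq_len(nEv)) {
        L <- length(ids)
        if (L == 0L) break
        len <- 1L + stats::rgeom(1, scn$indelLenGeomP)
        wFirst <- if (!is.null(parent$orfIds)) match(parent$orfIds[1L], ids) else NA_integer_
        wLast <- if (!is.null(parent$orfIds)) match(parent$orfIds[length(parent$orfIds)], ids) else NA_integer_
        if (stats::runif(1) < 0.5) {        # deletion
          start <- sample.int(L, 1L)
          del <- start:min(L, start + len - 1L)
          if (!is.na(wFirst) && any(del >= wFirst & del <= wLast)) next  # protect ORF
          ids <- ids[-del]
          bases <- bases[-del]
        } else {                            # insertion after position pos (0 = front)
          pos <- sample.int(L + 1L, 1L) - 1L
          if (!is.na(wFirst) && pos >= wFirst && pos < wLast) next       # protect ORF
          newIds <- reg$counter + seq_len(len)
          reg$counter <- reg$counter + len
          anchorAt <- if (pos == 0L) match(ids[1L], reg$ord) - 1L else match(ids[pos], reg$ord)
          reg$ord <- append(reg$ord, newIds, after = anchorAt)
          newBases <- sample(BASES, len, replace = TRUE, prob = pi)
          ids <- append(ids, newIds, after = pos)
          bases <- append(bases, newBases, after = pos)
        }
      }
      list(ids = ids, bases = bases, orfIds = parent$orfIds)
    }

    states <- list()
    rootState <- list(ids = seq_len(scn$locusLen),
                      bases = sample(BASES, scn$locusLen, replace = TRUE, prob = pi),
                      orfIds = NULL)
    if (scn$orfOriginBranch == "root") rootState <- plantWindow(rootState)
    states[[nodeName(root)]] <- rootState

    recurse <- function(nd) {
      for (ch in childrenOf[[as.character(nd)]]) {
        st <- evolveBranch(states[[nodeName(nd)]], edgeLen[ch])
        if (nodeName(ch) == scn$orfOriginBranch) st <- plantWindow(st)
        states[[nodeName(ch)]] <<- st
        if (ch > ntip) recurse(ch)
      }
    }
    recurse(root)

    ord <- reg$ord
    rows <- vapply(states, function(st) {
      row <- rep("-", length(ord))
      row[match(st$ids, ord)] <- st$bases
      paste(row, collapse = "")
    }, character(1))
    seqs <- vapply(states, function(st) paste(st$bases, collapse = ""), character(1))

    focalOrfSpan <- NULL
    focalState <- states[[scn$focalTaxon]]
    if (!is.null(focalState$orfIds)) {
      wpos <- match(focalState$orfIds, focalState$ids)
      focalOrfSpan <- c(min(wpos) - 1L, max(wpos))
    }
    structure(list(
      leafSeqs = seqs[phy$tip.label],
      trueAncestors = seqs[phy$node.label],
      trueAlignment = rows,
      originBranch = scn$orfOriginBranch,
      focalOrfSpan = focalOrfSpan,
      scenario = scn), class = "SimTruth")
  })
}

#' End-to-end branch recovery experiment on simulated loci
#'
#' For each scenario and replicate: simulate a locus, hand the pipeline only
#' what it would see in practice (the leaf alignment, the tree, and the
#' focal ORF), reconstruct ancestors, score best RFC and empirical P-value
#' at every ancestor on the focal path, call the branch of origin under the
#' P-value criterion, and compare with the simulated truth.
#'
#' @param scenarios named list of [simScenario()] objects (their `seed`
#'   fields are overridden by per-replicate seeds derived from `seed`).
#' @param nRepsPerScenario replicates per scenario.
#' @param seed master seed; per-replicate and per-node streams are derived
#'   with [deriveSeed()] so results are independent of evaluation order.
#' @param nReps randomizations per empirical P-value.
#' @param alpha significance threshold for the branch call.
#' @param criterion origin-assignment rule: `"pvalue"` (empirical P-value,
#'   the published default) or `"rfc_cutoff"` (first ancestor with best RFC
#'   above `rfcCutoff`; no null randomizations are run).
#' @param rfcCutoff RFC cutoff for `criterion = "rfc_cutoff"`.
#' @param minLen,params,deletionBias pipeline settings (see
#'   [bestRfcForNode()], [reconstructAncestors()]).
#' @return data.frame with one row per scenario x replicate: the true origin
#'   branch, the expected call (truth mapped to the root-excluded path:
#'   `"root"` maps to the most ancient non-root ancestor, a terminal origin
#'   to `"extant_only"`), the called branch, `correct`, and `nodeDist`
#'   (distance in path steps between call and expectation).
#' @export
recoveryExperiment <- function(scenarios, nRepsPerScenario = 20L, seed = 1L,
                               nReps = 200L, alpha = 0.01,
                               criterion = c("pvalue", "rfc_cutoff"),
                               rfcCutoff = 0.6, minLen = 30L,
                               params = alignParams(), deletionBias = FALSE) {
  criterion <- match.arg(criterion)
  out <- list()
  for (scName in names(scenarios)) {
    scn <- scenarios[[scName]]
    tree <- scn$tree
    path <- focalPathAncestors(tree, scn$focalTaxon)
    expected <- if (scn$orfOriginBranch == "root") path[1L]
      else if (scn$orfOriginBranch %in% treePhylo(tree)$tip.label) "extant_only"
      else scn$orfOriginBranch
    if (!expected %in% c(path, "extant_only"))
      stop(sprintf("origin branch '%s' is not on the focal path", scn$orfOriginBranch))
    for (rep in seq_len(nRepsPerScenario)) {
      repSeed <- deriveSeed(seed, sprintf("%s#%d", scName, rep))
      st <- simulateLocus(simScenario(
        tree = tree, locusLen = scn$locusLen, gcContent = scn$gcContent,
        subRateScale = scn$subRateScale, indelRate = scn$indelRate,
        indelLenGeomP = scn$indelLenGeomP, orfOriginBranch = scn$orfOriginBranch,
        orfLen = scn$orfLen, focalTaxon = scn$focalTaxon,
        purifyingStrength = scn$purifyingStrength,
        orfRateScale = scn$orfRateScale, plantAtg = scn$plantAtg,
        seed = repSeed))
      leafRows <- st$trueAlignment[treePhylo(tree)$tip.label]
      msa <- OrthologAlignment(leafRows, scn$focalTaxon,
                               focalOrfSpan = st$focalOrfSpan,
                               alignmentMode = "extended",
                               flankLen = st$focalOrfSpan[1L])
      refOrf <- focalOrfSeq(msa)
      # reconstruct on a tree whose branch lengths match the simulated
      # divergence (in practice branch lengths are estimated from the data)
      phySc <- treePhylo(tree)
      phySc$edge.length <- phySc$edge.length * scn$subRateScale
      treeSc <- new("PhyloTree", phy = phySc, rootExcluded = tree@rootExcluded)
      anc <- reconstructAncestors(msa, treeSc, fitBaseFreqs(msa),
                                  deletionBias = deletionBias)
      call <- if (criterion == "pvalue") {
        perNodeP <- vapply(path, function(nd) {
          ancSeq <- ancSequences(anc)[[nd]]
          if (!nchar(ancSeq)) return(1)
          empiricalPvalue(ancSeq, refOrf, nReps = nReps,
                          seed = deriveSeed(repSeed, nd), minLen = minLen,
                          params = params, nodeLabel = nd)$pValue
        }, numeric(1))
        assignBranchPvalue(perNodeP, tree, alpha = alpha,
                           focalTaxon = scn$focalTaxon)
      } else {
        perNodeRfc <- vapply(path, function(nd) {
          ancSeq <- ancSequences(anc)[[nd]]
          if (!nchar(ancSeq)) return(0)
          bestRfcForNode(ancSeq, refOrf, "noATG", minLen = minLen,
                         params = params)$bestRfc
        }, numeric(1))
        assignBranchCutoff(perNodeRfc, tree, rfcCutoff,
                           focalTaxon = scn$focalTaxon)
      }
      idxOf <- function(b) if (b == "extant_only") length(path) + 1L else match(b, path)
      out[[length(out) + 1L]] <- data.frame(
        scenario = scName, rep = rep, trueBranch = scn$orfOriginBranch,
        expectedCall = expected, calledBranch = call$branch,
        correct = call$branch == expected,
        nodeDist = abs(idxOf(call$branch) - idxOf(expected)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
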