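## Independent oracles used across the suite. These deliberately re-derive
## results through different code paths (plain-R dynamic programming, joint
## enumeration, per-column counting) than the implementations they check.

BASES4 <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

chars1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

randomSeq <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES4, n, replace = TRUE, prob = p), collapse = "")
}

## a stop-free (frame 0) coding sequence of n codons, no internal stops
randomOrfSeq <- function(nCodons) {
  codons <- apply(expand.grid(BASES4, BASES4, BASES4), 1, paste, collapse = "")
  codons <- setdiff(codons, STOPS)
  paste(sample(codons, nCodons, replace = TRUE), collapse = "")
}

## plain-R global alignment score oracle (same scoring semantics: gap run of
## length L costs open + (L-1)*extend; written independently of the C++ DP)
nwScoreOracle <- function(a, b, match = 5, mismatch = -4, open = -3, ext = -0.1) {
  A <- chars1(a); B <- chars1(b)
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1), 1] <- open + (0:(n - 1)) * ext
  if (m > 0) Y[1, 2:(m + 1)] <- open + (0:(m - 1)) * ext
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (A[i - 1] == "N" || B[j - 1] == "N") mismatch
         else if (A[i - 1] == B[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] + open, X[i - 1, j] + ext, Y[i - 1, j] + open)
    Y[i, j] <- max(M[i, j - 1] + open, X[i, j - 1] + open, Y[i, j - 1] + ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## per-column RFC counting oracle: explicit walk over alignment columns
rfcOracle <- function(refRow, ancRow, refOrfLen, ancStart, ancEnd) {
  rr <- chars1(refRow); ar <- chars1(ancRow)
  refSeen <- 0L; ancSeen <- 0L; count <- 0L
  for (k in seq_along(rr)) {
    refGap <- rr[k] == "-"; ancGap <- ar[k] == "-"
    if (!refGap && !ancGap &&
        refSeen < refOrfLen &&
        ancSeen >= ancStart && ancSeen < ancEnd &&
        (refSeen %% 3L) == ((ancSeen - ancStart) %% 3L))
      count <- count + 1L
    if (!refGap) refSeen <- refSeen + 1L
    if (!ancGap) ancSeen <- ancSeen + 1L
  }
  count / refOrfLen
}

## brute-force re-scan of one reported ORF hit: stop-free inside, proper
## boundaries for its definition
checkOrfHit <- function(seq, hit, minLen) {
  n <- nchar(seq)
  len <- hit$end - hit$start
  codon <- function(p) substr(seq, p + 1, p + 3)  # 0-based start
  ok <- len %% 3 == 0 && len > minLen && hit$start %% 3 == hit$frame %% 3
  if (len >= 6)
    for (p in seq(hit$start, hit$end - 6, by = 3))
      ok <- ok && !(codon(p) %in% STOPS)
  lastCod <- codon(hit$end - 3)
  if (hit$end + 3 <= n)  # not at the sequence edge: must end at a stop
    ok <- ok && (lastCod %in% STOPS)
  if (hit$definition == "ATG") ok <- ok && codon(hit$start) == "ATG"
  else if (hit$start >= 3)      # noATG: maximal, so a stop just upstream
    ok <- ok && (codon(hit$start - 3) %in% STOPS)
  ok
}

## joint-enumeration posterior oracle for small trees: enumerates all state
## assignments at internal nodes, computing transition matrices with
## ape::matexpo and building the GTR generator from first principles
enumPosteriorOracle <- function(phy, leafStates, freqs, rates = rep(1, 6),
                                catRates = 1) {
  B <- BASES4
  Q <- matrix(0, 4, 4, dimnames = list(B, B))
  pairIdx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pairIdx[k, 1]; j <- pairIdx[k, 2]
    Q[i, j] <- rates[k] * freqs[j]
    Q[j, i] <- rates[k] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(freqs * diag(Q)))
  ntip <- length(phy$tip.label)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  internals <- sort(unique(phy$edge[, 1]))
  k <- length(internals)
  grid <- as.matrix(expand.grid(rep(list(1:4), k)))
  postTot <- matrix(0, k, 4, dimnames = list(as.character(internals), B))
  for (cr in catRates) {
    Pt <- lapply(seq_len(nrow(phy$edge)), function(e)
      ape::matexpo(Q * phy$edge.length[e] * cr))
    probs <- apply(grid, 1, function(assign) {
      stateOf <- function(nd) {
        if (nd <= ntip) match(leafStates[[phy$tip.label[nd]]], B)
        else assign[match(nd, internals)]
      }
      p <- freqs[assign[match(root, internals)]]
      for (e in seq_len(nrow(phy$edge))) {
        sPar <- stateOf(phy$edge[e, 1]); sCh <- stateOf(phy$edge[e, 2])
        if (is.na(sCh)) next  # leaf with gap/N: marginalized (row sums to 1)
        p <- p * Pt[[e]][sPar, sCh]
      }
      p
    })
    for (i in seq_len(k)) for (s in 1:4)
      postTot[i, s] <- postTot[i, s] + sum(probs[grid[, i] == s]) / length(catRates)
  }
  post <- postTot / rowSums(postTot)
  rownames(post) <- vapply(internals, function(nd)
    phy$node.label[nd - ntip], character(1))
  list(posterior = post, lik = sum(postTot[1, ]))
}
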