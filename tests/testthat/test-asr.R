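test_that("fitBaseFreqs matches direct counting with a pseudocount floor", {
  eps <- 1e-4
  msaEq <- OrthologAlignment(
    c(A = paste(rep("ACGT", 15), collapse = ""),
      B = paste(rep("ACGT", 15), collapse = "")), "A")
  expect_equal(unname(fitBaseFreqs(msaEq)@baseFreqs), rep(0.25, 4),
               tolerance = 1e-12)

  msaA <- OrthologAlignment(c(A = strrep("A", 60), B = strrep("A", 60)), "A")
  expect_equal(unname(fitBaseFreqs(msaA)@baseFreqs),
               c(1 - 3 * eps, eps, eps, eps), tolerance = 1e-12)

  ## 60% GC simulated alignment: frequencies within 0.02 of (0.2,0.3,0.3,0.2)
  tr <- speciesTree()
  st <- simulateLocus(simScenario(tr, locusLen = 2000, gcContent = 0.6,
                                  subRateScale = 0.5, seed = 7))
  msa <- OrthologAlignment(st$trueAlignment[treePhylo(tr)$tip.label], "Scer",
                           focalOrfSpan = c(0L, 300L),
                           alignmentMode = "extended")
  fr <- fitBaseFreqs(msa)@baseFreqs
  expect_lt(max(abs(fr - c(0.2, 0.3, 0.3, 0.2))), 0.02)
  ## direct counting oracle on the same data
  all <- paste(alignedSeqs(msa), collapse = "")
  cnt <- as.numeric(table(factor(chars1(all), levels = BASES4)))
  expect_equal(unname(fr), cnt / sum(cnt) * (1 - 4e-4) + 1e-4,
               tolerance = 1e-12)
})

test_that("GTR rate matrix rows sum to zero and mean rate is one", {
  m <- SubstitutionModel(baseFreqs = c(0.1, 0.2, 0.3, 0.4),
                         rates = c(1, 2, 3, 4, 5, 6))
  Q <- gtrRateMatrix(m)
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(-sum(m@baseFreqs * diag(Q)), 1, tolerance = 1e-12)
})

test_that("marginal posteriors equal exhaustive joint enumeration", {
  ## 4-leaf tree, JC special case, t = 0.1 everywhere
  tr <- quartetTree()
  phy <- treePhylo(tr)
  msa <- OrthologAlignment(
    c(A = paste0("A", strrep("A", 29)), B = paste0("A", strrep("A", 29)),
      C = paste0("G", strrep("A", 29)), D = paste0("G", strrep("A", 29))), "A")
  ms <- marginalStates(msa, tr, SubstitutionModel())
  oracle <- enumPosteriorOracle(phy, list(A = "A", B = "A", C = "G", D = "G"),
                                freqs = rep(0.25, 4))
  for (nd in rownames(oracle$posterior))
    expect_equal(unname(ms[[nd]]$postMatrix[, 1]),
                 unname(oracle$posterior[nd, ]), tolerance = 1e-9)

  ## randomized instances: 5-leaf tree, non-uniform freqs, gaps, 2 gamma cats
  nwk <- "(((A:0.05,B:0.2)N1:0.1,C:0.3)N2:0.15,(D:0.25,E:0.1)N3:0.2)Root;"
  tr5 <- readTree(nwk)
  phy5 <- treePhylo(tr5)
  freqs <- c(A = 0.35, C = 0.15, G = 0.2, T = 0.3)
  shape <- 0.8
  catR <- unname(orfancestry:::gammaCategoryRates(shape, 2L))
  set.seed(11)
  cols <- replicate(12, sample(c(BASES4, "-"), 5, replace = TRUE,
                               prob = c(rep(0.22, 4), 0.12)))
  cols[, 1] <- rep("A", 5)  # ensure at least one fully observed uniform column
  cols[1, cols[1, ] == "-"] <- "T"  # keep the focal row gap-free
  recs <- apply(cols, 1, paste, collapse = "")
  names(recs) <- c("A", "B", "C", "D", "E")
  recs <- vapply(recs, function(s) paste0(s, strrep("A", 30 - nchar(s))),
                 character(1))
  msa5 <- OrthologAlignment(recs, "A")
  model <- SubstitutionModel(baseFreqs = freqs, gammaShape = shape,
                             nCategories = 2L)
  ms5 <- marginalStates(msa5, tr5, model)
  for (col in 1:12) {
    leafStates <- as.list(cols[, col])
    names(leafStates) <- c("A", "B", "C", "D", "E")
    if (all(unlist(leafStates) == "-")) next
    oracle <- enumPosteriorOracle(phy5, leafStates, freqs = freqs,
                                  catRates = catR)
    for (nd in rownames(oracle$posterior))
      expect_equal(unname(ms5[[nd]]$postMatrix[, col]),
                   unname(oracle$posterior[nd, ]), tolerance = 1e-9,
                   label = sprintf("node %s column %d", nd, col))
  }
  ## posteriors sum to one everywhere
  for (nd in names(ms5))
    expect_equal(unname(colSums(ms5[[nd]]$postMatrix)), rep(1, 30),
                 tolerance = 1e-9)
})

test_that("marginal reconstruction limit and symmetry cases hold", {
  ## identical leaves, shrinking branch lengths: posterior of observed base -> 1
  for (t in c(0.5, 0.05, 0.005)) {
    tr <- readTree(sprintf("((A:%g,B:%g)N1:%g,C:%g)Root;", t, t, t, t))
    msa <- OrthologAlignment(
      setNames(rep(strrep("C", 30), 3), c("A", "B", "C")), "A")
    ms <- marginalStates(msa, tr, SubstitutionModel())
    expect_identical(ms[["N1"]]$state[1], "C")
    if (t == 0.005) expect_gt(ms[["N1"]]$posterior[1], 0.99)
  }
  ## two-leaf symmetry: leaves A and G, equal branches, JC
  tr2 <- readTree("(A:0.2,B:0.2)Root;")
  msa2 <- OrthologAlignment(c(A = paste0("A", strrep("T", 29)),
                              B = paste0("G", strrep("T", 29))), "A")
  pm <- marginalStates(msa2, tr2, SubstitutionModel())[["Root"]]$postMatrix
  expect_equal(unname(pm["A", 1]), unname(pm["G", 1]), tolerance = 1e-12)
  expect_equal(unname(pm["A", 1]),
               unname(0.5 * (1 - pm["C", 1] - pm["T", 1])), tolerance = 1e-12)
})

test_that("reconstruction is invariant to leaf input order", {
  tr <- quartetTree()
  set.seed(4)
  recs <- setNames(replicate(4, randomSeq(60)), c("A", "B", "C", "D"))
  m1 <- OrthologAlignment(recs, "A")
  m2 <- OrthologAlignment(recs[c("D", "B", "A", "C")], "A")
  model <- fitBaseFreqs(m1)
  a1 <- reconstructAncestors(m1, tr, model)
  a2 <- reconstructAncestors(m2, tr, model)
  expect_identical(ancSequences(a1), ancSequences(a2))
})

test_that("Fitch indel reconstruction handles clear and ambiguous columns", {
  tr <- quartetTree()
  ## col 1: present everywhere; col 2: gap everywhere; col 3: present in the
  ## (A,B) clade only -> root ambiguous, N1 present, N2 absent
  recs <- c(A = "A-C" , B = "A-C", C = "A--", D = "A--")
  recs <- vapply(recs, function(s) paste0(s, strrep("G", 28)), character(1))
  msa <- OrthologAlignment(recs, "A")
  insBias <- reconstructIndels(msa, tr, deletionBias = FALSE)
  delBias <- reconstructIndels(msa, tr, deletionBias = TRUE)
  for (ind in list(insBias, delBias)) {
    expect_true(all(ind$nodePresence[, 1]))
    expect_false(any(ind$nodePresence[, 2]))
    expect_true(ind$nodePresence["N1", 3])
    expect_false(ind$nodePresence["N2", 3])
  }
  ## the tie at the root resolves by the deletion-bias flag
  expect_false(insBias$nodePresence["Root", 3])
  expect_true(delBias$nodePresence["Root", 3])
  expect_equal(unname(insBias$ambiguityFraction[c("N1", "N2")]), c(0, 0))
  expect_equal(unname(insBias$ambiguityFraction["Root"]), 1 / 31)
  ## flag toggles only ambiguous columns
  diffCols <- which(apply(insBias$nodePresence != delBias$nodePresence, 2, any))
  expect_true(all(diffCols %in% 3))
})

test_that("ancestors of identical leaves equal the leaves; truth is recovered", {
  tr <- speciesTree()
  seq <- randomOrfSeq(20)
  recs <- setNames(rep(seq, 8), treePhylo(tr)$tip.label)
  msa <- OrthologAlignment(recs, "Scer")
  anc <- reconstructAncestors(msa, tr, fitBaseFreqs(msa))
  for (nd in internalNodeLabels(tr))
    expect_identical(unname(ancSequences(anc)[[nd]]), seq)

  ## simulated truth, no indels, modest rates: >= 95% identity at the
  ## shallowest ancestor
  st <- simulateLocus(simScenario(tr, locusLen = 600, subRateScale = 1,
                                  indelRate = 0, seed = 21))
  msaS <- OrthologAlignment(st$trueAlignment[treePhylo(tr)$tip.label], "Scer",
                            focalOrfSpan = c(0L, 600L))
  ancS <- reconstructAncestors(msaS, tr, fitBaseFreqs(msaS))
  rec <- chars1(ancSequences(ancS)[["Anc1"]])
  tru <- chars1(st$trueAncestors[["Anc1"]])
  expect_identical(length(rec), length(tru))
  expect_gt(mean(rec == tru), 0.95)
})
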