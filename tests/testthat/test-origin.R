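pathRfc <- function(...) {
  v <- c(...)
  names(v) <- c("Anc5", "Anc4", "Anc3", "Anc2", "Anc1")[seq_along(v)]
  v
}

test_that("cutoff-based branch assignment walks root-to-leaf correctly", {
  tr <- speciesTree()
  allHigh <- pathRfc(1, 1, 1, 1, 1)
  expect_identical(assignBranchCutoff(allHigh, tr, 0.9, "Scer")$branch, "Anc5")
  allLow <- pathRfc(0, 0, 0, 0, 0)
  expect_identical(assignBranchCutoff(allLow, tr, 0.5, "Scer")$branch,
                   "extant_only")
  v <- pathRfc(0.4, 0.7, 0.9, 0.95, 1)
  expect_identical(assignBranchCutoff(v, tr, 0.6, "Scer")$branch, "Anc4")
  ## strict inequality at the boundary
  expect_identical(assignBranchCutoff(pathRfc(0.6, 0.6, 0.6, 0.6, 0.6),
                                      tr, 0.6, "Scer")$branch, "extant_only")
  expect_error(assignBranchCutoff(allHigh[-1], tr, 0.5, "Scer"), "missing")
})

test_that("P-value branch assignment and downstream consistency follow the rule", {
  tr <- speciesTree()
  allSig <- pathRfc(0.001, 0.001, 0.001, 0.001, 0.001)
  cl <- assignBranchPvalue(allSig, tr, 0.01, "Scer")
  expect_identical(cl$branch, "Anc5")
  expect_equal(cl$downstreamConsistency, 1)
  expect_identical(assignBranchPvalue(pathRfc(.5, .5, .5, .5, .5), tr, 0.01,
                                      "Scer")$branch, "extant_only")
  cl2 <- assignBranchPvalue(pathRfc(0.2, 0.004, 0.3, 0.002, 0.001), tr, 0.01,
                            "Scer")
  expect_identical(cl2$branch, "Anc4")
  expect_equal(cl2$downstreamConsistency, 2 / 3)
})

test_that("alpha limits and cutoff monotonicity hold on random inputs", {
  tr <- speciesTree()
  set.seed(20)
  for (rep in 1:25) {
    p <- pathRfc(runif(5))
    expect_identical(assignBranchPvalue(p, tr, alpha = 1, "Scer")$branch, "Anc5")
    expect_identical(assignBranchPvalue(p, tr, alpha = 0, "Scer")$branch,
                     "extant_only")
    rfc <- pathRfc(runif(5))
    path <- focalPathAncestors(tr, "Scer")
    idxOf <- function(b) if (b == "extant_only") 6L else match(b, path)
    prev <- idxOf(assignBranchCutoff(rfc, tr, 0, "Scer")$branch)
    for (cut in c(0.25, 0.5, 0.75, 1)) {
      cur <- idxOf(assignBranchCutoff(rfc, tr, cut, "Scer")$branch)
      expect_gte(cur, prev)   # raising the cutoff never gives a more ancient branch
      prev <- cur
    }
  }
})

test_that("robust-ancient requires the whole focal path above the cutoff", {
  tr <- speciesTree()
  expect_true(robustAncient(pathRfc(1, 1, 1, 1, 1), tr, 0.9, focalTaxon = "Scer"))
  expect_false(robustAncient(pathRfc(0.95, 0.95, 0.95, 0.95, 0.2), tr, 0.9,
                             focalTaxon = "Scer"))
  ## boundary: exactly 0.9 fails the strict criterion
  expect_false(robustAncient(pathRfc(0.9, 1, 1, 1, 1), tr, 0.9,
                             focalTaxon = "Scer"))
  ## robust-ancient implies the 0.9-cutoff call is the most ancient ancestor
  set.seed(33)
  for (rep in 1:25) {
    rfc <- pathRfc(runif(5, 0.5, 1))
    if (robustAncient(rfc, tr, 0.9, focalTaxon = "Scer"))
      expect_identical(assignBranchCutoff(rfc, tr, 0.9, "Scer")$branch, "Anc5")
  }
})

test_that("ensemble classification groups variants as specified", {
  mkCall <- function(branch) structure(list(branch = branch), class = "originCall")
  calls <- function(...) {
    b <- c(...)
    setNames(lapply(b, mkCall), paste0("v", seq_along(b)))
  }
  ens <- classifyEnsemble(calls("Anc5", "Anc5", "Anc5", "Anc5"), "Anc5")
  expect_identical(ens$category, "high_confidence_ancient")
  expect_equal(ens$nAgreeing, 4)

  ens2 <- classifyEnsemble(calls("extant_only", "extant_only", "extant_only",
                                 "extant_only"), "Anc5")
  expect_identical(ens2$category, "high_confidence_de_novo")
  expect_true(all(ens2$variantBranches == "extant_only"))  # species-specific

  ens3 <- classifyEnsemble(calls("Anc5", "Anc5", "Anc1", "extant_only"), "Anc5")
  expect_identical(ens3$category, "low_confidence_ancient")
  expect_equal(ens3$nAgreeing, 2)

  ens4 <- classifyEnsemble(calls("Anc4", "Anc4", "Anc5", "Anc5", "Anc5"), "Anc5")
  expect_identical(ens4$category, "other")

  ## invariant to variant ordering
  ens5 <- classifyEnsemble(calls("extant_only", "Anc1", "Anc5", "Anc5"), "Anc5")
  expect_identical(ens5$category, ens3$category)
  expect_error(classifyEnsemble(calls("Anc5"), "Anc5"), ">= 2")
})

test_that("alignment statistics match closed-form Kimura and gap counting", {
  msaId <- OrthologAlignment(c(A = strrep("ACGT", 9), B = strrep("ACGT", 9)),
                             "A")
  st <- msaStats(msaId)
  expect_equal(st$gapsPerSeq, 0)
  expect_equal(st$meanKimura, 0)

  ## exactly P = 0.1 (transitions), Q = 0.05 (transversions) over 1000 sites
  a <- rep("A", 1000)
  b <- a
  b[1:100] <- "G"     # transitions
  b[101:150] <- "C"   # transversions
  msaPQ <- OrthologAlignment(c(A = paste(a, collapse = ""),
                               B = paste(b, collapse = "")), "A",
                             focalOrfSpan = c(0L, 999L),
                             alignmentMode = "extended")
  d <- msaStats(msaPQ)$meanKimura
  expect_equal(d, -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               tolerance = 1e-12)

  ## an all-gap column raises gaps/seq by exactly 1, Kimura unchanged
  msaGap <- OrthologAlignment(c(A = paste(c(a, "-"), collapse = ""),
                                B = paste(c(b, "-"), collapse = "")), "A",
                              focalOrfSpan = c(0L, 999L),
                              alignmentMode = "extended")
  stG <- msaStats(msaGap)
  expect_equal(stG$gapsPerSeq, 1)
  expect_equal(stG$meanKimura, d, tolerance = 1e-12)

  ## saturated pair: undefined distance excluded with a warning
  msaSat <- OrthologAlignment(c(A = strrep("A", 30), B = strrep("G", 30),
                                C = strrep("A", 30)), "A")
  expect_warning(stS <- msaStats(msaSat), "undefined")
  expect_equal(stS$meanKimura, 0)  # only the A-C pair remains
})
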