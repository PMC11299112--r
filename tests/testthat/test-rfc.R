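test_that("global alignment is correct and deterministic on edge cases", {
  s <- randomOrfSeq(10)  # 30 nt
  a <- alignGlobal(s, s)
  expect_identical(a$refRow, s)
  expect_identical(a$ancRow, s)
  expect_equal(a$score, 30 * 5)

  ## several tied optima: fixed traceback yields one canonical result
  a1 <- alignGlobal("ACGT", "AC")
  a2 <- alignGlobal("ACGT", "AC")
  expect_identical(a1$refRow, a2$refRow)
  expect_identical(a1$ancRow, a2$ancRow)
  ## ungapping the rows recovers the inputs
  expect_identical(gsub("-", "", a1$refRow), "ACGT")
  expect_identical(gsub("-", "", a1$ancRow), "AC")

  expect_error(alignGlobal("", "ACGT"), "empty")
})

test_that("alignment scores match an independent plain-R DP oracle", {
  set.seed(99)
  for (rep in 1:25) {
    x <- randomSeq(50)
    y <- randomSeq(sample(30:60, 1))
    a <- alignGlobal(x, y)
    expect_equal(a$score, nwScoreOracle(x, y), tolerance = 1e-9)
    ## the reported alignment realizes the reported score
    sc <- 0; inGapX <- FALSE; inGapY <- FALSE
    rr <- chars1(a$refRow); ar <- chars1(a$ancRow)
    for (k in seq_along(rr)) {
      if (rr[k] == "-") {
        sc <- sc + if (inGapY) -0.1 else -3; inGapY <- TRUE; inGapX <- FALSE
      } else if (ar[k] == "-") {
        sc <- sc + if (inGapX) -0.1 else -3; inGapX <- TRUE; inGapY <- FALSE
      } else {
        sc <- sc + if (rr[k] == ar[k]) 5 else -4
        inGapX <- inGapY <- FALSE
      }
    }
    expect_equal(sc, a$score, tolerance = 1e-9)
  }
})

test_that("RFC reproduces the worked 43/50 example and the identity case", {
  ## 50-nt reference ORF; ancestral copy loses one base after 43 reference
  ## positions, shifting frame for the remaining 7 -> RFC = 43/50 = 0.86
  ref <- randomOrfSeq(17)
  ref <- substr(ref, 1, 50)
  anc <- paste0(substr(ref, 1, 43), substr(ref, 45, 50))
  aln <- list(refRow = ref,
              ancRow = paste0(substr(ref, 1, 43), "-", substr(ref, 45, 50)))
  expect_identical(gsub("-", "", aln$ancRow), anc)
  expect_equal(computeRfc(aln, 50L, list(start = 0L, end = 48L)), 0.86)
  expect_equal(rfcOracle(aln$refRow, aln$ancRow, 50L, 0L, 48L), 0.86)

  ## ancestral sequence containing the reference ORF verbatim -> RFC 1
  ref300 <- randomOrfSeq(100)
  anc300 <- paste0("TAAGGG", ref300, "CCTAA")
  res <- bestRfcForNode(anc300, ref300, "noATG")
  expect_equal(res$bestRfc, 1)

  ## ancestral ORF aligned wholly outside the reference ORF -> RFC 0
  aln0 <- list(refRow = paste0(strrep("-", 12), "ACGACGACG"),
               ancRow = paste0("GGGTTTGGGTTT", strrep("-", 9)))
  expect_equal(computeRfc(aln0, 9L, list(start = 0L, end = 12L)), 0)
})

test_that("RFC equals the per-column counting oracle on random alignments", {
  set.seed(123)
  for (rep in 1:40) {
    ref <- randomSeq(60)
    anc <- randomSeq(90)
    aln <- alignGlobal(ref, anc)
    s <- sample(0:30, 1)
    e <- s + 3 * sample(5:15, 1)
    e <- min(e, 90)
    if ((e - s) %% 3 != 0) e <- e - (e - s) %% 3
    expect_equal(computeRfc(aln, 60L, list(start = s, end = e)),
                 rfcOracle(aln$refRow, aln$ancRow, 60L, s, e),
                 tolerance = 1e-12)
  }
})

test_that("RFC invariants: content outside ORFs, overlap bound, monotonicity", {
  set.seed(5)
  ref <- randomOrfSeq(20)  # 60 nt
  ## a 1-nt frameshift at the midpoint: manual column count
  anc <- paste0(substr(ref, 1, 30), substr(ref, 32, 60))
  aln <- alignGlobal(ref, anc)
  manual <- rfcOracle(aln$refRow, aln$ancRow, 60L, 0L, 57L)
  expect_equal(computeRfc(aln, 60L, list(start = 0L, end = 57L)), manual)

  for (rep in 1:10) {
    refR <- randomSeq(45)
    ancR <- randomSeq(60)
    alnR <- alignGlobal(refR, ancR)
    ix <- orfancestry:::alnIndex(alnR)
    s <- 3L; e <- 33L
    val <- computeRfc(alnR, 45L, list(start = s, end = e))
    ## never exceeds aligned non-gap overlap of the two ORFs / ref length
    overlap <- sum(ix$refCh & ix$ancCh & ix$refIdx <= 45L &
                   ix$ancIdx - 1L >= s & ix$ancIdx - 1L < e)
    expect_lte(val, overlap / 45)
    ## extending the ancestral ORF in frame never decreases RFC
    val2 <- computeRfc(alnR, 45L, list(start = s, end = e + 9L))
    expect_gte(val2, val)
  }
})

test_that("best-RFC per node follows the strand policy and tie-breaks", {
  set.seed(31)
  ref <- randomOrfSeq(60)  # 180 nt
  expect_equal(bestRfcForNode(ref, ref, "noATG")$bestRfc, 1)

  ## reverse complement: forward-strand scan only, near-zero RFC
  rc <- paste(rev(chartr("ACGT", "TGCA", chars1(ref))), collapse = "")
  expect_lt(bestRfcForNode(rc, ref, "noATG")$bestRfc, 0.3)

  ## no qualifying ORF: best RFC 0 and absent ORF
  res <- bestRfcForNode("TAATAAGTAATAGCTAATGATTAATAGATAATGACTAATAAC", ref,
                        "noATG", minLen = 30)
  expect_equal(res$bestRfc, 0)
  expect_null(res$bestOrf)

  ## planted in-frame ORF of 0.8x the reference length scores about 0.8
  part <- substr(ref, 1, 144)
  anc <- paste0("CCTAAC", part, "TAACCC")
  r <- bestRfcForNode(anc, ref, "noATG")
  expect_equal(r$bestRfc, 0.8, tolerance = 0.05)
})
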