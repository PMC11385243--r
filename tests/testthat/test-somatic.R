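mkCalls <- function(pos, hf, alt = NULL, depth = 2000L, low = FALSE,
                    sample = "cell") {
  if (!length(pos)) {
    calls <- data.frame(pos = integer(), ref = character(),
                        alt = character(), altDepth = integer(),
                        refDepth = integer(), depth = integer(),
                        hf = numeric(), zygosity = character(),
                        pError = numeric(), lowConfidence = logical(),
                        stringsAsFactors = FALSE)
    attr(calls, "sample") <- sample
    return(calls)
  }
  refv <- refBase(REF, pos)
  if (is.null(alt))
    alt <- vapply(refv, function(r)
      setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  altD <- as.integer(round(hf * depth))
  calls <- data.frame(pos = as.integer(pos), ref = refv, alt = unname(alt),
                      altDepth = altD, refDepth = depth - altD,
                      depth = depth, hf = hf,
                      zygosity = classifyZygosity(hf),
                      pError = 0, lowConfidence = low,
                      stringsAsFactors = FALSE)
  attr(calls, "sample") <- sample
  calls
}

test_that("masking removes exactly the masked calls, preserving order", {
  calls <- mkCalls(c(515L, 5000L, 310L, 7000L), c(0.1, 0.2, 0.3, 0.4))
  kept <- applyMasks(calls, MASKS)
  expect_identical(kept$pos, c(5000L, 7000L))
  expect_identical(nrow(applyMasks(calls[0, ], MASKS)), 0L)
})

test_that("homology similarity is the shared fraction of consensus
           homoplasmies", {
  pos <- sort(sample(setdiff(seq_len(GENOME_LEN), maskedPositions(MASKS)),
                     10L))
  cons <- mkCalls(pos, rep(0.999, 10), sample = "consensus")
  cellSame <- mkCalls(pos, rep(0.995, 10), alt = cons$alt, sample = "c1")
  r <- homologyCheck(cellSame, cons)
  expect_equal(r$sharedFraction, 1)
  expect_true(r$pass)

  cell9 <- mkCalls(pos[1:9], rep(0.995, 9), alt = cons$alt[1:9],
                   sample = "c2")
  r9 <- homologyCheck(cell9, cons)
  expect_equal(r9$sharedFraction, 0.9)
  expect_false(r9$pass)

  expect_warning(r0 <- homologyCheck(cellSame, cons[0, ]),
                 "no homoplasmic")
  expect_true(is.na(r0$pass))
})

test_that("a contaminant cell with a different germline haplotype fails
           homology", {
  sim <- simulateSample(simSampleConfig(nCells = 2L, seed = 201L),
                        REF, MASKS, MAP, sampleName = "S1")
  other <- simulateSample(simSampleConfig(nCells = 1L, seed = 202L),
                          REF, MASKS, MAP, sampleName = "S2")
  consCalls <- applyMasks(callVariants(sim$consensus, REF), MASKS)
  own <- applyMasks(callVariants(sim$cells[[1]], REF), MASKS)
  attr(own, "sample") <- "own"
  contaminant <- applyMasks(callVariants(other$cells[[1]], REF), MASKS)
  attr(contaminant, "sample") <- "contaminant"
  expect_true(homologyCheck(own, consCalls)$pass)
  expect_false(homologyCheck(contaminant, consCalls)$pass)
})

test_that("somatic definition: heteroplasmic, consensus-absent, private", {
  consensus <- mkCalls(3000L, 0.05, sample = "consensus")
  cellA <- mkCalls(c(1000L, 2000L, 3000L), c(0.10, 0.10, 0.10),
                   alt = c("X", "X", consensus$alt[1]), sample = "A")
  cellA$alt[1:2] <- vapply(cellA$ref[1:2], function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  cellB <- mkCalls(2000L, 0.10, alt = cellA$alt[2], sample = "B")
  svs <- identifySomatic(list(A = cellA, B = cellB), consensus,
                         sample = "s")
  out <- somaticCalls(svs)
  # pos 1000: HF 0.10 in cell A only, absent elsewhere -> somatic in A
  # pos 2000: present in A and B -> somatic in neither
  # pos 3000: present in consensus at 0.05 -> not somatic
  expect_identical(out$pos, 1000L)
  expect_identical(out$cell, "A")
  expect_true(all(out$consensusAbsent & out$privacyPassed))
})

test_that("sub-threshold presence in a comparator does not veto privacy", {
  consensus <- mkCalls(integer(0), numeric(0), sample = "consensus")
  cellA <- mkCalls(1000L, 0.10, sample = "A")
  cellB <- mkCalls(1000L, 0.01, alt = cellA$alt, sample = "B")
  svs <- identifySomatic(list(A = cellA, B = cellB), consensus)
  expect_identical(somaticCalls(svs)$cell, "A")
})

test_that("single-cell samples degrade gracefully with a warning", {
  consensus <- mkCalls(integer(0), numeric(0))
  cellA <- mkCalls(1000L, 0.10, sample = "A")
  expect_warning(svs <- identifySomatic(list(A = cellA), consensus),
                 "privacy criterion degenerates")
  expect_identical(somaticCalls(svs)$pos, 1000L)
})

test_that("somatic sets are disjoint across cells and shrink monotonically
           with the analysis floor", {
  sim <- simulateSample(simSampleConfig(nCells = 6L, seed = 301L),
                        REF, MASKS, MAP, sampleName = "S1")
  res <- runSample(sim$cells, sim$consensus, REF, MASKS, sampleName = "S1")
  calls <- somaticCalls(res$somatic)
  expect_false(anyDuplicated(paste(calls$pos, calls$alt)) > 0)
  floors <- c(0.02, 0.05, 0.10, 0.20)
  counts <- vapply(floors, function(f)
    nrow(somaticCalls(identifySomatic(res$cellCalls, res$consensusCalls,
                                      analysisFloor = f,
                                      sample = "S1"))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a diluted private variant is treated as consensus-absent only
           below the detection floor", {
  # HF 0.30 in 1 of 10 cells -> consensus fraction 0.03 >= floor: vetoed;
  # HF 0.10 in 1 of 10 cells -> consensus fraction 0.01 < floor: somatic
  pool <- setdiff(seq_len(GENOME_LEN), maskedPositions(MASKS))
  p1 <- pool[100]; p2 <- pool[200]
  a1 <- setdiff(c("A", "C", "G", "T"), refBase(REF, p1))[1]
  a2 <- setdiff(c("A", "C", "G", "T"), refBase(REF, p2))[1]
  cells <- c(list(A = mkCalls(c(p1, p2), c(0.30, 0.10), alt = c(a1, a2),
                              sample = "A")),
             lapply(paste0("B", 1:9), function(nm)
               mkCalls(integer(0), numeric(0), sample = nm)))
  names(cells)[-1] <- paste0("B", 1:9)
  consensus <- mkCalls(c(p1, p2), c(0.03, 0.01), alt = c(a1, a2),
                       sample = "consensus")
  svs <- identifySomatic(cells, consensus, sample = "s")
  expect_identical(somaticCalls(svs)$pos, p2)
})
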