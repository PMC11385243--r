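codingPositions <- function() {
  iv <- MAP@intervals
  pc <- iv[iv$class == "protein-coding", ]
  unlist(lapply(seq_len(nrow(pc)), function(i) pc$start[i]:pc$end[i]))
}

randomCoding <- function(n, seed, genes = NULL) {
  set.seed(seed)
  iv <- MAP@intervals
  pc <- iv[iv$class == "protein-coding", ]
  if (!is.null(genes)) pc <- pc[pc$name %in% genes, ]
  pos <- sample(unlist(lapply(seq_len(nrow(pc)), function(i)
    pc$start[i]:pc$end[i])), n, replace = TRUE)
  refv <- refBase(REF, pos)
  alt <- vapply(refv, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  data.frame(pos = as.integer(pos), ref = refv, alt = unname(alt),
             stringsAsFactors = FALSE)
}

test_that("the hard-coded vertebrate mitochondrial code departs from the
           standard code exactly where it should", {
  expect_identical(translateCodons(c("AGA", "AGG")), c("*", "*"))
  expect_identical(translateCodons("ATA"), "M")
  expect_identical(translateCodons("TGA"), "W")
  expect_identical(translateCodons(c("ATG", "TAA", "TGG")),
                   c("M", "*", "W"))
  expect_true(is.na(translateCodons("NNA")))
})

test_that("locus gates: non-coding variants never get protein consequences
           or pathogenicity flags", {
  pos <- c(100L, 650L)  # D-loop, rRNA
  calls <- data.frame(pos = pos, ref = refBase(REF, pos), alt = "A",
                      stringsAsFactors = FALSE)
  calls$alt <- vapply(calls$ref, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  ann <- annotateConsequence(calls, MAP, REF)
  expect_identical(ann$consequence, c("non-coding", "non-coding"))
  st <- scoreTable(data.frame(pos = pos, ref = calls$ref, alt = calls$alt,
                              score = c(0.9, 0.9)), tool = "MutPred")
  cls <- classifyPathogenicity(ann, mutpred = st)
  expect_true(all(is.na(cls$pathogenicMutpred)))
})

test_that("annotation agrees with brute-force whole-protein translation", {
  v <- randomCoding(250, seed = 42)
  ann <- annotateConsequence(v, MAP, REF)
  # evaluate the oracle in the gene the annotation chose
  oracle <- vapply(seq_len(nrow(v)), function(i)
    bruteForceConsequence(v$pos[i], v$alt[i], ann$gene[i]), character(1))
  expect_identical(ann$consequence, oracle)
})

test_that("light-strand MT-ND6 variants are annotated on the reverse
           complement", {
  v <- randomCoding(80, seed = 43, genes = "MT-ND6")
  ann <- annotateConsequence(v, MAP, REF)
  expect_true(all(ann$gene == "MT-ND6"))
  oracle <- vapply(seq_len(nrow(v)), function(i)
    bruteForceConsequence(v$pos[i], v$alt[i], "MT-ND6"), character(1))
  expect_identical(ann$consequence, oracle)
})

test_that("stop gain and loss carry sub-flags and count as non-synonymous", {
  v <- randomCoding(800, seed = 44)
  ann <- annotateConsequence(v, MAP, REF)
  sg <- ann[!is.na(ann$subType) & ann$subType == "stop_gain", ]
  expect_gt(nrow(sg), 0)
  expect_true(all(sg$consequence == "non-synonymous"))
  expect_true(all(sg$altAA == "*"))
})

test_that("a reference mismatch is an integrity error", {
  pc <- MAP@intervals[MAP@intervals$name == "MT-ND1", ]
  p <- pc$start + 10L
  wrong <- setdiff(c("A", "C", "G", "T"), refBase(REF, p))[1]
  alt <- setdiff(c("A", "C", "G", "T"), c(wrong, refBase(REF, p)))[1]
  calls <- data.frame(pos = p, ref = wrong, alt = alt,
                      stringsAsFactors = FALSE)
  expect_error(annotateConsequence(calls, MAP, REF), "mismatch")
})

test_that("pathogenicity thresholds are strict and unscored stays NA", {
  pc <- MAP@intervals[MAP@intervals$name == "MT-CO1", ]
  pos <- pc$start + c(10L, 20L, 30L)
  refv <- refBase(REF, pos)
  alt <- vapply(refv, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  calls <- data.frame(pos = pos, ref = refv, alt = unname(alt),
                      stringsAsFactors = FALSE)
  ann <- annotateConsequence(calls, MAP, REF)
  mut <- scoreTable(data.frame(pos = pos[1:2], ref = refv[1:2],
                               alt = alt[1:2], score = c(0.60, 0.50)),
                    tool = "MutPred")
  apo <- scoreTable(data.frame(pos = pos[1:2], ref = refv[1:2],
                               alt = alt[1:2], score = c(0.38, 0.39)),
                    tool = "APOGEE2")
  cls <- classifyPathogenicity(ann, mutpred = mut, apogee2 = apo)
  expect_identical(cls$pathogenicMutpred, c(TRUE, FALSE, NA))
  expect_identical(cls$pathogenicApogee2, c(FALSE, TRUE, NA))
  expect_error(scoreTable(data.frame(pos = 1, ref = "A", alt = "G",
                                     score = 1.2)), "\\[0, 1\\]")
})

test_that("overlapping genes report the most severe consequence", {
  # positions in the MT-ATP8/MT-ATP6 overlap are evaluated in both frames
  v <- randomCoding(60, seed = 45)
  ov <- MAP@intervals[MAP@intervals$name %in% c("MT-ATP8", "MT-ATP6"), ]
  pos <- seq(max(ov$start), min(ov$end))
  refv <- refBase(REF, pos)
  alt <- vapply(refv, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  calls <- data.frame(pos = as.integer(pos), ref = refv, alt = unname(alt),
                      stringsAsFactors = FALSE)
  ann <- annotateConsequence(calls, MAP, REF)
  both <- vapply(seq_along(pos), function(i) {
    c8 <- bruteForceConsequence(pos[i], alt[i], "MT-ATP8")
    c6 <- bruteForceConsequence(pos[i], alt[i], "MT-ATP6")
    if (c8 == "non-synonymous" || c6 == "non-synonymous")
      "non-synonymous" else "synonymous"
  }, character(1))
  expect_identical(ann$consequence, both)
})
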