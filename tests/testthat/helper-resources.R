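# shared packaged resources, loaded once per test run
REF <- mtReference()
MAP <- locusMap()
MASKS <- maskSet()
GENOME_LEN <- 16569L

# allele-count table with exact depths and no error, from a variant list
makeCountTable <- function(variants = data.frame(pos = integer(),
                                                 alt = character(),
                                                 hf = numeric()),
                           depth = 2000, sample = "cell", seed = 1,
                           errorRate = 0, isConsensus = FALSE,
                           depthVec = NULL) {
  set.seed(seed)
  generateCounts(variants, depthMean = depth, depthSize = Inf,
                 errorRate = errorRate, reference = REF, sample = sample,
                 isConsensus = isConsensus, depth = depthVec)
}

# deterministic noise-free counts: alt reads = round(hf * depth)
exactCountTable <- function(variants, depth = 2000, sample = "cell",
                            isConsensus = FALSE) {
  refv <- refBase(REF, seq_len(GENOME_LEN))
  counts <- matrix(0L, nrow = GENOME_LEN, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_len(GENOME_LEN), match(refv, colnames(counts)))] <-
    as.integer(depth)
  if (nrow(variants)) {
    altN <- as.integer(round(variants$hf * depth))
    i <- cbind(variants$pos, match(variants$alt, colnames(counts)))
    r <- cbind(variants$pos, match(refv[variants$pos], colnames(counts)))
    counts[i] <- counts[i] + altN
    counts[r] <- counts[r] - altN
  }
  alleleCountTable(counts, sample = sample, isConsensus = isConsensus)
}

# brute-force consequence oracle: rebuild the whole coding sequence, apply
# the substitution, translate both proteins with the Biostrings machinery
# (vertebrate mitochondrial code, table 2) and compare
bruteForceConsequence <- function(pos, alt, geneName) {
  iv <- MAP@intervals
  gene <- iv[iv$name == geneName, ]
  s <- gene$start; e <- gene$end
  chars <- refBase(REF, s:e)
  mutChars <- chars
  mutChars[pos - s + 1L] <- alt
  asProtein <- function(x) {
    if (gene$strand == "light")
      x <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[x]))
    pad <- (3L - length(x) %% 3L) %% 3L
    x <- c(x, rep("A", pad))  # poly-A completion of a partial stop codon
    as.character(Biostrings::translate(
      Biostrings::DNAString(paste(x, collapse = "")),
      genetic.code = Biostrings::getGeneticCode("2"),
      no.init.codon = TRUE))
  }
  if (identical(asProtein(chars), asProtein(mutChars))) "synonymous"
  else "non-synonymous"
}
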