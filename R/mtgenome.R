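#' Load the mitochondrial reference genome
#'
#' Reads a single-record FASTA and validates that it is exactly 16,569 bp.
#' With no arguments, loads the packaged reference. The packaged sequence is
#' a synthetic stand-in with rCRS-like base composition (the genuine
#' NC_012920.1 sequence is not redistributed here); the packaged locus
#' annotation carries the genuine NC_012920.1 feature coordinates. All
#' consequence annotation is computed relative to whichever sequence is
#' loaded, so users with the real rCRS FASTA can supply it directly.
#'
#' @param fasta Path to a FASTA file, or `NULL` for the packaged reference.
#' @param name Sequence identifier to record.
#' @return An [MtReference-class] object.
#' @examples
#' ref <- mtReference()
#' refBase(ref, c(1, 16569))
#' @export
mtReference <- function(fasta = NULL, name = "NC_012920.1") {
  if (is.null(fasta)) {
    fasta <- system.file("extdata", "rCRS_synthetic.fasta",
                         package = "scMitoHet", mustWork = TRUE)
    name <- "NC_012920.1_synthetic"
  }
  set <- Biostrings::readDNAStringSet(fasta)
  if (length(set) != 1L)
    stop("reference FASTA must contain exactly one record")
  new("MtReference", sequence = set[[1L]], name = name)
}

#' Normalize a position onto the circular genome
#'
#' Maps any integer onto 1..16,569 by modular arithmetic, so that position
#' 16,570 is position 1 and position 0 is position 16,569.
#'
#' @param position Integer vector (any integers).
#' @return Integer vector in 1..16,569.
#' @export
wrapPosition <- function(position) {
  as.integer(((as.integer(position) - 1L) %% MT_GENOME_LENGTH) + 1L)
}

.checkPositions <- function(position) {
  position <- as.integer(position)
  if (any(is.na(position)) ||
      any(position < 1L | position > MT_GENOME_LENGTH))
    stop("position out of range: coordinates are 1-based in [1, 16569]")
  position
}

#' Reference base at given positions
#'
#' @param reference An [MtReference-class].
#' @param position Integer vector of 1-based positions.
#' @return Character vector of bases.
#' @export
refBase <- function(reference, position) {
  position <- .checkPositions(position)
  strsplit(as.character(reference@sequence), "")[[1L]][position]
}

.expandInterval <- function(start, end) {
  if (end >= start) start:end else c(start:MT_GENOME_LENGTH, 1L:end)
}

#' Build the circular locus map
#'
#' Constructs a [LocusMap-class] from an interval table (default: the
#' packaged NC_012920.1 annotation). Intervals are 1-based inclusive; the
#' D-loop wraps the origin (m.16024-576). For burden assignment every
#' position resolves to at most one locus class, with overlaps broken by
#' first-in-genome-order precedence (e.g. the MT-ATP8/MT-ATP6 overlap counts
#' as MT-ATP8); positions in no feature are `"intergenic"`.
#'
#' Normalization lengths are fixed constants (D-loop 1124, rRNA 2511, tRNA
#' 1486, protein-coding 11,382), not recomputed from the interval table; see
#' [computedLocusLengths()] for the arithmetic lengths.
#'
#' @param intervals `data.frame` with columns `name`, `start`, `end`,
#'   `strand`, `class`, or a path to such a TSV, or `NULL` for the packaged
#'   annotation.
#' @return A [LocusMap-class].
#' @examples
#' map <- locusMap()
#' locusOf(c(100, 16100, 3400), map)
#' @export
locusMap <- function(intervals = NULL) {
  if (is.null(intervals))
    intervals <- system.file("extdata", "rCRS_loci.tsv",
                             package = "scMitoHet", mustWork = TRUE)
  if (is.character(intervals))
    intervals <- read.table(intervals, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  classByPos <- rep("intergenic", MT_GENOME_LENGTH)
  nameByPos <- rep("intergenic", MT_GENOME_LENGTH)
  unset <- rep(TRUE, MT_GENOME_LENGTH)
  for (i in seq_len(nrow(intervals))) {
    p <- .expandInterval(intervals$start[i], intervals$end[i])
    take <- p[unset[p]]
    classByPos[take] <- intervals$class[i]
    nameByPos[take] <- intervals$name[i]
    unset[take] <- FALSE
  }
  new("LocusMap", intervals = intervals,
      normLengths = MT_NORMALIZATION_LENGTHS,
      classByPos = classByPos, nameByPos = nameByPos)
}

#' Locus class and name of genomic positions
#'
#' Resolves positions to their burden-assignment locus class and feature
#' name. D-loop positions on both sides of the circular origin resolve to
#' the D-loop.
#'
#' @param position Integer vector of 1-based positions in 1..16,569.
#' @param map A [LocusMap-class].
#' @return `data.frame` with columns `pos`, `class`, `name`.
#' @export
locusOf <- function(position, map) {
  position <- .checkPositions(position)
  data.frame(pos = position, class = map@classByPos[position],
             name = map@nameByPos[position], stringsAsFactors = FALSE)
}

#' Arithmetic locus-class lengths of a map
#'
#' Sums interval lengths per locus class, both raw (overlaps counted twice)
#' and deduplicated by the burden precedence rule. These differ by a few bp
#' from the fixed normalization constants carried in the map; normalization
#' always uses the constants.
#'
#' @param map A [LocusMap-class].
#' @return `data.frame` with columns `class`, `summed`, `deduplicated`,
#'   `normalization`.
#' @export
computedLocusLengths <- function(map) {
  iv <- map@intervals
  len <- ifelse(iv$end >= iv$start, iv$end - iv$start + 1L,
                MT_GENOME_LENGTH - iv$start + 1L + iv$end)
  summed <- tapply(len, iv$class, sum)
  dedup <- table(factor(map@classByPos, levels = LOCUS_CLASSES))
  cls <- LOCUS_CLASSES
  data.frame(class = cls, summed = as.integer(summed[cls]),
             deduplicated = as.integer(dedup[cls]),
             normalization = as.numeric(map@normLengths[cls]),
             stringsAsFactors = FALSE)
}

# Placeholder positions of the rCRS; masked under every configuration.
MT_PLACEHOLDER_MASK <- c(3106L, 3107L)

#' Build a mask set of low-complexity regions
#'
#' Default regions: m.66-71, m.300-316, m.513-525, m.3106-3107,
#' m.12418-12425 and m.16181-16194 (1-based, inclusive). The region printed
#' elsewhere as "12,418-21,425" exceeds the 16,569 bp genome; the packaged
#' default reads it as 12,418-12,425, the only physically possible
#' correction. Custom regions may be supplied, but the rCRS placeholder
#' positions 3,106-3,107 are always masked.
#'
#' @param regions `data.frame` with columns `start`, `end`, or a path to
#'   such a TSV, or `NULL` for the packaged default.
#' @return A [MaskSet-class].
#' @examples
#' masks <- maskSet()
#' inMask(c(66, 310, 1000), masks)
#' @export
maskSet <- function(regions = NULL) {
  if (is.null(regions))
    regions <- system.file("extdata", "default_masks.tsv",
                           package = "scMitoHet", mustWork = TRUE)
  if (is.character(regions))
    regions <- read.table(regions, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  start <- c(as.integer(regions$start), MT_PLACEHOLDER_MASK[1L])
  end <- c(as.integer(regions$end), MT_PLACEHOLDER_MASK[2L])
  if (any(end < start)) stop("mask regions must have end >= start")
  rng <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  new("MaskSet", ranges = rng)
}

#' Test mask membership
#'
#' @param position Integer vector of 1-based positions in 1..16,569.
#' @param masks A [MaskSet-class].
#' @return Logical vector: `TRUE` where the position lies in any mask
#'   interval (inclusive ends).
#' @export
inMask <- function(position, masks) {
  position <- .checkPositions(position)
  IRanges::overlapsAny(IRanges::IRanges(position, position), masks@ranges)
}

#' Masked positions as an integer vector
#' @param masks A [MaskSet-class].
#' @return Sorted integer vector of all masked positions.
#' @export
maskedPositions <- function(masks) {
  sort(unique(unlist(lapply(seq_along(masks@ranges), function(i)
    IRanges::start(masks@ranges)[i]:IRanges::end(masks@ranges)[i]))))
}

.geneInterval <- function(gene, map) {
  if (is.character(gene)) {
    i <- which(map@intervals$name == gene)
    if (length(i) != 1L) stop("unknown gene: ", gene)
    map@intervals[i, ]
  } else gene
}

#' Codon context of a position within a protein-coding gene
#'
#' Returns, for a position inside a protein-coding gene, the codon index
#' (1-based from the gene's frame anchor, i.e. its first coding position),
#' the offset within the codon (0-2) and the reference codon read 5'->3' on
#' the coding strand. For light-strand genes (MT-ND6) the codon is the
#' reverse complement of the reference triplet. Genes whose length is not a
#' multiple of three end in an incomplete stop codon completed by
#' polyadenylation; their trailing codon is padded with `A` and flagged.
#'
#' @param position A single 1-based position inside the gene.
#' @param gene A gene name or a one-row interval `data.frame`
#'   (from the map's intervals).
#' @param map A [LocusMap-class] (used when `gene` is a name).
#' @param reference An [MtReference-class].
#' @return List with `codonIndex`, `offset`, `codon`, `strand`,
#'   `incompleteStop`.
#' @export
codonContext <- function(position, gene, map, reference) {
  position <- .checkPositions(position)
  stopifnot(length(position) == 1L)
  gene <- .geneInterval(gene, map)
  if (gene$class != "protein-coding")
    stop("codon context is defined only for protein-coding genes")
  s <- gene$start; e <- gene$end
  if (position < s || position > e)
    stop("position ", position, " outside gene ", gene$name)
  # coding-strand offset j (0-based) from the frame anchor
  j <- if (gene$strand == "heavy") position - s else e - position
  codonIndex <- j %/% 3L + 1L
  offset <- j %% 3L
  n <- e - s + 1L
  cs <- (codonIndex - 1L) * 3L          # coding-strand start of codon
  codonPos <- cs + 0:2                  # may extend past gene end (partial)
  incomplete <- any(codonPos > n - 1L)
  genomic <- if (gene$strand == "heavy") s + codonPos else e - codonPos
  inside <- genomic >= s & genomic <= e
  bases <- rep("A", 3L)                 # poly-A completion of partial codons
  raw <- refBase(reference, genomic[inside])
  # genomic positions are already in coding (5'->3') order for both
  # strands, so the light strand needs complementation only
  if (gene$strand == "light") raw <- unname(.COMPLEMENT[raw])
  bases[inside] <- raw
  list(codonIndex = codonIndex, offset = offset,
       codon = paste(bases, collapse = ""), strand = gene$strand,
       incompleteStop = incomplete)
}
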