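#' Read and write allele-count tables
#'
#' The TSV schema is `pos`, `ref`, `A`, `C`, `G`, `T`, `depth`, one row per
#' covered position (uncovered positions may be omitted and are
#' zero-filled). `ref` is checked against the supplied reference when given.
#'
#' @param file Path to a TSV.
#' @param sample Sample identifier; defaults to the file name.
#' @param isConsensus Consensus flag.
#' @param reference Optional [MtReference-class] for `ref`-column
#'   validation.
#' @return An [AlleleCountTable-class].
#' @export
readAlleleCounts <- function(file, sample = NULL, isConsensus = FALSE,
                             reference = NULL) {
  tab <- read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("pos", "A", "C", "G", "T", "depth")
  if (!all(need %in% names(tab)))
    stop("count TSV needs columns: pos, ref, A, C, G, T, depth")
  pos <- .checkPositions(tab$pos)
  if (anyDuplicated(pos)) stop("duplicated positions in count table")
  if (!is.null(reference) && "ref" %in% names(tab)) {
    mismatch <- tab$ref != refBase(reference, pos)
    if (any(mismatch))
      stop("ref column disagrees with the reference sequence at ",
           sum(mismatch), " positions")
  }
  counts <- matrix(0L, nrow = MT_GENOME_LENGTH, ncol = 4L,
                   dimnames = list(NULL, MT_BASES))
  for (b in MT_BASES) counts[pos, b] <- as.integer(tab[[b]])
  if (!identical(as.integer(rowSums(counts)[pos]), as.integer(tab$depth)))
    stop("base counts do not sum to depth")
  if (is.null(sample)) sample <- sub("\\.tsv$", "", basename(file))
  alleleCountTable(counts, sample = sample, isConsensus = isConsensus)
}

#' @rdname readAlleleCounts
#' @param x An [AlleleCountTable-class].
#' @param reference An [MtReference-class] supplying the `ref` column.
#' @export
writeAlleleCounts <- function(x, file, reference) {
  stopifnot(is(x, "AlleleCountTable"))
  tab <- data.frame(pos = seq_len(MT_GENOME_LENGTH),
                    ref = refBase(reference, seq_len(MT_GENOME_LENGTH)),
                    x@counts, depth = x@depth, stringsAsFactors = FALSE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write calls as a single-sample VCF
#'
#' Minimal VCFv4.2 with per-call `GT:DP:AD:AF` genotype fields (AD as
#' ref,alt depths; AF the heteroplasmic fraction). One record per
#' (position, alt).
#'
#' @param calls Call `data.frame` from [callVariants()].
#' @param file Output path.
#' @param sample Sample column name.
#' @param contig Contig name written in the header and records.
#' @return The file path, invisibly.
#' @export
writeVariantVcf <- function(calls, file, sample = "sample",
                            contig = "chrM") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, MT_GENOME_LENGTH),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    paste0("##FORMAT=<ID=AF,Number=A,Type=Float,",
           "Description=\"Heteroplasmic fraction alt/(alt+ref)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t"))
  gt <- ifelse(calls$zygosity == "homoplasmic", "1", "0/1")
  body <- if (nrow(calls))
    paste(contig, calls$pos, ".", calls$ref, calls$alt, ".", "PASS", ".",
          "GT:DP:AD:AF",
          paste0(gt, ":", calls$depth, ":", calls$refDepth, ",",
                 calls$altDepth, ":", formatC(calls$hf, format = "g",
                                              digits = 6)),
          sep = "\t")
  else character(0)
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read calls from a single-sample VCF with allele depths
#'
#' Parses substitution records carrying `AD` (and optionally `DP`) genotype
#' fields via the VariantAnnotation package and recomputes HF as
#' alt/(alt+ref) from the allele depths.
#'
#' @param file Path to a VCF.
#' @param minLevel Analysis floor used to re-derive zygosity.
#' @param minSiteDepth Low-confidence site depth threshold.
#' @return A call `data.frame` in [callVariants()] layout.
#' @export
readVariantVcf <- function(file, minLevel = 0.02, minSiteDepth = 100L) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readVariantVcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(file)
  snv <- VariantAnnotation::isSNV(vcf)
  vcf <- vcf[snv]
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no AD genotype field")
  refD <- vapply(ad[, 1L], function(x) as.integer(x[1L]), integer(1L))
  altD <- vapply(ad[, 1L], function(x) as.integer(x[2L]), integer(1L))
  rr <- SummarizedExperiment::rowRanges(vcf)
  depth <- {
    dp <- VariantAnnotation::geno(vcf)$DP
    if (is.null(dp)) refD + altD else as.integer(dp[, 1L])
  }
  hf <- computeHF(altD, refD)
  calls <- data.frame(
    pos = as.integer(IRanges::start(rr)),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a[[1L]]), character(1L)),
    altDepth = altD, refDepth = refD, depth = depth, hf = hf,
    zygosity = classifyZygosity(hf, lower = minLevel),
    pError = NA_real_, lowConfidence = depth < minSiteDepth,
    stringsAsFactors = FALSE)
  calls[order(calls$pos, calls$alt), , drop = FALSE]
}

#' Write a simulated sample to disk
#'
#' Writes per-cell count TSVs, the consensus TSV and a truth TSV into a
#' directory; identical seeds yield byte-identical files.
#'
#' @param sim Output of [simulateSample()].
#' @param dir Output directory (created if needed).
#' @param reference The [MtReference-class] used for the simulation.
#' @return Invisibly, the vector of written paths.
#' @export
writeSimSample <- function(sim, dir, reference = mtReference()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cn in names(sim$cells)) {
    p <- file.path(dir, paste0(cn, ".counts.tsv"))
    writeAlleleCounts(sim$cells[[cn]], p, reference)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "consensus.counts.tsv")
  writeAlleleCounts(sim$consensus, p, reference)
  t <- file.path(dir, "truth.tsv")
  write.table(sim$truth, t, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p, t))
}
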