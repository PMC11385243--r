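# Vertebrate mitochondrial genetic code (translation table 2), hard-coded.
# Differences from the standard code: AGA/AGG are stops, ATA is Met,
# TGA is Trp.
MT_GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "*", AGG = "*",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Translate codons under the vertebrate mitochondrial code
#'
#' Translation table 2: AGA and AGG are stop codons, ATA encodes methionine
#' and TGA encodes tryptophan. Codons containing characters other than
#' A/C/G/T (or shorter than 3 bases) translate to `NA`.
#'
#' @param codons Character vector of DNA codons (e.g. `"ATA"`).
#' @return Character vector of one-letter amino acids (`"*"` for stop).
#' @examples
#' translateCodons(c("AGA", "ATA", "TGA", "ATG"))
#' @export
translateCodons <- function(codons) {
  unname(MT_GENETIC_CODE[toupper(codons)])
}
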