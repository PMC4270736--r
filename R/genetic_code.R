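#' Standard genetic code
#'
#' Named character vector mapping the 64 DNA codons to one-letter amino-acid
#' codes, with `"*"` for the three stop codons. Used by the site classifier,
#' the KA/KS counter and the Fop calculator.
#'
#' @format Named character vector of length 64.
#' @export
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Translate a DNA codon
#'
#' @param codon Character vector of three-letter codons (uppercase DNA).
#' @return One-letter amino-acid codes; `"*"` for stops, `NA` for codons
#'   containing masked or non-ACGT characters.
#' @export
translate_codon <- function(codon) {
  aa <- unname(GENETIC_CODE_STD[codon])
  aa
}

# The four unambiguous nucleotide states; everything else is MASKED ("N").
NUCS <- c("A", "C", "G", "T")
MASKED <- "N"
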