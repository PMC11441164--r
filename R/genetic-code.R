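# Standard genetic code, written out by hand so codon-effect classification
# does not depend on a sequence package at run time.
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

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_STD[codon]
  ifelse(is.na(aa), "X", aa)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Codons containing `N` or `-` translate to `X`.
#'
#' @param seq a single DNA string whose length is a multiple of 3.
#' @return a single amino-acid string (`*` marks stop codons).
#' @export
translate_cds <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) abort("sequence length is not a multiple of 3.")
  codons <- substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
  paste(translate_codon(codons), collapse = "")
}
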