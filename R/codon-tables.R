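#' Codon state space used by the phylogenetic models
#'
#' All 64 codons in lexicographic order over the DNA alphabet (TTT, TTC, ...).
#' The coding model restricts itself to the 61 sense codons; the noncoding
#' model keeps all 64.
#'
#' @return Character vector of length 64.
#' @keywords internal
all_codons <- function() {
  nt <- c("T", "C", "A", "G")
  as.vector(outer(nt, outer(nt, nt, paste0), function(a, b) paste0(a, b)))
}

# names(x) = codons, value = one-letter amino acid, "*" for stops
codon_translation_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  tab <- as.character(gc)
  names(tab) <- chartr("U", "T", names(gc))
  tab
}

sense_codons <- function() {
  tab <- codon_translation_table()
  names(tab)[tab != "*"]
}

#' Translate a DNA sequence codon-by-codon
#'
#' Standard genetic code; codons containing gaps, `N` or other ambiguity
#' codes translate to `X`. A trailing partial codon is dropped.
#'
#' @param dna A single DNA string.
#' @return One-letter amino-acid string, with `*` for stop codons.
#' @examples
#' translate_dna("ATGGCTTGA")
#' @export
translate_dna <- function(dna) {
  codons <- split_codons(toupper(dna))
  tab <- codon_translation_table()
  aa <- tab[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
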