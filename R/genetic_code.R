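# Standard genetic code (translation table 1) and codon indexing shared by
# the simulators, the six-frame translator and the dN/dS machinery.

NT <- c("A", "C", "G", "T")

#' The 64 codons in lexicographic A<C<G<T order
#' @return character vector of 64 codons.
#' @export
all_codons <- function() {
  as.vector(t(outer(
    as.vector(t(outer(NT, NT, paste0))), NT, paste0
  )))
}

genetic_code_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Translate a codon vector to amino acids
#'
#' Stops are returned as `*`; codons containing characters outside
#' A/C/G/T (for example `N`) translate to `X`.
#'
#' @param codons character vector of 3-letter codons.
#' @return character vector of single-letter amino acids.
#' @export
translate_codons <- function(codons) {
  gc <- genetic_code_table()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

SENSE_CODONS <- NULL  # filled at load time

sense_codons <- function() {
  gc <- genetic_code_table()
  names(gc)[gc != "*"]
}

stop_codons <- function() c("TAA", "TAG", "TGA")

is_transition <- function(a, b) {
  pur <- c("A", "G")
  (a %in% pur) == (b %in% pur) & a != b
}
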