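# Affine-gap local protein alignment used by the translated search.
#
# Scoring follows the BLAST convention for "open 11 / extend 1": a gap of
# length L costs open + L * extend, which is also the Biostrings
# convention, so the dynamic programming itself is delegated to
# Biostrings::pairwiseAlignment.

#' Default Karlin-Altschul parameters for gapped BLOSUM62 (11/1)
#' @return list with lambda, K, gap_open, gap_extend, matrix name.
#' @export
default_scoring <- function() {
  list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
       lambda = 0.267, K = 0.041)
}

#' Score a local alignment of two peptides
#'
#' @param a,b peptide strings (may contain `*` and `X`).
#' @param scoring list as from [default_scoring()].
#' @return the optimal affine-gap local alignment score (numeric).
#' @export
local_align_score <- function(a, b, scoring = default_scoring()) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    scoreOnly = TRUE)
}

# Full local alignment; returns the PairwiseAlignments object.
local_align <- function(a, b, scoring = default_scoring()) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
}

# Karlin-Altschul bit score and e-value.
bit_score <- function(raw, scoring = default_scoring()) {
  (scoring$lambda * raw - log(scoring$K)) / log(2)
}

karlin_evalue <- function(raw, m, n, scoring = default_scoring()) {
  m * n * 2^(-bit_score(raw, scoring))
}
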