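# Six-frame translation supporting the translated homology search.

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1, +2, +3 read the sequence as given, -1, -2, -3 read the
#' reverse complement.  The standard genetic code is used, stop codons
#' become `*`, codons containing `N` become `X`, and a trailing partial
#' codon is dropped.
#'
#' @param nt nucleotide string (A/C/G/T/N).
#' @return named character vector of six peptides
#'   (`"+1" "+2" "+3" "-1" "-2" "-3"`); frames shorter than one codon are
#'   empty strings.
#' @export
sixframe_translate <- function(nt) {
  nt <- toupper(nt)
  if (nchar(nt) < 3L) stop2("sequence shorter than one codon")
  if (!is_nt_string(nt)) stop2("non-nucleotide characters in sequence")
  rc <- revcomp(nt)
  frame1 <- function(s, off) {
    sub <- substring(s, off, nchar(s))
    paste(translate_codons(codon_split(sub)), collapse = "")
  }
  out <- c(
    "+1" = frame1(nt, 1L), "+2" = frame1(nt, 2L), "+3" = frame1(nt, 3L),
    "-1" = frame1(rc, 1L), "-2" = frame1(rc, 2L), "-3" = frame1(rc, 3L))
  out
}

# Map an amino-acid interval [aa_start, aa_end] in a given frame back to
# 1-based inclusive nucleotide coordinates on the forward strand of the
# original sequence of length nt_len.
frame_aa_to_nt <- function(frame, aa_start, aa_end, nt_len) {
  off <- abs(frame)  # 1, 2 or 3
  s <- (aa_start - 1L) * 3L + off
  e <- aa_end * 3L + off - 1L
  if (frame > 0) c(s, e) else c(nt_len - e + 1L, nt_len - s + 1L)
}
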