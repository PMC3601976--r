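#' @keywords internal
"_PACKAGE"

#' @importFrom stats rmultinom runif rbinom setNames quantile sd var
#' @importFrom utils head tail read.delim write.table
NULL

stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from a single integer seed; each
#' module draws from its own named substream so that changing one stage
#' never perturbs another.  The substream seed is a polynomial hash of
#' the stream name folded into the master seed, reduced modulo a Mersenne
#' prime so it stays inside R's 32-bit integer range.
#'
#' @param seed integer master seed.
#' @param stream character scalar naming the substream.
#' @return an integer usable with [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stream))
  p <- 2147483647  # 2^31 - 1
  h <- as.double(seed %% p)
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% p
  as.integer(h)
}

with_stream_seed <- function(seed, stream, expr) {
  if (!is.null(seed)) set.seed(substream_seed(seed, stream))
  expr
}

#' Reverse-complement a nucleotide string
#'
#' @param x character vector of nucleotide strings (A/C/G/T/N, any case).
#' @return character vector of reverse complements, uppercased.
#' @export
revcomp <- function(x) {
  up <- toupper(x)
  flipped <- chartr("ACGTN", "TGCAN", up)
  vapply(strsplit(flipped, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# split a nucleotide string into codon triplets (drops trailing partial codon)
codon_split <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

is_nt_string <- function(x) grepl("^[ACGTN]+$", x)

# stable check that a numeric matrix is symmetric within tolerance
check_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
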