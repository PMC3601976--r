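# BLAST tabular (outfmt 6) hit tables.
#
# Columns, in the fixed 12-column ordering:
#   qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#   evalue bitscore
# Query coordinates are 1-based inclusive on the nucleotide contig.

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a BLAST outfmt-6 hit table
#'
#' Rows are preserved in file order.  Extra trailing columns are ignored
#' with a warning; rows with fewer than 12 columns or unparseable numeric
#' fields are an error naming the line.
#'
#' @param path tab-separated file; may be empty (returns a 0-row table).
#' @return data.frame with the 12 outfmt-6 columns, typed.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- empty_hit_table()
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 12L)) {
    stop2("malformed hit table row (fewer than 12 columns) at line ",
          which(ncols < 12L)[1])
  }
  if (any(ncols > 12L)) {
    warning("ignoring extra columns beyond the 12 outfmt-6 fields")
  }
  m <- t(vapply(parts, function(p) p[1:12], character(12)))
  num <- function(j, int = FALSE) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) stop2("non-numeric value in column ", OUTFMT6_COLS[j],
                        " at line ", which(is.na(v))[1])
    if (int) as.integer(v) else v
  }
  out <- data.frame(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = num(3), length = num(4, TRUE), mismatch = num(5, TRUE),
    gapopen = num(6, TRUE), qstart = num(7, TRUE), qend = num(8, TRUE),
    sstart = num(9, TRUE), send = num(10, TRUE),
    evalue = num(11), bitscore = num(12),
    stringsAsFactors = FALSE)
  if (any(out$qstart > out$qend)) {
    stop2("qstart > qend at line ", which(out$qstart > out$qend)[1])
  }
  if (any(out$pident < 0 | out$pident > 100)) stop2("pident outside [0, 100]")
  out
}

empty_hit_table <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a hit table in outfmt-6
#' @param hits data.frame as returned by [read_hit_table()] or
#'   [translated_search()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  m <- hits[, OUTFMT6_COLS, drop = FALSE]
  m$evalue <- formatC(m$evalue, format = "g", digits = 3)
  m$pident <- formatC(m$pident, format = "f", digits = 2)
  m$bitscore <- formatC(m$bitscore, format = "f", digits = 1)
  write.table(m, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
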