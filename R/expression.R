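# Stage-wise expression quantification: naive exact/near-exact read
# counting and RPKM normalization.

#' Count reads per gene by naive full-length matching
#'
#' A read counts for a gene when it matches some position of the gene
#' (either strand) with at most `max_mismatch` mismatches.  Reads
#' matching several genes are assigned to the gene with the fewest
#' mismatches; ties are discarded and reported as ambiguous.
#'
#' @param reads sequence-record data.frame of reads (nt).
#' @param gene_seqs named character vector of gene sequences.
#' @param max_mismatch tolerated mismatches per read (default 0).
#' @return list with `counts` (named integer vector per gene),
#'   `n_ambiguous`, `n_unmapped`.
#' @export
naive_map_counts <- function(reads, gene_seqs, max_mismatch = 0L) {
  if (length(gene_seqs) == 0L) stop2("empty gene set")
  genes_fwd <- Biostrings::DNAStringSet(gene_seqs)
  counts <- setNames(integer(length(gene_seqs)), names(gene_seqs))
  n_amb <- 0L; n_un <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- reads$residues[i]
    best_mm <- NA_integer_; best_gene <- NA_integer_; tie <- FALSE
    for (g in seq_along(gene_seqs)) {
      mm <- min_mismatch_hit(r, genes_fwd[[g]], max_mismatch)
      if (is.na(mm)) next
      if (is.na(best_mm) || mm < best_mm) {
        best_mm <- mm; best_gene <- g; tie <- FALSE
      } else if (mm == best_mm) tie <- TRUE
    }
    if (is.na(best_mm)) n_un <- n_un + 1L
    else if (tie) n_amb <- n_amb + 1L
    else counts[best_gene] <- counts[best_gene] + 1L
  }
  list(counts = counts, n_ambiguous = n_amb, n_unmapped = n_un)
}

# smallest mismatch count (<= max_mm) at which read matches gene on
# either strand, NA when none
min_mismatch_hit <- function(read, gene, max_mm) {
  pats <- c(read, revcomp(read))
  for (mm in 0:max_mm) {
    for (p in pats) {
      n <- Biostrings::countPattern(Biostrings::DNAString(p), gene,
                                    max.mismatch = mm)
      if (n > 0) return(mm)
    }
  }
  NA_integer_
}

#' RPKM table from counts, gene lengths and library sizes
#'
#' `rpkm = count / (length/1000) / (library_size/1e6)`; the library
#' size is the total number of mapped reads in each library.
#'
#' @param counts gene x stage matrix (or named vector for one stage).
#' @param gene_lengths named vector of gene lengths (nt), all positive.
#' @param library_sizes per-stage mapped-read totals, all positive.
#' @return object of class `expression_table`: list with `counts`,
#'   `rpkm`, `gene_lengths`, `library_sizes`.
#' @export
rpkm_table <- function(counts, gene_lengths, library_sizes) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1,
                                          dimnames = list(names(counts), NULL))
  if (any(gene_lengths <= 0)) stop2("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop2("library sizes must be positive")
  stopifnot(nrow(counts) == length(gene_lengths),
            ncol(counts) == length(library_sizes))
  rpkm <- 1e9 * sweep(sweep(counts, 1, gene_lengths, "/"),
                      2, library_sizes, "/")
  structure(list(counts = counts, rpkm = rpkm,
                 gene_lengths = gene_lengths,
                 library_sizes = library_sizes),
            class = "expression_table")
}

#' Per-gene stage summary of an expression table
#'
#' @param et an `expression_table`.
#' @return data.frame per gene: min_stage, max_stage (ties broken by
#'   stage order), max_min_fold (Inf flag when the minimum is zero) and
#'   log10 values for plotting.
#' @export
stage_summary <- function(et) {
  r <- et$rpkm
  if (ncol(r) < 2L) stop2("need at least two stages")
  stages <- colnames(r) %||% paste0("stage", seq_len(ncol(r)))
  rows <- lapply(seq_len(nrow(r)), function(g) {
    v <- r[g, ]
    i_min <- which.min(v); i_max <- which.max(v)
    fold <- if (v[i_min] == 0) Inf else v[i_max] / v[i_min]
    data.frame(gene = rownames(r)[g] %||% paste0("gene", g),
               min_stage = stages[i_min], max_stage = stages[i_max],
               min_rpkm = v[i_min], max_rpkm = v[i_max],
               max_min_fold = fold, infinite_fold = v[i_min] == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "log10_rpkm") <- log10(r + 1e-3)
  out
}
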