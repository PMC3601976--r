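# Gene-structure validation: ORF finding, single-intron inference from
# genomic/CDS comparison, splice-site motifs, cross-species intron
# conservation and protein identity/similarity.
#
# Coordinates are 0-based half-open internally; GFF3 output is 1-based
# inclusive.

#' Gene structure (exons + one intron) on a genomic sequence
#'
#' @param exons 2-column matrix of 0-based half-open exon intervals.
#' @param intron length-2 vector, 0-based half-open intron interval.
#' @param phase intron phase (0/1/2): position of the intron within the
#'   codon reading frame.
#' @param donor,acceptor the first/last two intron nucleotides.
#' @param gene_id optional identifier.
#' @return object of class `gene_structure`.
#' @export
gene_structure <- function(exons, intron, phase, donor, acceptor,
                           gene_id = NA_character_) {
  stopifnot(ncol(exons) == 2L, all(exons[, 2] >= exons[, 1]),
            length(intron) == 2L, intron[2] > intron[1],
            phase %in% 0:2)
  if (nrow(exons) >= 2L && any(exons[-1L, 1] < exons[-nrow(exons), 2])) {
    stop2("exon intervals overlap or are unordered")
  }
  structure(list(gene_id = gene_id, exons = unname(exons),
                 intron = unname(intron), phase = phase,
                 donor = donor, acceptor = acceptor),
            class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat(sprintf("gene structure%s: intron [%d, %d) phase %d, %s..%s\n",
              if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
              x$intron[1], x$intron[2], x$phase, x$donor, x$acceptor))
  invisible(x)
}

#' Find the longest ATG-initiated open reading frame
#'
#' Searches all six frames; an ORF runs from an ATG to the next stop
#' codon (included) or, if none, to the frame end.  Ties are broken by
#' the earlier start, then by forward strand / lower frame.
#'
#' @param nt nucleotide sequence.
#' @param min_codons minimum ORF length in codons (start and any stop
#'   included).
#' @return list with `cds` (nt string, stop included when present),
#'   `frame` (+1..+3, -1..-3), `aa_start` (1-based codon offset in the
#'   frame), `nt_start`, `nt_end` (1-based inclusive on the forward
#'   strand).
#' @export
find_orf <- function(nt, min_codons = 30L) {
  nt <- toupper(nt)
  if (nchar(nt) < 6L) stop2("sequence too short")
  peps <- sixframe_translate(nt)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  best <- NULL
  for (i in seq_along(frames)) {
    pep <- peps[i]
    if (!nzchar(pep)) next
    starts <- gregexpr("M", pep, fixed = TRUE)[[1]]
    if (starts[1] == -1L) next
    stops <- c(gregexpr("*", pep, fixed = TRUE)[[1]])
    for (s in starts) {
      stop_after <- stops[stops >= s]
      e <- if (length(stop_after) && stop_after[1] != -1L) stop_after[1]
           else nchar(pep)
      len <- e - s + 1L
      if (is.null(best) || len > best$len) {
        best <- list(len = len, frame = frames[i], aa_start = s, aa_end = e)
      }
    }
  }
  if (is.null(best) || best$len < min_codons) {
    stop2("no open reading frame of at least ", min_codons, " codons")
  }
  coords <- frame_aa_to_nt(best$frame, best$aa_start, best$aa_end, nchar(nt))
  strand_seq <- if (best$frame > 0) nt else revcomp(nt)
  off <- abs(best$frame)
  cds <- substring(strand_seq, (best$aa_start - 1L) * 3L + off,
                   best$aa_end * 3L + off - 1L)
  list(cds = cds, frame = best$frame, aa_start = best$aa_start,
       nt_start = coords[1], nt_end = coords[2])
}

#' Infer a single intron by comparing genomic and CDS sequences
#'
#' Finds the decomposition genomic = prefix + intron + suffix with
#' prefix + suffix = cds (allowing up to `max_mismatch` exonic
#' mismatches).  Among multiple solutions, one whose intron starts with
#' `GT` and ends with `AG` is preferred, then the longest prefix.
#'
#' @param genomic genomic sequence containing exactly one intron.
#' @param cds the spliced coding sequence.
#' @param max_mismatch tolerated exonic mismatches (default 0).
#' @param gene_id stored in the result.
#' @return a [gene_structure()].
#' @export
infer_intron <- function(genomic, cds, max_mismatch = 0L,
                         gene_id = NA_character_) {
  genomic <- toupper(genomic); cds <- toupper(cds)
  gl <- nchar(genomic); cl <- nchar(cds)
  il <- gl - cl
  if (il < 4L) stop2("structure not single-intron: genomic must exceed ",
                     "cds by at least 4 nt")
  g <- chars(genomic); cc <- chars(cds)
  # mismatches of cds prefix of length p against genomic start
  pref_mm <- cumsum(g[seq_len(cl)] != cc)
  # mismatches of cds suffix of length s against genomic end
  suf_mm <- rev(cumsum(rev(g[(gl - cl + 1L):gl] != cc)))
  sols <- integer(0)
  for (p in 0:cl) {
    mm <- (if (p > 0) pref_mm[p] else 0L) +
      (if (p < cl) suf_mm[p + 1L] else 0L)
    if (mm <= max_mismatch) sols <- c(sols, p)
  }
  if (length(sols) == 0L) stop2("structure not single-intron: cds not ",
                                "derivable from genomic")
  intron_of <- function(p) substring(genomic, p + 1L, p + il)
  canonical <- vapply(sols, function(p) {
    i <- intron_of(p)
    startsWith(i, "GT") && endsWith(i, "AG")
  }, TRUE)
  pool <- if (any(canonical)) sols[canonical] else sols
  p <- max(pool)
  intr <- intron_of(p)
  gene_structure(
    exons = rbind(c(0L, p), c(p + il, gl)),
    intron = c(p, p + il), phase = p %% 3L,
    donor = substring(intr, 1, 2), acceptor = substring(intr, il - 1L, il),
    gene_id = gene_id)
}

#' Splice-site motif flags of an inferred structure
#'
#' @param structure a [gene_structure()].
#' @param genomic the genomic sequence it was inferred on.
#' @return list with donor_canonical (`GT`), acceptor_canonical (`AG`).
#' @export
check_splice_sites <- function(structure, genomic) {
  genomic <- toupper(genomic)
  i <- structure$intron
  intr <- substring(genomic, i[1] + 1L, i[2])
  list(donor_canonical = startsWith(intr, "GT"),
       acceptor_canonical = endsWith(intr, "AG"))
}

#' Cross-species intron position conservation
#'
#' @param structure_a,structure_b [gene_structure()] objects.
#' @param genomic_a,genomic_b the corresponding genomic sequences.
#' @param cds_alignment named character vector of aligned CDSs (gaps
#'   `-`) containing entries named `id_a` and `id_b`.
#' @param id_a,id_b alignment names of the two CDSs.
#' @return list with `same_start` (intron insertion points map to the
#'   same alignment column with equal phase) and `shared_prefix_len`
#'   (identical run from the introns' 5' ends).
#' @export
intron_conservation <- function(structure_a, genomic_a,
                                structure_b, genomic_b,
                                cds_alignment, id_a, id_b) {
  for (id in c(id_a, id_b)) {
    if (!id %in% names(cds_alignment)) stop2("CDS absent from alignment: ", id)
  }
  col_of <- function(aln_seq, cds_pos) {
    # alignment column holding the cds_pos-th non-gap character
    res <- which(cumsum(chars(aln_seq) != "-") == cds_pos)[1]
    if (is.na(res)) stop2("intron insertion point beyond aligned CDS")
    res
  }
  pa <- structure_a$intron[1]; pb <- structure_b$intron[1]
  same <- col_of(cds_alignment[[id_a]], pa) ==
    col_of(cds_alignment[[id_b]], pb) &&
    structure_a$phase == structure_b$phase
  ia <- substring(toupper(genomic_a), pa + 1L, structure_a$intron[2])
  ib <- substring(toupper(genomic_b), pb + 1L, structure_b$intron[2])
  n <- min(nchar(ia), nchar(ib))
  ca <- chars(ia)[seq_len(n)]; cb <- chars(ib)[seq_len(n)]
  diff <- which(ca != cb)
  list(same_start = same,
       shared_prefix_len = if (length(diff)) diff[1] - 1L else n)
}

#' Percent identity and similarity of an aligned protein pair
#'
#' Computed over ungapped columns only; similarity adds pairs with a
#' positive substitution-matrix score (conservative substitutions).
#'
#' @param a,b equal-length aligned amino-acid strings (gaps `-`).
#' @param matrix substitution matrix name (default "BLOSUM62").
#' @return list with percent_identity, percent_similarity, n_ungapped.
#' @export
alignment_identity_similarity <- function(a, b, matrix = "BLOSUM62") {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop2("aligned sequences differ in length")
  ca <- chars(a); cb <- chars(b)
  use <- ca != "-" & cb != "-"
  if (!any(use)) stop2("no ungapped columns")
  mat <- get_substitution_matrix(matrix)
  ident <- ca[use] == cb[use]
  pos <- mat[cbind(ca[use], cb[use])] > 0
  list(percent_identity = 100 * mean(ident),
       percent_similarity = 100 * mean(ident | pos),
       n_ungapped = sum(use))
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Write gene structures as GFF3
#'
#' @param structures list of [gene_structure()] objects.
#' @param seqids genomic sequence names (recycled).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(structures, seqids, path) {
  seqids <- rep_len(seqids, length(structures))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(structures)) {
    st <- structures[[i]]
    gid <- if (is.na(st$gene_id)) paste0("gene", i) else st$gene_id
    for (k in seq_len(nrow(st$exons))) {
      writeLines(sprintf("%s\thgtrace\texon\t%d\t%d\t.\t+\t.\tParent=%s",
                         seqids[i], st$exons[k, 1] + 1L, st$exons[k, 2],
                         gid), con)
    }
    writeLines(sprintf("%s\thgtrace\tintron\t%d\t%d\t.\t+\t%d\tParent=%s",
                       seqids[i], st$intron[1] + 1L, st$intron[2],
                       st$phase, gid), con)
  }
  invisible(path)
}
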