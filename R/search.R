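# Translated (six-frame x six-frame) homology search over small sequence
# databases.  This is a deterministic seed-and-extend engine: frame pairs
# sharing at least one exact length-k amino-acid word are aligned with
# affine-gap local dynamic programming and scored with Karlin-Altschul
# statistics.  With seed_k = 0 every frame pair is aligned exhaustively.

frame_table <- function(records, min_len = 1L) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    peps <- sixframe_translate(records$residues[i])
    data.frame(id = records$id[i], frame = c(1L, 2L, 3L, -1L, -2L, -3L),
               peptide = unname(peps), stringsAsFactors = FALSE)
  })
  ft <- do.call(rbind, rows)
  ft[nchar(ft$peptide) >= min_len, , drop = FALSE]
}

kmer_set <- function(pep, k) {
  n <- nchar(pep)
  if (n < k) return(character(0))
  unique(substring(pep, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Translated homology search of nucleotide queries against a nucleotide database
#'
#' Every query x subject pair is scored by the best affine-gap local
#' alignment over its translated frame pairs; bit scores follow the
#' Karlin-Altschul formula `(lambda * S - ln K) / ln 2` and e-values are
#' `m * n * 2^(-bitscore)` with `m` the query frame length and `n` the
#' total database length, both in amino acids.  Hits above the e-value
#' cutoff are dropped; results are sorted by bit score (desc), e-value
#' (asc), then subject id.
#'
#' @param queries,subjects nucleotide sequence-record data.frames.
#' @param taxon_map optional [taxon_group_map()]; when supplied (and the
#'   subjects carry species labels) the result gains subject_species and
#'   subject_group columns.
#' @param evalue_cutoff drop hits with larger e-value (default 1e-10).
#' @param max_targets keep at most this many hits per query.
#' @param seed_k word length of the exact-match prefilter; 0 disables the
#'   prefilter and aligns all 36 frame pairs per sequence pair.
#' @param seed_min minimum number of shared words for a frame pair to be
#'   aligned (ignored when `seed_k = 0`).
#' @param scoring list as from [default_scoring()].
#' @return data.frame in outfmt-6 column order plus frame,
#'   subject_species and subject_group.
#' @export
translated_search <- function(queries, subjects, taxon_map = NULL,
                              evalue_cutoff = 1e-10, max_targets = Inf,
                              seed_k = 5L, seed_min = 2L,
                              scoring = default_scoring()) {
  hits <- empty_search_result()
  if (nrow(subjects) == 0L || nrow(queries) == 0L) return(hits)
  qf <- frame_table(queries)
  sf <- frame_table(subjects)
  n_db <- sum(nchar(subjects$residues) %/% 3L)

  # candidate (query frame row, subject frame row) pairs
  if (seed_k > 0L) {
    sf_kmers <- lapply(sf$peptide, kmer_set, k = seed_k)
    idx <- list2env(split(rep(seq_len(nrow(sf)), lengths(sf_kmers)),
                          unlist(sf_kmers)), hash = TRUE)
    cand <- lapply(seq_len(nrow(qf)), function(i) {
      km <- kmer_set(qf$peptide[i], seed_k)
      if (length(km) == 0L) return(integer(0))
      shared <- table(unlist(mget(km, envir = idx,
                                  ifnotfound = list(integer(0)))))
      sort(as.integer(names(shared))[shared >= seed_min])
    })
  } else {
    cand <- rep(list(seq_len(nrow(sf))), nrow(qf))
  }
  pairs <- data.frame(
    q = rep(seq_len(nrow(qf)), lengths(cand)),
    s = unlist(cand))
  if (nrow(pairs) == 0L) return(hits)

  # score candidate frame pairs, one batched call per query frame
  # (local alignment scores are symmetric, so subject frames go in as
  # the pattern set)
  align_batch <- function(qi, sjs, score_only) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(sf$peptide[sjs]),
      Biostrings::AAString(qf$peptide[qi]), type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      scoreOnly = score_only)
  }
  pairs$score <- NA_real_
  for (qi in unique(pairs$q)) {
    rows <- which(pairs$q == qi)
    pairs$score[rows] <- align_batch(qi, pairs$s[rows], TRUE)
  }
  pairs <- pairs[pairs$score > 0, , drop = FALSE]
  if (nrow(pairs) == 0L) return(hits)

  # best frame pair per (query id, subject id), deterministic tie-break
  pairs$qid <- qf$id[pairs$q]
  pairs$sid <- sf$id[pairs$s]
  frame_rank <- function(f) match(f, c(1L, 2L, 3L, -1L, -2L, -3L))
  ord <- order(pairs$qid, pairs$sid, -pairs$score,
               frame_rank(qf$frame[pairs$q]), frame_rank(sf$frame[pairs$s]))
  pairs <- pairs[ord, , drop = FALSE]
  best <- pairs[!duplicated(paste(pairs$qid, pairs$sid, sep = "\r")), ,
                drop = FALSE]

  # e-value cutoff before the (full) alignment pass
  best$m <- nchar(qf$peptide[best$q])
  best$evalue <- karlin_evalue(best$score, best$m, n_db, scoring)
  best <- best[best$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(best) == 0L) return(hits)

  qlen <- setNames(nchar(queries$residues), queries$id)
  slen <- setNames(nchar(subjects$residues), subjects$id)
  out <- vector("list", length(unique(best$q)))
  for (b in seq_along(unique(best$q))) {
    qi <- unique(best$q)[b]
    rows <- which(best$q == qi)
    pa <- align_batch(qi, best$s[rows], FALSE)
    ins <- Biostrings::nindel(pa)
    # pattern = subject frame, subject = query frame (symmetric score)
    saa_s <- Biostrings::start(Biostrings::pattern(pa))
    saa_e <- Biostrings::end(Biostrings::pattern(pa))
    qaa_s <- Biostrings::start(Biostrings::subject(pa))
    qaa_e <- Biostrings::end(Biostrings::subject(pa))
    qnt <- t(vapply(seq_along(rows), function(r) frame_aa_to_nt(
      qf$frame[qi], qaa_s[r], qaa_e[r], qlen[[best$qid[rows[r]]]]),
      c(0, 0)))
    snt <- t(vapply(seq_along(rows), function(r) frame_aa_to_nt(
      sf$frame[best$s[rows[r]]], saa_s[r], saa_e[r],
      slen[[best$sid[rows[r]]]]), c(0, 0)))
    out[[b]] <- data.frame(
      qseqid = best$qid[rows], sseqid = best$sid[rows],
      pident = Biostrings::pid(pa),
      length = nchar(as.character(Biostrings::pattern(pa))),
      mismatch = Biostrings::nmismatch(pa),
      gapopen = Biostrings::insertion(ins)[, "Length"] +
        Biostrings::deletion(ins)[, "Length"],
      qstart = qnt[, 1], qend = qnt[, 2],
      sstart = snt[, 1], send = snt[, 2],
      evalue = best$evalue[rows],
      bitscore = bit_score(Biostrings::score(pa), scoring),
      frame = qf$frame[qi], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$bitscore, res$evalue, res$sseqid), , drop = FALSE]
  if (is.finite(max_targets)) {
    res <- do.call(rbind, lapply(split(res, res$qseqid), head, n = max_targets))
  }
  if (!is.null(taxon_map)) {
    sp <- setNames(subjects$species, subjects$id)
    res$subject_species <- unname(sp[res$sseqid])
    res$subject_group <- group_of_species(res$subject_species, taxon_map)
  }
  rownames(res) <- NULL
  res
}

empty_search_result <- function() {
  cbind(empty_hit_table(),
        data.frame(frame = integer(), stringsAsFactors = FALSE))
}
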