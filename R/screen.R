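# The four-stage taxon-aware HGT candidate screening cascade.
#
# Stage 1: the top translated-search hit must come from a donor-candidate
#          (host-lineage) species.
# Stage 2: the contig must be longer than 500 nt, the top donor hit's
#          identity must lie in [60, 95] % and its query span must cover
#          at least half of the contig (guards against chimeric contigs
#          with one short near-identical stretch).
# Stage 3: no close-relative species may appear among the 10 best hits.
# Stage 4: considering all hits, either no close-relative hit exists at
#          all, or the best donor bit score must exceed the best
#          close-relative bit score by a configurable ratio (a contig
#          "rescued" this way is flagged in the report).
#
# The reported funnel mirrors published practice by combining stages 1+2
# into a single "initial screening" count.

#' Default thresholds for the screening cascade
#'
#' @param min_contig_len contigs must be strictly longer than this (nt).
#' @param identity_range inclusive percent-identity bounds on the top
#'   donor hit.
#' @param min_aligned_frac minimum fraction of the contig covered by the
#'   top donor hit's query span.
#' @param top_n_close_check number of best hits inspected in stage 3.
#' @param stage4_bit_ratio minimum best-donor / best-close-relative bit
#'   score ratio for a stage-4 rescue.
#' @param evalue_cutoff e-value cutoff applied by the search.
#' @return named list of thresholds.
#' @export
screen_thresholds <- function(min_contig_len = 500L,
                              identity_range = c(60, 95),
                              min_aligned_frac = 0.5,
                              top_n_close_check = 10L,
                              stage4_bit_ratio = 1.2,
                              evalue_cutoff = 1e-10) {
  stopifnot(min_contig_len >= 0, length(identity_range) == 2L,
            identity_range[1] <= identity_range[2],
            min_aligned_frac >= 0, min_aligned_frac <= 1,
            top_n_close_check >= 1L, stage4_bit_ratio > 0)
  list(min_contig_len = min_contig_len, identity_range = identity_range,
       min_aligned_frac = min_aligned_frac,
       top_n_close_check = top_n_close_check,
       stage4_bit_ratio = stage4_bit_ratio, evalue_cutoff = evalue_cutoff)
}

#' Apply the four-stage screening cascade to a hit table
#'
#' @param hits hit data.frame (outfmt-6 columns); must either carry a
#'   subject_species column (as produced by [translated_search()]) or be
#'   resolvable through `subject_species`.
#' @param contig_lengths named integer vector, one entry per screened
#'   contig (contigs without hits are still reported and fail stage 1).
#' @param taxon_map [taxon_group_map()] resolving every subject species.
#' @param thresholds list from [screen_thresholds()].
#' @param subject_species optional named vector mapping subject ids to
#'   species, for imported hit tables.
#' @return an object of class `screen_report`: list with `per_contig`
#'   (per-contig stage flags and failure reasons), `funnel` (input,
#'   after_initial, after_stage3, candidates) and `candidates`.
#' @export
apply_screen_cascade <- function(hits, contig_lengths, taxon_map,
                                 thresholds = screen_thresholds(),
                                 subject_species = NULL) {
  if (is.null(names(contig_lengths)) || anyDuplicated(names(contig_lengths))) {
    stop2("contig_lengths must be uniquely named")
  }
  if (nrow(hits) > 0 && is.null(hits$subject_species)) {
    if (is.null(subject_species)) {
      stop2("hits lack subject_species; supply subject_species")
    }
    sp <- subject_species[hits$sseqid]
    if (anyNA(sp)) stop2("subject id(s) missing from subject_species map: ",
                         paste(unique(hits$sseqid[is.na(sp)]), collapse = ", "))
    hits$subject_species <- unname(sp)
  }
  if (nrow(hits) > 0) {
    hits$subject_group <- group_of_species(hits$subject_species, taxon_map)
    unknown_contig <- setdiff(unique(hits$qseqid), names(contig_lengths))
    if (length(unknown_contig)) {
      stop2("hits reference contigs absent from contig_lengths: ",
            paste(unknown_contig, collapse = ", "))
    }
    hits <- hits[order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid), ,
                 drop = FALSE]
  }
  th <- thresholds
  ids <- names(contig_lengths)
  hit_split <- if (nrow(hits) > 0) split(hits, hits$qseqid) else list()

  eval_one <- function(id) {
    len <- contig_lengths[[id]]
    h <- hit_split[[id]]
    res <- list(stage1 = FALSE, stage2 = FALSE, stage3 = FALSE,
                stage4 = FALSE, rescued = FALSE, reason = "")
    if (is.null(h) || nrow(h) == 0L) {
      res$reason <- "no hits"
      return(res)
    }
    res$stage1 <- h$subject_group[1] == "donor_candidate"
    if (!res$stage1) res$reason <- paste0("top hit is ", h$subject_group[1])

    donor <- h[h$subject_group == "donor_candidate", , drop = FALSE]
    if (nrow(donor) > 0) {
      top <- donor[1, ]
      span <- top$qend - top$qstart + 1L
      ok_len <- len > th$min_contig_len
      ok_id <- top$pident >= th$identity_range[1] &&
        top$pident <= th$identity_range[2]
      ok_span <- span >= th$min_aligned_frac * len
      res$stage2 <- ok_len && ok_id && ok_span
      if (res$stage1 && !res$stage2) {
        res$reason <- paste0(
          if (!ok_len) "contig too short; " else "",
          if (!ok_id) sprintf("identity %.1f outside [%g, %g]; ",
                              top$pident, th$identity_range[1],
                              th$identity_range[2]) else "",
          if (!ok_span) "aligned span < half of contig; " else "")
      }
    } else {
      res$reason <- if (res$stage1) "no donor hit" else res$reason
    }

    top_n <- head(h, th$top_n_close_check)
    res$stage3 <- !any(top_n$subject_group == "close_relative")
    if (res$stage1 && res$stage2 && !res$stage3) {
      res$reason <- "close relative among top hits"
    }

    close_all <- h[h$subject_group == "close_relative", , drop = FALSE]
    if (nrow(close_all) == 0L) {
      res$stage4 <- TRUE
    } else if (nrow(donor) > 0) {
      ratio <- max(donor$bitscore) / max(close_all$bitscore)
      res$stage4 <- ratio >= th$stage4_bit_ratio
      res$rescued <- res$stage4
      if (res$stage1 && res$stage2 && res$stage3 && !res$stage4) {
        res$reason <- sprintf("donor/close bit ratio %.2f < %.2f",
                              ratio, th$stage4_bit_ratio)
      }
    }
    res
  }

  rows <- lapply(ids, eval_one)
  per_contig <- data.frame(
    contig = ids,
    length = as.integer(contig_lengths),
    stage1 = vapply(rows, `[[`, TRUE, "stage1"),
    stage2 = vapply(rows, `[[`, TRUE, "stage2"),
    stage3 = vapply(rows, `[[`, TRUE, "stage3"),
    stage4 = vapply(rows, `[[`, TRUE, "stage4"),
    rescued = vapply(rows, `[[`, TRUE, "rescued"),
    reason = vapply(rows, `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  per_contig$candidate <- per_contig$stage1 & per_contig$stage2 &
    per_contig$stage3 & per_contig$stage4
  funnel <- c(
    input = nrow(per_contig),
    after_initial = sum(per_contig$stage1 & per_contig$stage2),
    after_stage3 = sum(per_contig$stage1 & per_contig$stage2 &
                         per_contig$stage3),
    candidates = sum(per_contig$candidate))
  structure(list(per_contig = per_contig, funnel = funnel,
                 candidates = per_contig$contig[per_contig$candidate]),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("HGT screening cascade\n")
  cat(sprintf("  contigs in:        %d\n", x$funnel[["input"]]))
  cat(sprintf("  initial screen:    %d\n", x$funnel[["after_initial"]]))
  cat(sprintf("  close-rel. veto:   %d\n", x$funnel[["after_stage3"]]))
  cat(sprintf("  final candidates:  %d\n", x$funnel[["candidates"]]))
  if (length(x$candidates)) {
    cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the screening stage end to end
#'
#' Composes [translated_search()] (or an imported hit table) with
#' [apply_screen_cascade()].
#'
#' @param contigs parasite contig records (nt).
#' @param reference_db reference records (nt) with species labels.
#' @param taxon_map [taxon_group_map()].
#' @param thresholds list from [screen_thresholds()].
#' @param hits optional pre-computed hit table; when `NULL` the internal
#'   search engine is used.
#' @param seed_k see [translated_search()].
#' @return list with `report` (a `screen_report`) and `hits`.
#' @export
run_screen <- function(contigs, reference_db, taxon_map,
                       thresholds = screen_thresholds(), hits = NULL,
                       seed_k = 5L) {
  if (is.null(hits)) {
    hits <- translated_search(contigs, reference_db, taxon_map,
                              evalue_cutoff = thresholds$evalue_cutoff,
                              seed_k = seed_k)
  }
  lens <- setNames(nchar(contigs$residues), contigs$id)
  sp <- setNames(reference_db$species, reference_db$id)
  report <- apply_screen_cascade(hits, lens, taxon_map, thresholds,
                                 subject_species = sp)
  list(report = report, hits = hits)
}

#' Write a screen report to TSV files
#' @param report a `screen_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$per_contig, file.path(dir, "screen_per_contig.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  funnel <- data.frame(stage = names(report$funnel),
                       contigs = as.integer(report$funnel))
  write.table(funnel, file.path(dir, "screen_funnel.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
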