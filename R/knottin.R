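# Rule-based cysteine-scaffold (KNOTTIN-style) scoring.
#
# Albumin-1 KNOTTINs carry six conserved cysteines forming three
# disulfide bonds; the scaffold is characterized by the number of
# cysteines and the lengths of the five inter-cysteine loops.  The
# scorer is an original rule-based statistic: loop-length windows are
# derived from a packaged (synthetic) albumin-1-like alignment and each
# satisfied feature contributes a weighted subscore.  The numeric scale
# of external KNOTTIN predictors is not reproduced.

#' Cysteine-scaffold profile from a packaged or user alignment
#'
#' Loop windows are the observed min/max inter-cysteine loop lengths in
#' the profile sequences, widened by `margin`.
#'
#' @param fasta FASTA of profile proteins (all must share the same
#'   cysteine count); defaults to the packaged synthetic
#'   albumin-1-like set.
#' @param margin widening of the observed loop-length ranges.
#' @param weights subscore weights: count, loop (each), cterm.
#' @param threshold pass threshold on the total score.
#' @return profile list used by [cysteine_scaffold_score()].
#' @export
scaffold_profile <- function(fasta = system.file("extdata",
                                                 "albumin1_knottin_synthetic.fasta",
                                                 package = "hgtrace"),
                             margin = 2L,
                             weights = list(count = 10, loop = 3, cterm = 2),
                             threshold = 27) {
  recs <- read_fasta(fasta)
  pos <- lapply(recs$residues, function(p) which(chars(p) == "C"))
  n_cys <- unique(lengths(pos))
  if (length(n_cys) != 1L) stop2("profile sequences differ in cysteine count")
  loops <- do.call(rbind, lapply(pos, function(p) diff(p) - 1L))
  windows <- cbind(lo = pmax(0L, apply(loops, 2, min) - margin),
                   hi = apply(loops, 2, max) + margin)
  cterm_has_cys <- any(vapply(recs$residues, function(p) {
    any(chars(p)[nchar(p) - 0:1] == "C")
  }, TRUE))
  list(n_cys = n_cys, loop_windows = windows,
       cterm_cys_allowed = cterm_has_cys,
       weights = weights, threshold = threshold)
}

#' Score a protein against the cysteine-scaffold profile
#'
#' Subscores: exact cysteine count; each inter-cysteine loop length
#' inside its profiled window (only evaluated when the count matches);
#' no cysteine in the two C-terminal residues (unless the profile has
#' one).  The protein passes when the total reaches the profile
#' threshold.
#'
#' @param protein amino-acid string (at least 30 residues).
#' @param profile list from [scaffold_profile()].
#' @return object of class `scaffold_score`: list with cys_count,
#'   cys_positions, loop_lengths, subscores, total, pass.
#' @export
cysteine_scaffold_score <- function(protein, profile = scaffold_profile()) {
  protein <- toupper(protein)
  if (nchar(protein) < 30L) stop2("protein shorter than 30 aa")
  p <- chars(protein)
  pos <- which(p == "C")
  w <- profile$weights
  sub <- c(count = 0, loops = 0, cterm = 0)
  loops <- integer(0)
  if (length(pos) == profile$n_cys) {
    sub["count"] <- w$count
    loops <- diff(pos) - 1L
    ok <- loops >= profile$loop_windows[, "lo"] &
      loops <= profile$loop_windows[, "hi"]
    sub["loops"] <- w$loop * sum(ok)
  }
  if (profile$cterm_cys_allowed || !any(p[length(p) - 0:1] == "C")) {
    sub["cterm"] <- w$cterm
  }
  total <- sum(sub)
  structure(list(cys_count = length(pos), cys_positions = pos,
                 loop_lengths = loops, subscores = sub, total = total,
                 pass = total >= profile$threshold,
                 threshold = profile$threshold),
            class = "scaffold_score")
}

#' @export
print.scaffold_score <- function(x, ...) {
  cat(sprintf("scaffold score %.1f (threshold %.1f): %s\n", x$total,
              x$threshold, if (x$pass) "PASS" else "fail"))
  cat(sprintf("  %d cysteines; loops: %s\n", x$cys_count,
              paste(x$loop_lengths, collapse = ", ")))
  invisible(x)
}
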