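# Pairwise distances and neighbor joining.

#' Pairwise nucleotide distance matrix (JC69 or K2P)
#'
#' Columns where either sequence has a gap (`-`) or `N` are excluded
#' pairwise.  The Jukes-Cantor distance is
#' `d = -(3/4) ln(1 - 4p/3)` with `p` the mismatch proportion; pairs
#' with `p >= 3/4` are returned as `NA` and flagged in the `saturated`
#' attribute.
#'
#' @param alignment named character vector of equal-length aligned
#'   nucleotide sequences.
#' @param model "JC" or "K2P".
#' @return symmetric distance matrix with a logical `saturated`
#'   attribute of the same shape.
#' @export
distance_matrix <- function(alignment, model = c("JC", "K2P")) {
  model <- match.arg(model)
  n <- length(alignment)
  if (n < 2L) stop2("need at least two sequences")
  if (length(unique(nchar(alignment))) != 1L) {
    stop2("sequences are not aligned (unequal lengths)")
  }
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  D <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(D))
  pur <- m %in% c("A", "G"); dim(pur) <- dim(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- ok[i, ] & ok[j, ]
    L <- sum(use)
    if (L == 0L) stop2("no overlapping columns for pair ",
                       names(alignment)[i], " / ", names(alignment)[j])
    diff <- m[i, use] != m[j, use]
    if (model == "JC") {
      p <- sum(diff) / L
      if (p >= 0.75) { D[i, j] <- D[j, i] <- NA; sat[i, j] <- sat[j, i] <- TRUE }
      else D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
    } else {
      ts <- diff & (pur[i, use] == pur[j, use])
      P <- sum(ts) / L; Qp <- sum(diff & !ts) / L
      a <- 1 - 2 * P - Qp; b <- 1 - 2 * Qp
      if (a <= 0 || b <= 0) { D[i, j] <- D[j, i] <- NA; sat[i, j] <- sat[j, i] <- TRUE }
      else D[i, j] <- D[j, i] <- -0.5 * log(a) - 0.25 * log(b)
    }
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ via [ape::nj()]; negative branch-length estimates are
#' clamped to zero.
#'
#' @param D symmetric distance matrix with no `NA`/`NaN` entries.
#' @return unrooted [ape::phylo].
#' @export
nj_tree <- function(D) {
  if (anyNA(D)) stop2("distance matrix contains NA/NaN (saturated pairs?)")
  if (!check_symmetric(D)) stop2("distance matrix must be square and symmetric")
  if (nrow(D) < 3L) stop2("need at least 3 taxa")
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
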