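# Nei-Gojobori (1986) codon-site counting and pairwise dN/dS.
#
# Conventions (fixed): mutations to stop codons are excluded from the
# per-position site denominators; codons differing at several positions
# are averaged over all minimal mutational pathways that avoid stop
# codons; distances use the Jukes-Cantor correction
# d = -(3/4) ln(1 - 4p/3).

.ng86_cache <- new.env(parent = emptyenv())

#' Synonymous and nonsynonymous site counts of one codon
#'
#' For each of the three positions the fraction of the (non-stop)
#' single-nucleotide mutations that are synonymous is accumulated into
#' `S`; `N = 3 - S`.
#'
#' @param codon a sense codon over A/C/G/T.
#' @return named numeric vector `c(S = ..., N = ...)`.
#' @export
codon_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop2("ambiguous or invalid codon: ", codon)
  if (codon %in% stop_codons()) stop2("stop codon has no site counts: ", codon)
  aa <- translate_codons(codon)
  b <- chars(codon)
  S <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(NT, b[pos]), function(nt) {
      x <- b; x[pos] <- nt; paste(x, collapse = "")
    }, "")
    aas <- translate_codons(muts)
    keep <- aas != "*"
    if (any(keep)) S <- S + sum(aas[keep] == aa) / sum(keep)
  }
  c(S = S, N = 3 - S)
}

# pathway-averaged (Sd, Nd) for one ordered codon pair; NA when every
# minimal pathway passes through a stop codon
codon_pair_changes <- function(a, b) {
  pa <- chars(a); pb <- chars(b)
  diff_pos <- which(pa != pb)
  k <- length(diff_pos)
  if (k == 0L) return(c(Sd = 0, Nd = 0))
  orders <- if (k == 1L) list(diff_pos) else
    lapply(asplit(permutations(k), 1), function(p) diff_pos[p])
  acc <- c(Sd = 0, Nd = 0); n_valid <- 0L
  for (ord in orders) {
    cur <- pa; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- pb[pos]
      c_cur <- paste(cur, collapse = ""); c_nxt <- paste(nxt, collapse = "")
      if (translate_codons(c_nxt) == "*" && c_nxt != b) { ok <- FALSE; break }
      if (translate_codons(c_cur) == translate_codons(c_nxt)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + c(Sd = sd, Nd = nd); n_valid <- n_valid + 1L }
  }
  if (n_valid == 0L) return(c(Sd = NA_real_, Nd = NA_real_))
  acc / n_valid
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub)))
  }))
}

ng86_tables <- function() {
  if (!is.null(.ng86_cache$tables)) return(.ng86_cache$tables)
  sense <- sense_codons()
  sites <- t(vapply(sense, codon_site_counts, c(S = 0, N = 0)))
  n <- length(sense)
  Sd <- matrix(0, n, n, dimnames = list(sense, sense))
  Nd <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ch <- codon_pair_changes(sense[i], sense[j])
    Sd[i, j] <- ch[["Sd"]]; Nd[i, j] <- ch[["Nd"]]
  }
  .ng86_cache$tables <- list(sense = sense, sites = sites, Sd = Sd, Nd = Nd)
  .ng86_cache$tables
}

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Nei-Gojobori dN/dS between two coding sequences
#'
#' @param cds_a,cds_b equal-length coding sequences; codon pairs
#'   containing gaps, ambiguity codes or stop codons are skipped, as are
#'   the (rare) pairs whose every minimal pathway crosses a stop.
#' @param scope label stored in the result.
#' @return object of class `codon_change_summary`: list with Nd, Sd,
#'   N_sites, S_sites, pN, pS, dN, dS, omega (NA when dS is 0 or
#'   saturated), saturated flags and the number of codons used.
#' @export
ng86_pairwise <- function(cds_a, cds_b, scope = "pair") {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop2("sequences differ in length")
  if (nchar(cds_a) %% 3L != 0L) stop2("length not divisible by 3")
  ca <- codon_split(cds_a); cb <- codon_split(cds_b)
  tab <- ng86_tables()
  ia <- match(ca, tab$sense); ib <- match(cb, tab$sense)
  usable <- !is.na(ia) & !is.na(ib)
  ia <- ia[usable]; ib <- ib[usable]
  pairSd <- tab$Sd[cbind(ia, ib)]
  pairNd <- tab$Nd[cbind(ia, ib)]
  path_ok <- !is.na(pairSd)
  if (any(!path_ok)) {
    warning(sum(!path_ok), " codon pair(s) skipped: all pathways cross stops")
  }
  ia <- ia[path_ok]; ib <- ib[path_ok]
  Sd <- sum(pairSd[path_ok]); Nd <- sum(pairNd[path_ok])
  S_sites <- (sum(tab$sites[ia, "S"]) + sum(tab$sites[ib, "S"])) / 2
  N_sites <- (sum(tab$sites[ia, "N"]) + sum(tab$sites[ib, "N"])) / 2
  summarize_counts(Nd, Sd, N_sites, S_sites, scope = scope,
                   n_codons = length(ia))
}

summarize_counts <- function(Nd, Sd, N_sites, S_sites, scope, n_codons = NA) {
  pN <- if (N_sites > 0) Nd / N_sites else NA_real_
  pS <- if (S_sites > 0) Sd / S_sites else NA_real_
  dN <- jc_correct(pN); dS <- jc_correct(pS)
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  structure(list(scope = scope, Nd = Nd, Sd = Sd,
                 N_sites = N_sites, S_sites = S_sites,
                 pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
                 saturated = c(N = !is.na(pN) && pN >= 0.75,
                               S = !is.na(pS) && pS >= 0.75),
                 n_codons = n_codons),
            class = "codon_change_summary")
}

#' @export
print.codon_change_summary <- function(x, ...) {
  cat(sprintf("codon changes [%s]: Nd=%.2f Sd=%.2f N=%.1f S=%.1f\n",
              x$scope, x$Nd, x$Sd, x$N_sites, x$S_sites))
  cat(sprintf("  dN=%s dS=%s omega=%s\n",
              format(x$dN, digits = 4), format(x$dS, digits = 4),
              if (is.na(x$omega)) "undefined" else format(x$omega, digits = 4)))
  invisible(x)
}
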