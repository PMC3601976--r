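# Sequence evolution along trees: an HKY nucleotide generator and an
# MG94-style codon generator (instantaneous rate zero for
# multi-nucleotide codon changes, proportional to
# pi_target * kappa^[transition] * omega^[nonsynonymous]).
# Branch transitions use exact transition-probability matrices obtained
# by spectral decomposition of the (reversible) rate matrix.

# spectral decomposition of a reversible Q with stationary pi;
# returns function(t) -> transition matrix P(t)
decompose_q <- function(Q, pi) {
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  A <- diag(1 / d) %*% e$vectors
  B <- t(e$vectors) %*% diag(d)
  vals <- e$values
  function(t) {
    P <- A %*% (exp(vals * t) * B)
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

#' HKY rate matrix, normalized to one substitution per site per unit time
#' @param kappa transition/transversion rate ratio.
#' @param pi base frequencies (A, C, G, T).
#' @return 4x4 rate matrix with rownames A, C, G, T.
#' @export
hky_q <- function(kappa, pi) {
  stopifnot(length(pi) == 4L, abs(sum(pi) - 1) < 1e-8)
  Q <- matrix(0, 4, 4, dimnames = list(NT, NT))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    Q[i, j] <- pi[j] * if (is_transition(NT[i], NT[j])) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# sample child states from parent states given a transition matrix
sample_states <- function(parent, P) {
  child <- integer(length(parent))
  for (s in unique(parent)) {
    idx <- which(parent == s)
    child[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                             prob = P[s, ])
  }
  child
}

# generic preorder simulation over an ape tree; root_states integer,
# pfun(t) gives the transition matrix for an edge of length t (already
# scaled to expected substitutions)
simulate_along_tree <- function(tree, root_states, pfun) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  states <- vector("list", n_tip + tree$Nnode)
  states[[root]] <- root_states
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # preorder: ape edges are not guaranteed preorder, so walk explicitly
  pending <- which(tree$edge[, 1] == root)
  while (length(pending)) {
    e <- pending[1]; pending <- pending[-1]
    par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
    states[[chl]] <- sample_states(states[[par]], pfun(tree$edge.length[e]))
    pending <- c(pending, which(tree$edge[, 1] == chl))
  }
  stats::setNames(states[seq_len(n_tip)], tree$tip.label)
}

#' Evolve a nucleotide sequence along a tree under HKY
#'
#' @param tree [ape::phylo] with branch lengths (time units).
#' @param root_seq root nucleotide string over A/C/G/T.
#' @param rate substitutions/site per unit branch length.
#' @param kappa,pi HKY parameters.
#' @param seed integer seed (substream "evolve_nt"); `NULL` uses the
#'   current RNG state.
#' @return named character vector of gapless leaf sequences.
#' @export
evolve_nt <- function(tree, root_seq, rate, kappa = 2,
                      pi = c(A = .25, C = .25, G = .25, T = .25),
                      seed = NULL) {
  if (nchar(root_seq) == 0L) stop2("root sequence is empty")
  if (!is_nt_string(root_seq) || grepl("N", root_seq)) {
    stop2("root sequence must be over A/C/G/T")
  }
  with_stream_seed(seed, "evolve_nt", {
    pfun0 <- decompose_q(hky_q(kappa, pi), pi)
    pfun <- function(t) pfun0(t * rate)
    root <- match(chars(root_seq), NT)
    leaves <- simulate_along_tree(tree, root, pfun)
    vapply(leaves, function(s) paste(NT[s], collapse = ""), "")
  })
}

# ---- codon model ----------------------------------------------------------

codon_state_space <- function(exclude_aa = NULL) {
  cods <- sense_codons()
  aa <- translate_codons(cods)
  if (!is.null(exclude_aa) && !is.na(exclude_aa)) {
    keep <- !(aa %in% chars(exclude_aa))
    cods <- cods[keep]; aa <- aa[keep]
  }
  list(codons = cods, aa = aa,
       mat = do.call(rbind, strsplit(cods, "")))
}

#' MG94-style codon rate matrix for one omega class
#'
#' Normalized so the expected number of nucleotide substitutions per
#' codon per unit time is 1.
#'
#' @param kappa transition/transversion ratio.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param pi nucleotide frequencies; codon frequencies are their product
#'   (F1x4), renormalized over the retained sense codons.
#' @param exclude_aa optional string of amino acids removed from the
#'   state space (a hard structural constraint: those residues can never
#'   arise).
#' @return list with `Q`, `pi_codon`, `codons`.
#' @export
mg94_q <- function(kappa, omega, pi, exclude_aa = NULL) {
  sp <- codon_state_space(exclude_aa)
  n <- length(sp$codons)
  pi_codon <- apply(sp$mat, 1, function(r) prod(pi[r]))
  pi_codon <- pi_codon / sum(pi_codon)
  Q <- matrix(0, n, n, dimnames = list(sp$codons, sp$codons))
  for (i in seq_len(n)) {
    diffs <- sp$mat != rep(sp$mat[i, ], each = n)
    nd <- rowSums(diffs)
    for (j in which(nd == 1L)) {
      pos <- which(diffs[j, ])
      a <- sp$mat[i, pos]; b <- sp$mat[j, pos]
      r <- pi[b] * (if (is_transition(a, b)) kappa else 1)
      if (sp$aa[i] != sp$aa[j]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi_codon * diag(Q))
  list(Q = Q / mu, pi_codon = pi_codon, codons = sp$codons)
}

#' Evolve a coding sequence along a tree under an MG94-style model
#'
#' Sites are assigned to omega classes i.i.d. by proportion (or by an
#' explicit `site_classes` vector); the per-site class is returned as
#' the planted truth.  Branch lengths are interpreted as time and
#' multiplied by `3 * rate` to give expected substitutions per codon
#' under neutrality.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param root_cds root coding sequence (length divisible by 3, no
#'   internal stops).
#' @param kappa transition/transversion ratio.
#' @param omega_classes data.frame with columns omega, prop and
#'   optionally exclude_aa (amino acids structurally forbidden for
#'   sites of that class, e.g. "C" outside a cysteine scaffold).
#' @param pi nucleotide frequencies.
#' @param rate substitutions/site per unit branch length.
#' @param site_classes optional integer vector (one entry per codon)
#'   indexing rows of `omega_classes`; overrides random assignment.
#' @param seed integer seed (substream "evolve_codon").
#' @return list with `leaves` (named character vector of leaf CDS),
#'   `site_classes` (integer vector), `omega_classes`.
#' @export
evolve_codon <- function(tree, root_cds, kappa = 2,
                         omega_classes = data.frame(omega = 0.2, prop = 1),
                         pi = c(A = .25, C = .25, G = .25, T = .25),
                         rate = 1, site_classes = NULL, seed = NULL) {
  if (nchar(root_cds) %% 3L != 0L) stop2("root CDS length not divisible by 3")
  cods <- codon_split(root_cds)
  if (any(cods %in% stop_codons())) stop2("internal stop codon in root CDS")
  if (abs(sum(omega_classes$prop) - 1) > 1e-8) {
    stop2("omega class proportions must sum to 1")
  }
  if (!grepl("^[ACGT]+$", root_cds)) stop2("root CDS contains non-ACGT characters")
  with_stream_seed(seed, "evolve_codon", {
    n_codon <- length(cods)
    if (is.null(site_classes)) {
      site_classes <- sample.int(nrow(omega_classes), n_codon, replace = TRUE,
                                 prob = omega_classes$prop)
    }
    stopifnot(length(site_classes) == n_codon)
    excl <- omega_classes$exclude_aa %||% rep(NA_character_, nrow(omega_classes))
    leaves_codons <- matrix(NA_character_, length(tree$tip.label), n_codon,
                            dimnames = list(tree$tip.label, NULL))
    for (k in sort(unique(site_classes))) {
      m <- mg94_q(kappa, omega_classes$omega[k], pi, exclude_aa = excl[k])
      idx <- which(site_classes == k)
      root_k <- match(cods[idx], m$codons)
      if (anyNA(root_k)) {
        stop2("root codon(s) excluded from the class-", k, " state space")
      }
      pfun0 <- decompose_q(m$Q, m$pi_codon)
      pfun <- function(t) pfun0(t * 3 * rate)
      sim_k <- simulate_along_tree(tree, root_k, pfun)
      for (tp in tree$tip.label) leaves_codons[tp, idx] <- m$codons[sim_k[[tp]]]
    }
    leaves <- apply(leaves_codons, 1, paste, collapse = "")
    list(leaves = leaves, site_classes = site_classes,
         omega_classes = omega_classes)
  })
}

#' Random coding sequence without stop codons
#'
#' Codons are drawn with F1x4 probabilities from the sense codons.
#'
#' @param n_codons number of codons.
#' @param pi nucleotide frequencies.
#' @param forced named character vector of codons to pin; names are
#'   1-based codon positions.
#' @param exclude_aa amino acids whose codons are never drawn.
#' @return a CDS string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, pi = c(A = .25, C = .25, G = .25, T = .25),
                       forced = NULL, exclude_aa = NULL) {
  sp <- codon_state_space(exclude_aa)
  w <- apply(sp$mat, 1, function(r) prod(pi[r]))
  idx <- sample.int(length(sp$codons), n_codons, replace = TRUE, prob = w)
  cods <- sp$codons[idx]
  if (!is.null(forced)) cods[as.integer(names(forced))] <- forced
  paste(cods, collapse = "")
}

#' Random nucleotide sequence
#' @param n length in nt.
#' @param pi nucleotide frequencies.
#' @return a nucleotide string.
#' @export
random_nt <- function(n, pi = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(NT, n, replace = TRUE, prob = pi), collapse = "")
}
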