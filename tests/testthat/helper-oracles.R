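# Independent oracles used to validate the package implementations.
# These are deliberately naive (enumeration / direct dynamic
# programming) and share no code with the functions they check.

# --- affine-gap local alignment (Gotoh), gap of length L costs
#     open + L * ext ------------------------------------------------------
oracle_local_align <- function(a, b, mat, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (horizontal)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[ca[i], cb[j]]
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                              Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# --- brute-force synonymous site counts of a codon --------------------------
oracle_codon_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  b <- strsplit(codon, "")[[1]]
  S <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(c("A", "C", "G", "T"), b[pos]), function(nt) {
      x <- b; x[pos] <- nt; paste(x, collapse = "")
    }, "")
    maa <- gc[muts]
    keep <- maa != "*"
    if (any(keep)) S <- S + sum(maa[keep] == aa) / sum(keep)
  }
  c(S = S, N = 3 - S)
}

# --- likelihood by exhaustive summation over internal-node states -----------
# transition matrix by eigendecomposition of the (general) rate matrix,
# independent of the package's reversible-decomposition route
oracle_pmat <- function(Q, t) {
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

oracle_site_loglik <- function(alignment, tree, Q, pi) {
  nt <- c("A", "C", "G", "T")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internals <- (n_tip + 1L):n_node
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    oracle_pmat(Q, tree$edge.length[e]))
  vapply(seq_len(ncol(m)), function(site) {
    obs <- m[tree$tip.label, site]
    total <- 0
    grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
    for (g in seq_len(nrow(grid))) {
      states <- integer(n_node)
      states[internals] <- grid[g, ]
      lik <- pi[states[n_tip + 1L]]
      ok <- TRUE
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        if (ch <= n_tip) {
          s <- obs[ch]
          if (s %in% nt) {
            lik <- lik * P[[e]][states[par], match(s, nt)]
          }  # gap/N: marginalizes to 1
        } else {
          lik <- lik * P[[e]][states[par], states[ch]]
        }
        if (lik == 0) { ok <- FALSE; break }
      }
      if (ok) total <- total + lik
    }
    log(total)
  }, 0)
}
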