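# Per-site log-likelihood of an alignment on a tree under GTR, by
# Felsenstein's pruning algorithm, with optional discrete-gamma rate
# heterogeneity.  Gap and N columns contribute all-ones partials
# (missing data).

#' GTR model parameters
#'
#' @param exchangeabilities symmetric rates in the order AC, AG, AT, CG,
#'   CT, GT (equal rates give JC/F81).
#' @param pi base frequencies (A, C, G, T).
#' @param gamma_categories number of discrete-gamma rate categories
#'   (1 = no rate heterogeneity).
#' @param alpha gamma shape (used when `gamma_categories > 1`).
#' @return validated parameter list.
#' @export
gtr_params <- function(exchangeabilities = rep(1, 6),
                       pi = c(A = .25, C = .25, G = .25, T = .25),
                       gamma_categories = 1L, alpha = 1) {
  stopifnot(length(exchangeabilities) == 6L, all(exchangeabilities > 0),
            length(pi) == 4L, abs(sum(pi) - 1) < 1e-8,
            gamma_categories >= 1L, alpha > 0)
  list(exchangeabilities = exchangeabilities, pi = setNames(pi, NT),
       gamma_categories = as.integer(gamma_categories), alpha = alpha)
}

#' GTR rate matrix, normalized to one substitution per site per unit time
#' @param params list from [gtr_params()].
#' @return 4x4 rate matrix.
#' @export
gtr_q <- function(params) {
  s <- params$exchangeabilities; pi <- params$pi
  Q <- matrix(0, 4, 4, dimnames = list(NT, NT))
  pair <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pair[k, 1]; j <- pair[k, 2]
    Q[i, j] <- s[k] * pi[j]
    Q[j, i] <- s[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

alignment_matrix <- function(alignment) {
  if (length(unique(nchar(alignment))) != 1L) {
    stop2("sequences are not aligned (unequal lengths)")
  }
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Per-site log-likelihood by Felsenstein pruning
#'
#' @param alignment named character vector of aligned nucleotide
#'   sequences (gaps `-` and `N` treated as missing).
#' @param tree [ape::phylo] whose tip labels equal the alignment names;
#'   may be rooted or unrooted (the model is reversible, so the
#'   likelihood does not depend on the root position).
#' @param params list from [gtr_params()].
#' @return object of class `site_likelihoods`: list with `site_loglik`
#'   (numeric vector), `total`, `params`.
#' @export
felsenstein_loglik <- function(alignment, tree, params = gtr_params()) {
  m <- alignment_matrix(alignment)
  sym_diff <- c(setdiff(tree$tip.label, rownames(m)),
                setdiff(rownames(m), tree$tip.label))
  if (length(sym_diff)) {
    stop2("tree/alignment leaf mismatch: ", paste(sym_diff, collapse = ", "))
  }
  nsites <- ncol(m)
  n_tip <- length(tree$tip.label)
  pfun0 <- decompose_q(gtr_q(params), params$pi)
  rates_w <- if (params$gamma_categories > 1L) {
    r <- phangorn::discrete.gamma(params$alpha, params$gamma_categories)
    list(rates = r, w = rep(1 / params$gamma_categories,
                            params$gamma_categories))
  } else list(rates = 1, w = 1)

  tip_partial <- function(label) {
    p <- matrix(0, 4, nsites)
    s <- m[label, ]
    known <- match(s, NT)
    miss <- is.na(known)
    p[cbind(known[!miss], which(!miss))] <- 1
    p[, miss] <- 1
    p
  }

  # postorder traversal independent of edge ordering
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lik_sites <- matrix(0, length(rates_w$rates), nsites)
  for (k in seq_along(rates_w$rates)) {
    rate <- rates_w$rates[k]
    partial <- function(node) {
      if (node <= n_tip) {
        return(list(p = tip_partial(tree$tip.label[node]), logscale = 0))
      }
      p <- matrix(1, 4, nsites); logscale <- 0
      for (e in children[[as.character(node)]]) {
        child <- partial(tree$edge[e, 2])
        P <- pfun0(tree$edge.length[e] * rate)
        p <- p * (P %*% child$p)
        logscale <- logscale + child$logscale
        cmax <- apply(p, 2, max)
        cmax[cmax == 0] <- 1
        p <- sweep(p, 2, cmax, "/")
        logscale <- logscale + log(cmax)
      }
      list(p = p, logscale = logscale)
    }
    root <- partial(n_tip + 1L)
    lik_sites[k, ] <- log(colSums(params$pi * root$p)) + root$logscale
  }
  site_loglik <- if (nrow(lik_sites) == 1L) lik_sites[1, ] else {
    apply(lik_sites, 2, function(v) {
      mx <- max(v); mx + log(sum(rates_w$w * exp(v - mx)))
    })
  }
  structure(list(site_loglik = site_loglik, total = sum(site_loglik),
                 params = params),
            class = "site_likelihoods")
}

#' Optimize branch lengths of a fixed topology by maximum likelihood
#'
#' Delegates to phangorn's `pml`/`optim.pml` with the topology held
#' fixed, then returns the tree with optimized branch lengths.
#'
#' @param alignment named character vector of aligned nt sequences.
#' @param topology [ape::phylo]; branch lengths (if any) are used as
#'   starting values.
#' @param model "JC" or "GTR".
#' @return [ape::phylo] with ML branch lengths.
#' @export
optimize_branch_lengths <- function(alignment, topology, model = c("JC", "GTR")) {
  model <- match.arg(model)
  m <- alignment_matrix(alignment)
  dat <- phangorn::phyDat(m, type = "DNA")
  tr <- ape::unroot(topology)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr$edge.length[tr$edge.length <= 1e-8] <- 1e-8
  fit <- phangorn::pml(tr, dat, model = model)
  fit <- suppressWarnings(phangorn::optim.pml(
    fit, optEdge = TRUE, optBf = (model == "GTR"), optQ = (model == "GTR"),
    control = phangorn::pml.control(trace = 0)))
  fit$tree
}
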