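# Parsimony ancestral reconstruction on nucleotides with codon-level
# classification of the implied changes, pooled per branch or lineage,
# plus a per-site constraint scan.
#
# Reconstruction is Fitch/Sankoff (unit cost) per nucleotide position;
# all equally parsimonious assignments (up to a cap) are enumerated and
# the implied per-branch synonymous/nonsynonymous counts averaged over
# them.  Multi-position codon changes on one branch are averaged over
# minimal stop-avoiding pathways; a change whose endpoint is a stop
# codon (possible in ancestral reconstructions) counts its differing
# positions as nonsynonymous.

# Sankoff unit-cost DP for one column; states: 1..4 (NT), NA = missing.
# Returns a list of optimal assignments (integer vectors over all nodes).
enumerate_mp_assignments <- function(tree, tip_states, cap = 256L) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  INF <- 1e9
  cost <- matrix(0, n_node, 4L)
  for (i in seq_len(n_tip)) {
    if (!is.na(tip_states[i])) {
      cost[i, ] <- INF; cost[i, tip_states[i]] <- 0
    }
  }
  # explicit postorder
  order_nodes <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_nodes <- c(v, order_nodes)
    for (e in children[[as.character(v)]] %||% integer(0)) {
      stack <- c(stack, tree$edge[e, 2])
    }
  }
  for (v in order_nodes) {
    if (v <= n_tip) next
    for (e in children[[as.character(v)]]) {
      ch <- tree$edge[e, 2]
      step <- vapply(1:4, function(s) min(cost[ch, ] + (1:4 != s)), 0)
      cost[v, ] <- cost[v, ] + step
    }
  }
  assigns <- lapply(which(cost[root, ] == min(cost[root, ])), function(s) {
    a <- rep(NA_integer_, n_node); a[root] <- s; list(a)
  })
  assigns <- unlist(assigns, recursive = FALSE)
  # preorder expansion
  pre <- rev(order_nodes)
  for (v in pre) {
    if (v == root) next
    par <- tree$edge[tree$edge[, 2] == v, 1]
    new_assigns <- list()
    for (a in assigns) {
      s_par <- a[par]
      opts <- which(cost[v, ] + (1:4 != s_par) ==
                      min(cost[v, ] + (1:4 != s_par)))
      for (s in opts) {
        b <- a; b[v] <- s
        new_assigns[[length(new_assigns) + 1L]] <- b
        if (length(new_assigns) >= cap) break
      }
      if (length(new_assigns) >= cap) break
    }
    assigns <- new_assigns
  }
  assigns
}

# classification of the change along one branch between two codons
branch_codon_changes <- function(codon_parent, codon_child) {
  if (codon_parent == codon_child) return(c(Sd = 0, Nd = 0))
  tab <- ng86_tables()
  i <- match(codon_parent, tab$sense); j <- match(codon_child, tab$sense)
  if (!is.na(i) && !is.na(j)) {
    ch <- c(Sd = tab$Sd[i, j], Nd = tab$Nd[i, j])
    if (!anyNA(ch)) return(ch)
  }
  nd <- sum(chars(codon_parent) != chars(codon_child))
  c(Sd = 0, Nd = nd)
}

# per-column, per-branch expected (Sd, Nd) averaged over equally
# parsimonious reconstructions; internal workhorse shared by
# parsimony_branch_counts() and site_constraint_scan()
column_branch_counts <- function(tree, codons, cap = 256L) {
  n_tip <- length(tree$tip.label)
  pos_states <- lapply(1:3, function(p) {
    s <- substring(codons, p, p)
    st <- match(s, NT)
    st
  })
  asg <- lapply(pos_states, function(st)
    enumerate_mp_assignments(tree, st, cap = cap))
  n_edge <- nrow(tree$edge)
  acc <- matrix(0, n_edge, 2L, dimnames = list(NULL, c("Sd", "Nd")))
  combos <- expand.grid(a = seq_along(asg[[1]]), b = seq_along(asg[[2]]),
                        c = seq_along(asg[[3]]))
  if (nrow(combos) > cap) combos <- combos[seq_len(cap), , drop = FALSE]
  for (r in seq_len(nrow(combos))) {
    a1 <- asg[[1]][[combos$a[r]]]; a2 <- asg[[2]][[combos$b[r]]]
    a3 <- asg[[3]][[combos$c[r]]]
    for (e in seq_len(n_edge)) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      cp <- paste0(NT[a1[par]], NT[a2[par]], NT[a3[par]])
      cc <- paste0(NT[a1[ch]], NT[a2[ch]], NT[a3[ch]])
      if (is.na(cp) || is.na(cc)) next
      acc[e, ] <- acc[e, ] + branch_codon_changes(cp, cc)
    }
  }
  acc / nrow(combos)
}

branch_names <- function(tree) {
  n_tip <- length(tree$tip.label)
  vapply(seq_len(nrow(tree$edge)), function(e) {
    ch <- tree$edge[e, 2]
    if (ch <= n_tip) tree$tip.label[ch] else paste0("node", ch)
  }, "")
}

#' Per-branch parsimony counts of synonymous/nonsynonymous changes
#'
#' @param codon_alignment named character vector of equal-length,
#'   gap-free or gapped coding sequences (columns with gaps/ambiguity
#'   are treated as missing for the affected leaves).
#' @param tree rooted [ape::phylo]; leaves must match the alignment.
#' @param cap maximum number of equally parsimonious reconstructions
#'   averaged per column.
#' @return data.frame with branch (named by its child node), parent,
#'   child, Sd, Nd.
#' @export
parsimony_branch_counts <- function(codon_alignment, tree, cap = 256L) {
  m <- check_codon_alignment(codon_alignment, tree)
  n_codon <- nchar(codon_alignment[1]) %/% 3L
  acc <- matrix(0, nrow(tree$edge), 2L,
                dimnames = list(NULL, c("Sd", "Nd")))
  for (k in seq_len(n_codon)) {
    codons <- substring(codon_alignment[tree$tip.label],
                        3L * k - 2L, 3L * k)
    acc <- acc + column_branch_counts(tree, codons, cap = cap)
  }
  data.frame(branch = branch_names(tree),
             parent = tree$edge[, 1], child = tree$edge[, 2],
             Sd = acc[, "Sd"], Nd = acc[, "Nd"],
             stringsAsFactors = FALSE)
}

check_codon_alignment <- function(codon_alignment, tree) {
  if (length(unique(nchar(codon_alignment))) != 1L) {
    stop2("alignment sequences differ in length")
  }
  if (nchar(codon_alignment[1]) %% 3L != 0L) {
    stop2("alignment length not divisible by 3")
  }
  sym <- c(setdiff(tree$tip.label, names(codon_alignment)),
           setdiff(names(codon_alignment), tree$tip.label))
  if (length(sym)) stop2("tree/alignment leaf mismatch: ",
                         paste(sym, collapse = ", "))
  invisible(codon_alignment)
}

# mean per-sequence site opportunities over the alignment
alignment_site_counts <- function(codon_alignment) {
  tab <- ng86_tables()
  per_seq <- vapply(codon_alignment, function(s) {
    idx <- match(codon_split(s), tab$sense)
    idx <- idx[!is.na(idx)]
    c(S = sum(tab$sites[idx, "S"]), N = sum(tab$sites[idx, "N"]))
  }, c(S = 0, N = 0))
  rowMeans(per_seq)
}

#' Pool per-branch substitution counts into named lineages
#'
#' @param branch_counts result of [parsimony_branch_counts()].
#' @param lineage_definitions named list of character vectors of branch
#'   names; the sets must be disjoint.
#' @param codon_alignment alignment used for the counts (provides the
#'   site opportunities of the pooled dN/dS).
#' @return data.frame per pool with Nd, Sd, N_sites, S_sites, the
#'   per-site substitution densities dN = Nd/N_sites and
#'   dS = Sd/S_sites (parsimony change counts are events, not
#'   proportions of differing sites, so no multiple-hit correction is
#'   applied), omega = dN/dS (NA when Sd = 0, flagged by `sd_zero`) and
#'   ds_dn_ratio = dS/dN, the opportunity-corrected "synonymous
#'   outnumber nonsynonymous" ratio.
#' @export
pool_lineages <- function(branch_counts, lineage_definitions, codon_alignment) {
  all_br <- unlist(lineage_definitions)
  if (anyDuplicated(all_br)) {
    stop2("branch assigned to more than one pool: ",
          paste(unique(all_br[duplicated(all_br)]), collapse = ", "))
  }
  missing_br <- setdiff(all_br, branch_counts$branch)
  if (length(missing_br)) stop2("unknown branch in pools: ",
                                paste(missing_br, collapse = ", "))
  sites <- alignment_site_counts(codon_alignment)
  rows <- lapply(names(lineage_definitions), function(pool) {
    sel <- branch_counts$branch %in% lineage_definitions[[pool]]
    Nd <- sum(branch_counts$Nd[sel]); Sd <- sum(branch_counts$Sd[sel])
    dN <- Nd / sites[["N"]]; dS <- Sd / sites[["S"]]
    data.frame(pool = pool, Nd = Nd, Sd = Sd,
               N_sites = sites[["N"]], S_sites = sites[["S"]],
               dN = dN, dS = dS,
               omega = if (Sd > 0) dN / dS else NA_real_,
               sd_zero = Sd == 0,
               ds_dn_ratio = if (Nd > 0) dS / dN else Inf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-codon-site constraint scan
#'
#' For every codon column the observed parsimony nonsynonymous changes
#' are compared with an opportunity-scaled expectation (tree-wide
#' substitution intensity times the column's nonsynonymous site count);
#' the constraint score is `ln(expected_N / (observed_N + 0.5))`, so
#' invariant columns with high opportunity score highest.  Columns
#' whose consensus amino acid is cysteine are flagged.
#'
#' @inheritParams parsimony_branch_counts
#' @return data.frame with site, obs_N, obs_S, exp_N, score,
#'   is_cysteine.
#' @export
site_constraint_scan <- function(codon_alignment, tree, cap = 256L) {
  check_codon_alignment(codon_alignment, tree)
  n_codon <- nchar(codon_alignment[1]) %/% 3L
  tab <- ng86_tables()
  obs <- matrix(0, n_codon, 2L, dimnames = list(NULL, c("Sd", "Nd")))
  opp <- matrix(0, n_codon, 2L, dimnames = list(NULL, c("S", "N")))
  cons_aa <- character(n_codon)
  for (k in seq_len(n_codon)) {
    codons <- substring(codon_alignment[tree$tip.label],
                        3L * k - 2L, 3L * k)
    cc <- column_branch_counts(tree, codons, cap = cap)
    obs[k, ] <- colSums(cc)
    idx <- match(codons, tab$sense)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      opp[k, "S"] <- mean(tab$sites[idx, "S"])
      opp[k, "N"] <- mean(tab$sites[idx, "N"])
    }
    aa <- translate_codons(codons[!is.na(match(codons, tab$sense))])
    cons_aa[k] <- if (length(aa)) names(which.max(table(aa))) else NA_character_
  }
  mu <- sum(obs) / sum(opp)
  exp_N <- mu * opp[, "N"]
  data.frame(site = seq_len(n_codon),
             obs_N = obs[, "Nd"], obs_S = obs[, "Sd"],
             exp_N = exp_N,
             score = log(exp_N / (obs[, "Nd"] + 0.5)),
             is_cysteine = cons_aa == "C",
             stringsAsFactors = FALSE)
}
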