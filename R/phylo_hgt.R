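# Clade-nesting support for a horizontal-transfer hypothesis: are the
# parasite sequences monophyletic, and is that clade nested inside the
# donor-candidate clade once the tree is rooted on the outgroup?

placement_checks <- function(tree, groups) {
  parasite <- names(groups)[groups == "self"]
  node <- if (length(parasite) == 1L) {
    match(parasite, tree$tip.label)
  } else {
    ape::getMRCA(tree, parasite)
  }
  desc_tips <- function(nd) {
    if (nd <= length(tree$tip.label)) return(tree$tip.label[nd])
    tree$tip.label[unlist(phangorn::Descendants(tree, nd, "tips"))]
  }
  clade <- desc_tips(node)
  mono <- setequal(clade, parasite) || length(parasite) == 1L
  # smallest enclosing clade that brings in non-parasite leaves
  host_node <- node
  while (setequal(desc_tips(host_node), parasite)) {
    parent <- tree$edge[tree$edge[, 2] == host_node, 1]
    if (length(parent) == 0L) break
    host_node <- parent
  }
  neighbors <- setdiff(desc_tips(host_node), parasite)
  nested <- mono && length(neighbors) > 0 &&
    all(groups[neighbors] == "donor_candidate")
  list(parasite_monophyly = mono, nested_in_donor = nested)
}

#' Phylogenetic support for nesting of parasite sequences in the donor clade
#'
#' Builds a neighbor-joining tree (JC distances), roots it on the
#' outgroup, asks whether the parasite sequences form a clade whose
#' smallest enclosing clade is otherwise purely donor-candidate, and
#' bootstraps alignment columns to attach a support percentage to that
#' nesting.
#'
#' @param alignment named character vector of aligned nt sequences.
#' @param groups named character vector mapping each alignment name to
#'   "self" (parasite), "donor_candidate" or "other" (outgroup).
#' @param n_bootstrap column-resampling replicates.
#' @param seed integer seed (substream "placement").
#' @return list with parasite_monophyly, nested_in_donor, support (%).
#' @export
hgt_placement_support <- function(alignment, groups, n_bootstrap = 1000L,
                                  seed = NULL) {
  if (is.null(names(groups))) stop2("groups must be named")
  missing_g <- setdiff(names(alignment), names(groups))
  if (length(missing_g)) {
    stop2("groups missing for: ", paste(missing_g, collapse = ", "))
  }
  outgroup <- names(groups)[groups == "other"]
  if (length(outgroup) == 0L) stop2("no outgroup (group 'other') sequence")
  if (sum(groups == "self") < 1L || sum(groups == "donor_candidate") < 2L) {
    stop2("need at least 1 parasite and 2 donor-candidate sequences")
  }
  groups <- groups[names(alignment)]

  build_and_check <- function(aln) {
    tr <- nj_tree(distance_matrix(aln, "JC"))
    tr <- ape::root(tr, outgroup = intersect(outgroup, tr$tip.label),
                    resolve.root = TRUE)
    placement_checks(tr, groups)
  }
  obs <- build_and_check(alignment)

  m <- alignment_matrix(alignment)
  nsites <- ncol(m)
  hits <- with_stream_seed(seed, "placement", {
    vapply(seq_len(n_bootstrap), function(b) {
      cols <- sample.int(nsites, nsites, replace = TRUE)
      aln_b <- setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                        rownames(m))
      res <- tryCatch(build_and_check(aln_b), error = function(e) NULL)
      !is.null(res) && res$parasite_monophyly && res$nested_in_donor
    }, TRUE)
  })
  list(parasite_monophyly = obs$parasite_monophyly,
       nested_in_donor = obs$nested_in_donor,
       support = 100 * mean(hits))
}
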