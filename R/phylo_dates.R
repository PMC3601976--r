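# Strict-clock node dating by mean path lengths: each node's depth is
# the mean root-to-tip path length through it, a single global rate is
# fixed by one calibrated node, and ages are depths divided by that
# rate.  The calibration is used as a point value; a clocklikeness
# diagnostic (coefficient of variation of tip depths) is reported so
# non-clock inputs are visible.

#' Root a tree on an outgroup, balancing the root edge
#'
#' [ape::root()] places the new root at the outgroup attachment node,
#' which leaves one root child with a zero-length stem; for clock
#' dating the root should instead sit on the outgroup edge at the point
#' equalizing the mean root-to-tip paths of its two sides.  This helper
#' redistributes the two root-edge lengths accordingly (their sum is
#' preserved).
#'
#' @param tree unrooted (or rooted) [ape::phylo] with branch lengths.
#' @param outgroup tip label(s) to root on.
#' @return rooted [ape::phylo].
#' @export
root_on_outgroup <- function(tree, outgroup) {
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  re <- which(tr$edge[, 1] == root)
  if (length(re) != 2L) return(tr)
  dep <- ape::node.depth.edgelength(tr)
  mean_path <- vapply(re, function(e) {
    ch <- tr$edge[e, 2]
    tips <- if (ch <= n_tip) ch else
      unlist(phangorn::Descendants(tr, ch, "tips"))
    mean(dep[tips]) - dep[ch]
  }, 0)
  total <- sum(tr$edge.length[re])
  x <- (mean_path[2] - mean_path[1] + total) / 2
  x <- min(max(x, 0), total)
  tr$edge.length[re] <- c(x, total - x)
  tr
}

#' Strict-clock mean-path-length node dating
#'
#' @param tree rooted [ape::phylo] with branch lengths in
#'   substitutions/site.
#' @param calibration_node either "root" or a character vector of tip
#'   labels whose MRCA is the calibrated node.
#' @param calibration_age age assigned to the calibration node (e.g. My).
#' @return list with `ages` (numeric, one per node; tips first as in
#'   ape), `rate` (substitutions/site per unit age), `tip_depth_cv`
#'   (clocklikeness diagnostic), `tree`.
#' @export
mpl_dates <- function(tree, calibration_node = "root", calibration_age) {
  if (is.null(tree$edge.length)) stop2("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_node <- n_tip + tree$Nnode
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  # mean path length to descendant tips, post-order
  mpl <- numeric(n_node); ntips_below <- integer(n_node)
  walk <- function(node) {
    if (node <= n_tip) { mpl[node] <<- 0; ntips_below[node] <<- 1L; return() }
    tot <- 0; cnt <- 0L
    for (e in children[[as.character(node)]]) {
      ch <- tree$edge[e, 2]
      walk(ch)
      tot <- tot + (mpl[ch] + tree$edge.length[e]) * ntips_below[ch]
      cnt <- cnt + ntips_below[ch]
    }
    mpl[node] <<- tot / cnt; ntips_below[node] <<- cnt
  }
  walk(root)

  calib <- if (identical(calibration_node, "root")) root else {
    if (!all(calibration_node %in% tree$tip.label)) {
      stop2("calibration tips not in tree")
    }
    if (length(calibration_node) == 1L) {
      stop2("calibration_node needs at least two tips (or \"root\")")
    }
    ape::getMRCA(tree, calibration_node)
  }
  if (mpl[calib] <= 0) stop2("calibration node has zero depth")
  rate <- mpl[calib] / calibration_age
  ages <- mpl / rate

  # enforce parent >= child age (can be violated on non-clock trees)
  clamped <- FALSE
  pre <- order(ape::node.depth.edgelength(tree)[tree$edge[, 2]])
  for (e in pre) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (ages[ch] > ages[par]) { ages[ch] <- ages[par]; clamped <- TRUE }
  }
  if (clamped) warning("non-clocklike tree: some ages clamped to parent age")

  depth <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]
  cv <- if (mean(depth) > 0) sd(depth) / mean(depth) else NA_real_
  list(ages = ages, rate = rate, tip_depth_cv = cv, tree = tree)
}

#' Age of the MRCA of a set of tips under an mpl_dates result
#' @param dates result of [mpl_dates()].
#' @param tips character vector of tip labels.
#' @return numeric age.
#' @export
mrca_age <- function(dates, tips) {
  tr <- dates$tree
  node <- if (length(tips) == 1L) match(tips, tr$tip.label) else
    ape::getMRCA(tr, tips)
  dates$ages[node]
}
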