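# Simulation of dated species trees and a gene tree carrying one
# horizontal transfer followed by one duplication.
#
# Species trees are pure-birth in topology (random joins, which matches
# the Yule labelled-history distribution); node ages are uniform order
# statistics below the crown age, so tree depth is controlled exactly by
# the stated crown age.  Trees are represented internally as nested
# lists with absolute node ages and rendered to newick, where branch
# lengths are in the same time units (My) as the ages.

sim_nested_yule <- function(labels, crown_age) {
  n <- length(labels)
  if (n == 1L) return(list(age = 0, label = labels, children = NULL))
  ages <- if (n == 2L) crown_age else c(sort(runif(n - 2L, 0, crown_age)), crown_age)
  pool <- lapply(labels, function(l) list(age = 0, label = l, children = NULL))
  for (a in ages) {
    pick <- sample.int(length(pool), 2L)
    merged <- list(age = a, label = NULL,
                   children = pool[pick])
    pool <- c(pool[-pick], list(merged))
  }
  pool[[1]]
}

nested_to_newick <- function(node, parent_age = NULL) {
  body <- if (is.null(node$children)) {
    node$label
  } else {
    paste0("(", paste(vapply(node$children, nested_to_newick, "",
                             parent_age = node$age), collapse = ","), ")")
  }
  if (is.null(parent_age)) paste0(body, ";")
  else paste0(body, ":", format(parent_age - node$age, digits = 12))
}

nested_tips <- function(node) {
  if (is.null(node$children)) return(node$label)
  unlist(lapply(node$children, nested_tips))
}

nested_relabel <- function(node, suffix) {
  if (is.null(node$children)) {
    node$label <- paste0(node$label, suffix)
  } else {
    node$children <- lapply(node$children, nested_relabel, suffix = suffix)
  }
  node
}

# maximal clade containing `label` whose crown age is strictly below
# `age`; NULL when even the tip lineage qualifies only trivially
nested_find_clade_below <- function(node, age, label) {
  if (!(label %in% nested_tips(node))) return(NULL)
  if (node$age < age) return(node)
  if (is.null(node$children)) return(NULL)
  for (ch in node$children) {
    hit <- nested_find_clade_below(ch, age, label)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

nested_replace <- function(node, target, replacement) {
  if (identical(node, target)) return(replacement)
  if (is.null(node$children)) return(node)
  node$children <- lapply(node$children, nested_replace,
                          target = target, replacement = replacement)
  node
}

# insert `graft` on the lineage leading to tip `tip_label`, at `age`
nested_graft_on_lineage <- function(node, tip_label, age, graft) {
  if (is.null(node$children)) {
    if (!identical(node$label, tip_label)) return(node)
    return(list(age = age, label = NULL, children = list(node, graft)))
  }
  on_path <- vapply(node$children, function(ch) tip_label %in% nested_tips(ch), TRUE)
  i <- which(on_path)
  stopifnot(length(i) == 1L)
  child <- node$children[[i]]
  if (child$age < age && node$age >= age) {
    node$children[[i]] <- list(age = age, label = NULL,
                               children = list(child, graft))
  } else {
    node$children[[i]] <- nested_graft_on_lineage(child, tip_label, age, graft)
  }
  node
}

#' Scenario parameters for the synthetic transfer benchmark
#'
#' Defaults follow the study system: a donor (host legume) clade with
#' crown age 39 My, a transfer into one donor lineage 16 My ago, a
#' parasite crown age of 11 My and a single gene duplication 5 My ago in
#' a designated parasite subclade.
#'
#' @param n_host_taxa,n_parasite_taxa clade sizes.
#' @param root_age donor-clade crown age (My).
#' @param transfer_age age of the horizontal transfer (My).
#' @param parasite_crown_age crown age of the parasite gene clade (My).
#' @param duplication_age age of the parasite-lineage duplication (My);
#'   0 disables the duplication.
#' @param subst_rate substitutions/site/My for nucleotide evolution.
#' @param kappa transition/transversion rate ratio.
#' @param pi base frequencies (A, C, G, T).
#' @param omega_classes data.frame with columns omega, prop describing
#'   the dN/dS site classes of coding simulations.
#' @param n_background number of vertically inherited background gene
#'   families in the transcriptome fixture.
#' @param intron_length intron length (nt) for genomic fixtures.
#' @param expression_profile per-stage target RPKM vector for the
#'   planted gene (the default spans a >1000-fold range with the minimum
#'   at stage 3 and the maximum at stage 6.2, mirroring an
#'   attachment-stage trough and a reproductive-stage peak).
#' @param seed master seed; every generator derives named substreams.
#' @return a validated scenario list.
#' @export
sim_scenario <- function(n_host_taxa = 6L, n_parasite_taxa = 4L,
                         root_age = 39, transfer_age = 16,
                         parasite_crown_age = 11, duplication_age = 5,
                         subst_rate = 0.01, kappa = 2,
                         pi = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                         omega_classes = data.frame(omega = c(0.05, 0.35),
                                                    prop = c(0.5, 0.5)),
                         n_background = 50L, intron_length = 90L,
                         expression_profile = c(stage0 = 40, stage1 = 25,
                                                stage2 = 15, stage3 = 0.6,
                                                stage4 = 30, stage5 = 80,
                                                stage6.1 = 250,
                                                stage6.2 = 600),
                         seed = 1L) {
  sc <- list(n_host_taxa = as.integer(n_host_taxa),
             n_parasite_taxa = as.integer(n_parasite_taxa),
             root_age = root_age, transfer_age = transfer_age,
             parasite_crown_age = parasite_crown_age,
             duplication_age = duplication_age,
             subst_rate = subst_rate, kappa = kappa, pi = pi,
             omega_classes = omega_classes,
             n_background = as.integer(n_background),
             intron_length = as.integer(intron_length),
             expression_profile = expression_profile,
             seed = as.integer(seed))
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  if (!(sc$transfer_age > 0 && sc$transfer_age < sc$root_age)) {
    stop2("need 0 < transfer_age < root_age")
  }
  if (sc$duplication_age >= sc$transfer_age || sc$duplication_age < 0) {
    stop2("need 0 <= duplication_age < transfer_age")
  }
  if (sc$parasite_crown_age >= sc$transfer_age) {
    stop2("parasite_crown_age must be below transfer_age")
  }
  if (abs(sum(sc$pi) - 1) > 1e-8) stop2("pi must sum to 1")
  if (abs(sum(sc$omega_classes$prop) - 1) > 1e-8) {
    stop2("omega class proportions must sum to 1")
  }
  if (sc$n_host_taxa < 2L || sc$n_parasite_taxa < 1L) {
    stop2("need at least 2 host and 1 parasite taxa")
  }
  invisible(sc)
}

#' Simulate a dated gene tree containing one horizontal transfer
#'
#' Builds ultrametric pure-birth species trees for the host (donor) and
#' parasite clades, then a gene tree in which the parasite gene clade
#' attaches inside the host clade on the lineage of a designated donor
#' species at `transfer_age`, with one subsequent duplication at
#' `duplication_age` in the deepest parasite subclade younger than the
#' duplication.  Branch lengths are in time units.
#'
#' @param scenario list from [sim_scenario()].
#' @param seed optional override of `scenario$seed`.
#' @return list with `gene_tree`, `host_tree`, `parasite_tree`
#'   ([ape::phylo]) and `events` (donor tip, gene-to-species map,
#'   duplication info).
#' @export
simulate_gene_tree_with_hgt <- function(scenario, seed = scenario$seed) {
  validate_scenario(scenario)
  with_stream_seed(seed, "gene_tree", {
    host_names <- sprintf("Donor_%d", seq_len(scenario$n_host_taxa))
    para_names <- sprintf("Parasite_%d", seq_len(scenario$n_parasite_taxa))
    host <- sim_nested_yule(host_names, scenario$root_age)
    para <- if (scenario$n_parasite_taxa == 1L) {
      list(age = 0, label = para_names, children = NULL)
    } else {
      sim_nested_yule(para_names, scenario$parasite_crown_age)
    }

    dup_species <- character(0)
    if (scenario$duplication_age > 0) {
      # the duplication is planted in the subclade holding the focal
      # (first) parasite species
      clade <- nested_find_clade_below(para, scenario$duplication_age,
                                       para_names[1])
      if (is.null(clade)) {  # duplicate the focal tip lineage alone
        clade <- list(age = 0, label = para_names[1], children = NULL)
      }
      dup_species <- nested_tips(clade)
      dup_node <- list(age = scenario$duplication_age, label = NULL,
                       children = list(nested_relabel(clade, "_1"),
                                       nested_relabel(clade, "_2")))
      para2 <- nested_replace(para, clade, dup_node)
      if (identical(para2, para) && is.null(para$children)) para2 <- dup_node
      para <- para2
    }

    donor_tip <- sample(host_names, 1L)
    gene <- nested_graft_on_lineage(host, donor_tip, scenario$transfer_age, para)

    gene_tree <- parse_newick(nested_to_newick(gene))
    parasite_gene_ids <- setdiff(gene_tree$tip.label, host_names)
    # undecorated ids are single-copy species; "_1"/"_2" mark paralogs
    gene_species <- ifelse(parasite_gene_ids %in% para_names,
                           parasite_gene_ids,
                           sub("_[12]$", "", parasite_gene_ids))
    list(gene_tree = gene_tree,
         host_tree = parse_newick(nested_to_newick(host)),
         parasite_tree = parse_newick(nested_to_newick(para)),
         events = list(transfer_age = scenario$transfer_age,
                       duplication_age = scenario$duplication_age,
                       donor_tip = donor_tip,
                       parasite_gene_ids = parasite_gene_ids,
                       gene_species = setNames(gene_species, parasite_gene_ids),
                       duplicated_species = dup_species))
  })
}

#' Node ages of an ultrametric (or nearly ultrametric) rooted tree
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @return numeric vector of ages (max root-to-tip depth minus node
#'   depth) indexed by node number (tips first, as in ape).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}
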