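# End-to-end pipeline over the synthetic fixture: orchestrates the
# simulate, screen, phylo, selection, structure and expression stages,
# keeps intermediate results in memory and writes machine-readable TSV
# reports.  Identical seeds give identical reports.

PIPELINE_STAGES <- c("simulate", "screen", "phylo", "selection",
                     "structure", "expression")

#' Basal donor clade opposite the recipient lineage
#'
#' The host-tree root splits the donors in two; the side not containing
#' the recipient (donor_tip) lineage is the natural rooting clade for
#' the gene tree (it is monophyletic there by construction).
#'
#' @param sim result of [simulate_gene_tree_with_hgt()] (or the `xeno`
#'   component of a fixture).
#' @return character vector of donor tip labels.
#' @export
basal_donor_outgroup <- function(sim) {
  host <- sim$host_tree
  n_tip <- length(host$tip.label)
  root_children <- host$edge[host$edge[, 1] == n_tip + 1L, 2]
  sides <- lapply(root_children, function(ch) {
    if (ch <= n_tip) host$tip.label[ch]
    else host$tip.label[unlist(phangorn::Descendants(host, ch, "tips"))]
  })
  recipient_side <- vapply(sides, function(s) sim$events$donor_tip %in% s, TRUE)
  unlist(sides[!recipient_side])
}

#' Taxon-role assignment for the xenolog family alignment
#'
#' All parasite gene copies are "self"; the basal donor clade opposite
#' the recipient lineage becomes the outgroup ("other"), provided at
#' least two donor-candidate leaves remain (otherwise only its deepest
#' tip is used); remaining donors stay "donor_candidate".
#'
#' @param fixture result of [make_transcriptome_fixture()].
#' @return named character vector over the alignment sequences.
#' @export
xeno_groups <- function(fixture) {
  aln_names <- names(fixture$xeno$alignment)
  parasites <- fixture$xeno$events$parasite_gene_ids
  donors <- setdiff(aln_names, parasites)
  out <- intersect(basal_donor_outgroup(fixture$xeno), donors)
  if (length(donors) - length(out) < 2L) {
    dmat <- ape::cophenetic.phylo(fixture$xeno$host_tree)
    out <- out[which.max(dmat[out, fixture$xeno$events$donor_tip])]
  }
  groups <- setNames(rep("donor_candidate", length(aln_names)), aln_names)
  groups[parasites] <- "self"
  groups[out] <- "other"
  groups
}

#' Alternative ("no transfer") topology for the topology tests
#'
#' Moves the parasite clade from its nested position to the basal
#' (outgroup) side of the donor clade — the closest realizable
#' arrangement to "the parasite sequences fall outside the donor clade
#' sampled here", which is what vertical inheritance would predict.
#' Always topologically distinct from the nested placement because the
#' recipient lineage sits on the other side of the root.
#'
#' @param tree rooted [ape::phylo] containing the parasite tips.
#' @param parasite_tips tip labels of the parasite clade.
#' @param outgroup_tips basal clade next to which the parasites are
#'   re-attached.
#' @return rooted [ape::phylo] with the same tip set.
#' @export
make_vertical_alternative <- function(tree, parasite_tips, outgroup_tips) {
  pclade <- if (length(parasite_tips) == 1L) {
    structure(list(edge = matrix(c(2L, 1L), 1), tip.label = parasite_tips,
                   edge.length = 0.05, Nnode = 1L), class = "phylo")
  } else {
    ape::extract.clade(tree, ape::getMRCA(tree, parasite_tips))
  }
  pclade$root.edge <- 0.05
  rest <- ape::drop.tip(tree, parasite_tips)
  at <- if (length(outgroup_tips) == 1L) {
    match(outgroup_tips, rest$tip.label)
  } else {
    ape::getMRCA(rest, intersect(outgroup_tips, rest$tip.label))
  }
  e <- which(rest$edge[, 2] == at)
  pos <- if (length(e)) min(0.05, rest$edge.length[e] / 2) else 0
  ape::bind.tree(rest, pclade, where = at, position = pos)
}

#' Partition gene-tree branches into lineage pools
#'
#' Branches whose descendant tips are all parasite copies form the
#' "parasite" pool, branches with only donor tips the "donor" pool and
#' the rest (the transfer backbone) the "backbone" pool.
#'
#' @param tree rooted [ape::phylo].
#' @param parasite_tips tip labels of the parasite copies.
#' @return named list of branch-name vectors as used by
#'   [pool_lineages()].
#' @export
define_lineage_pools <- function(tree, parasite_tips) {
  br <- branch_names(tree)
  n_tip <- length(tree$tip.label)
  pool <- vapply(seq_len(nrow(tree$edge)), function(e) {
    ch <- tree$edge[e, 2]
    tips <- if (ch <= n_tip) tree$tip.label[ch] else
      tree$tip.label[unlist(phangorn::Descendants(tree, ch, "tips"))]
    if (all(tips %in% parasite_tips)) "parasite"
    else if (!any(tips %in% parasite_tips)) "donor"
    else "backbone"
  }, "")
  split(br, pool)
}

#' Run the synthetic-data pipeline
#'
#' @param config list from [default_config()] or [read_config()].
#' @param stages character vector of stage names, or "all".  Later
#'   stages depend on earlier ones; requesting a stage without its
#'   prerequisite is an error naming the stage.
#' @param out_dir report directory (created); `NULL` disables writing.
#' @return named list of per-stage results, invisibly when writing.
#' @export
run_pipeline <- function(config = default_config(), stages = "all",
                         out_dir = NULL) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop2("unknown pipeline stage(s): ",
                         paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  res <- list(config = config)
  log_msg <- function(...) message("[hgtrace] ", sprintf(...))
  need <- function(what, stage) {
    if (is.null(res[[what]])) stop2("stage '", stage, "' requires stage '",
                                    what, "' to run first")
    res[[what]]
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        log_msg("simulating fixture (seed %d)", config$seed)
        res$simulate <- make_transcriptome_fixture(config$scenario,
                                                   seed = config$seed)
      },
      screen = {
        fx <- need("simulate", "screen")
        log_msg("screening %d contigs", nrow(fx$contigs))
        res$screen <- run_screen(fx$contigs, fx$references, fx$taxon_map,
                                 thresholds = config$screen,
                                 seed_k = config$search$seed_k)
      },
      phylo = {
        fx <- need("simulate", "phylo")
        log_msg("phylogenetic confirmation and dating")
        res$phylo <- phylo_stage(fx, config)
      },
      selection = {
        fx <- need("simulate", "selection")
        log_msg("selection-constraint analysis")
        res$selection <- selection_stage(fx)
      },
      structure = {
        fx <- need("simulate", "structure")
        log_msg("gene-structure and scaffold validation")
        res$structure <- structure_stage(fx, config)
      },
      expression = {
        fx <- need("simulate", "expression")
        log_msg("stage-wise expression profiling")
        res$expression <- expression_stage(fx, config)
      })
  }
  if (!is.null(out_dir)) {
    write_pipeline_reports(res, out_dir)
    return(invisible(res))
  }
  res
}

phylo_stage <- function(fixture, config) {
  aln <- fixture$xeno$alignment
  groups <- xeno_groups(fixture)
  placement <- hgt_placement_support(aln, groups,
                                     n_bootstrap = config$phylo$n_bootstrap,
                                     seed = config$seed)
  # NJ estimate rooted on the basal donor clade
  est <- nj_tree(distance_matrix(aln, "JC"))
  outgroup <- intersect(basal_donor_outgroup(fixture$xeno), names(aln))
  est <- root_on_outgroup(est, outgroup)

  parasites <- fixture$xeno$events$parasite_gene_ids
  alt <- make_vertical_alternative(est, parasites, outgroup)
  t_hgt <- optimize_branch_lengths(aln, est, model = "JC")
  t_alt <- optimize_branch_lengths(aln, alt, model = "JC")
  sl <- rbind(
    hgt = felsenstein_loglik(aln, t_hgt)$site_loglik,
    vertical = felsenstein_loglik(aln, t_alt)$site_loglik)
  rell <- rell_topology_test(sl, n_reps = config$phylo$rell_reps,
                             seed = config$seed)

  donors <- setdiff(names(aln), parasites)
  dates <- mpl_dates(est, calibration_node = donors,
                     calibration_age = config$phylo$calibration_age)
  ages <- c(
    transfer = mrca_age(dates, c(parasites, fixture$xeno$events$donor_tip)),
    parasite_crown = if (length(parasites) > 1)
      mrca_age(dates, parasites) else NA_real_,
    duplication = duplication_age_estimate(dates, fixture))
  list(placement = placement, rell = rell, dates = dates, ages = ages,
       tree = est, alternative = alt)
}

duplication_age_estimate <- function(dates, fixture) {
  dup_sp <- fixture$xeno$events$duplicated_species
  if (length(dup_sp) == 0L) return(NA_real_)
  copies <- paste0(dup_sp[1], c("_1", "_2"))
  if (!all(copies %in% dates$tree$tip.label)) return(NA_real_)
  mrca_age(dates, copies)
}

selection_stage <- function(fixture) {
  aln <- fixture$xeno$alignment
  tree <- fixture$xeno$gene_tree
  parasites <- fixture$xeno$events$parasite_gene_ids
  bc <- parsimony_branch_counts(aln, tree)
  pools <- define_lineage_pools(tree, parasites)
  pooled <- pool_lineages(bc, pools, aln)
  scan <- site_constraint_scan(aln, tree)
  # pairwise dN/dS between one parasite copy and the recipient donor
  pair <- ng86_pairwise(aln[[parasites[1]]],
                        aln[[fixture$xeno$events$donor_tip]],
                        scope = "parasite_vs_donor")
  list(branch_counts = bc, pools = pools, pooled = pooled,
       site_scan = scan, pairwise = pair)
}

structure_stage <- function(fixture, config) {
  ev <- fixture$xeno$events
  aln <- fixture$xeno$alignment
  focal <- names(ev$gene_species)[ev$gene_species == FOCAL_PARASITE]
  ids <- c(focal, ev$donor_tip)
  scen <- fixture$scenario
  # homologous insertion point for every copy (the transfer carried the
  # genomic sequence, so intron positions are conserved)
  insert_after <- (nchar(aln[[ids[1]]]) %/% 2L) %/% 3L * 3L + 1L
  genomics <- list(); structures <- list(); splice <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    cds <- aln[[id]]
    intr <- fixture$xeno$introns[[id]]
    genomic <- paste0(substring(cds, 1, insert_after), intr,
                      substring(cds, insert_after + 1L, nchar(cds)))
    st <- infer_intron(genomic, cds, gene_id = id)
    genomics[[id]] <- genomic
    structures[[id]] <- st
    splice[[id]] <- check_splice_sites(st, genomic)
  }
  conserv <- intron_conservation(
    structures[[ids[1]]], genomics[[ids[1]]],
    structures[[ev$donor_tip]], genomics[[ev$donor_tip]],
    aln, ids[1], ev$donor_tip)
  prot <- function(id) paste(translate_codons(codon_split(aln[[id]])),
                             collapse = "")
  idsim <- alignment_identity_similarity(prot(ids[1]), prot(ev$donor_tip))
  profile <- scaffold_profile()
  scores <- lapply(ids, function(id) cysteine_scaffold_score(prot(id), profile))
  names(scores) <- ids
  list(structures = structures, splice = splice, conservation = conserv,
       identity_similarity = idsim, scaffold = scores)
}

expression_stage <- function(fixture, config) {
  ec <- config$expression
  scen <- fixture$scenario
  ev <- fixture$xeno$events
  focal <- names(ev$gene_species)[ev$gene_species == FOCAL_PARASITE]
  genes <- setNames(unlist(fixture$xeno$alignment[focal]), focal)
  with_stream_seed(config$seed, "expr_background", {
    for (i in seq_len(ec$n_flat_background)) {
      genes[[sprintf("flat%03d", i)]] <- random_nt(600, scen$pi)
    }
  })
  stages <- names(scen$expression_profile)
  prof <- matrix(ec$flat_rpkm, length(genes), length(stages),
                 dimnames = list(names(genes), stages))
  for (g in focal) prof[g, ] <- scen$expression_profile
  libs <- setNames(rep(ec$deep_library_size, length(stages)), stages)
  sim <- simulate_stage_reads(genes, prof, ec$read_length, libs,
                              seed = config$seed, emit_reads = FALSE)
  et <- rpkm_table(sim$counts, nchar(genes), libs)
  summ <- stage_summary(et)
  list(truth_counts = sim$counts, table = et,
       summary = summ[summ$gene %in% focal, , drop = FALSE],
       profile = prof)
}

write_pipeline_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(res$simulate)) {
    write_fasta(res$simulate$contigs, file.path(out_dir, "contigs.fasta"))
    write_fasta(res$simulate$references, file.path(out_dir, "references.fasta"))
    wtsv(res$simulate$truth, "truth.tsv")
    write_tree(res$simulate$xeno$gene_tree, file.path(out_dir, "gene_tree.nwk"))
  }
  if (!is.null(res$screen)) {
    write_screen_report(res$screen$report, out_dir)
    write_hit_table(res$screen$hits, file.path(out_dir, "hits.tsv"))
  }
  if (!is.null(res$phylo)) {
    p <- res$phylo
    wtsv(data.frame(quantity = c("parasite_monophyly", "nested_in_donor",
                                 "support_pct", "age_transfer",
                                 "age_parasite_crown", "age_duplication"),
                    value = c(p$placement$parasite_monophyly,
                              p$placement$nested_in_donor,
                              p$placement$support, p$ages["transfer"],
                              p$ages["parasite_crown"],
                              p$ages["duplication"])),
         "phylo_summary.tsv")
    wtsv(p$rell, "topology_tests.tsv")
  }
  if (!is.null(res$selection)) {
    wtsv(res$selection$pooled, "selection_pools.tsv")
    wtsv(res$selection$site_scan, "site_constraint.tsv")
  }
  if (!is.null(res$structure)) {
    s <- res$structure
    wtsv(data.frame(
      gene = names(s$scaffold),
      scaffold_total = vapply(s$scaffold, `[[`, 0, "total"),
      scaffold_pass = vapply(s$scaffold, `[[`, TRUE, "pass"),
      donor_canonical = vapply(s$splice, `[[`, TRUE, "donor_canonical"),
      acceptor_canonical = vapply(s$splice, `[[`, TRUE, "acceptor_canonical")),
      "structure_summary.tsv")
  }
  if (!is.null(res$expression)) {
    rp <- res$expression$table$rpkm
    wtsv(data.frame(gene = rownames(rp), rp, check.names = FALSE),
         "rpkm.tsv")
    wtsv(res$expression$summary, "expression_summary.tsv")
  }
  invisible(out_dir)
}
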