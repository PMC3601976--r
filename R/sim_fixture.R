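# Transcriptome fixture with one planted horizontal transfer, genomic
# (introned) fixtures, and stage-structured read simulation.
#
# The fixture emulates the real study design: a focal parasite
# transcriptome screened against two closely related nonparasitic
# species, a clade of distantly related donor-candidate (host-lineage)
# taxa, and two intermediate "other" taxa.  Background gene families are
# vertically inherited and therefore have a close-relative ortholog at
# small divergence; the planted xenolog family exists only in the donor
# clade and the parasites.

FOCAL_PARASITE <- "Parasite_1"

fixture_species <- function(scenario) {
  donors <- sprintf("Donor_%d", seq_len(scenario$n_host_taxa))
  list(parasite = FOCAL_PARASITE,
       close = c("Closerel_1", "Closerel_2"),
       donors = donors,
       others = c("Other_1", "Other_2"))
}

#' Taxon-group map used by the bundled fixture
#' @param scenario list from [sim_scenario()].
#' @return a [taxon_group_map()] covering all fixture species.
#' @export
fixture_taxon_map <- function(scenario = sim_scenario()) {
  sp <- fixture_species(scenario)
  taxon_group_map(
    species = c(sp$parasite, sp$close, sp$donors, sp$others),
    group = c("self", rep("close_relative", length(sp$close)),
              rep("donor_candidate", length(sp$donors)),
              rep("other", length(sp$others))))
}

# dated species tree used for vertically inherited background families
background_species_tree <- function(scenario) {
  sp <- fixture_species(scenario)
  tip <- function(l) list(age = 0, label = l, children = NULL)
  node <- function(a, ch) list(age = a, label = NULL, children = ch)
  ast <- node(15, list(node(10, list(tip(sp$parasite), tip(sp$close[1]))),
                       tip(sp$close[2])))
  oth <- node(30, list(tip(sp$others[1]), tip(sp$others[2])))
  lam <- node(80, list(ast, oth))
  don <- sim_nested_yule(sp$donors, scenario$root_age)
  parse_newick(nested_to_newick(node(120, list(lam, don))))
}

# canonical cysteine spacing of the planted KNOTTIN-like protein:
# 6 cysteines with inter-cysteine loop lengths 6, 5, 3, 10, 4
knottin_cys_positions <- function(offset = 40L) {
  offset + cumsum(c(0L, 7L, 6L, 4L, 11L, 5L))
}

#' Generate the default transcriptome fixture with a planted transfer
#'
#' Emits `scenario$n_background` vertically inherited gene families
#' (present in close relatives, donors and the parasite) plus one
#' planted xenolog family (present only in the donor clade and the
#' parasites, with cysteine codons pinned by an omega = 0 site class),
#' together with a per-contig truth table.  Contig lengths vary and
#' include contigs shorter than the 500 nt screening bound.
#'
#' @param scenario list from [sim_scenario()].
#' @param seed optional override of `scenario$seed`.
#' @return list with `contigs`, `references` (sequence records),
#'   `taxon_map`, `truth` (per-contig table), and `xeno` (gene tree,
#'   codon alignment, events, cysteine positions, per-site classes).
#' @export
make_transcriptome_fixture <- function(scenario = sim_scenario(),
                                       seed = scenario$seed) {
  validate_scenario(scenario)
  sp <- fixture_species(scenario)
  map <- fixture_taxon_map(scenario)

  contigs <- list(); refs <- list(); truth <- list()
  with_stream_seed(seed, "fixture_background", {
    bg_tree <- background_species_tree(scenario)
    for (f in seq_len(scenario$n_background)) {
      fam <- sprintf("bg%02d", f)
      rate_f <- scenario$subst_rate * stats::rlnorm(1, 0, 0.25)
      n_cod <- sample(90:260, 1)
      root <- random_cds(n_cod, scenario$pi)
      ev <- evolve_codon(bg_tree, root, kappa = scenario$kappa,
                         omega_classes = scenario$omega_classes,
                         pi = scenario$pi, rate = rate_f)
      cds <- ev$leaves
      utr5 <- random_nt(sample(10:80, 1), scenario$pi)
      utr3 <- random_nt(sample(10:80, 1), scenario$pi)
      contig_nt <- paste0(utr5, cds[[sp$parasite]], utr3)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") contig_nt <- revcomp(contig_nt)
      cid <- paste0("contig_", fam)
      contigs[[cid]] <- data.frame(id = cid, residues = contig_nt,
                                   stringsAsFactors = FALSE)
      truth[[cid]] <- data.frame(contig = cid, family = fam,
                                 is_xenolog = FALSE, donor_lineage = NA,
                                 strand = strand, length = nchar(contig_nt),
                                 stringsAsFactors = FALSE)
      for (s in setdiff(names(cds), sp$parasite)) {
        rid <- paste0(s, "_", fam)
        refs[[rid]] <- data.frame(id = rid, residues = cds[[s]], species = s,
                                  stringsAsFactors = FALSE)
      }
    }
  })

  # planted xenolog family
  sim <- simulate_gene_tree_with_hgt(scenario, seed = substream_seed(seed, "fixture_xeno_tree"))
  xeno <- with_stream_seed(seed, "fixture_xeno_seq", {
    n_cod <- 160L
    cys_aa <- knottin_cys_positions()
    forced <- setNames(rep("TGT", length(cys_aa)), cys_aa)
    forced <- c(setNames("ATG", 1L), forced)
    # cysteine is structurally forbidden outside the scaffold positions,
    # which evolve under omega = 0 (class 1)
    root <- random_cds(n_cod, scenario$pi, forced = forced, exclude_aa = "C")
    oc <- rbind(data.frame(omega = 0, prop = 0, exclude_aa = NA),
                cbind(scenario$omega_classes, exclude_aa = "C"))
    cls <- 1L + sample.int(nrow(scenario$omega_classes), n_cod, replace = TRUE,
                           prob = scenario$omega_classes$prop)
    cls[cys_aa] <- 1L
    ev <- evolve_codon(sim$gene_tree, root, kappa = scenario$kappa,
                       omega_classes = oc, pi = scenario$pi,
                       rate = scenario$subst_rate, site_classes = cls)
    # evolve one ancestral intron along the same gene tree (GT..AG ends
    # pinned, interior at the genomic nucleotide rate)
    intron_interior <- if (scenario$intron_length > 4L) {
      evolve_nt(sim$gene_tree, random_nt(scenario$intron_length - 4L, scenario$pi),
                rate = scenario$subst_rate, kappa = scenario$kappa,
                pi = scenario$pi)
    } else NULL
    introns <- if (is.null(intron_interior)) {
      setNames(rep("GTAG", length(ev$leaves)), names(ev$leaves))
    } else {
      setNames(paste0("GT", intron_interior[names(ev$leaves)], "AG"),
               names(ev$leaves))
    }
    list(alignment = ev$leaves, site_classes = cls, cys_positions = cys_aa,
         introns = introns)
  })

  focal_ids <- names(sim$events$gene_species)[
    sim$events$gene_species == sp$parasite]
  xeno_contigs <- with_stream_seed(seed, "fixture_xeno_contigs", {
    out <- list()
    for (g in focal_ids) {
      utr5 <- random_nt(sample(50:120, 1), scenario$pi)
      utr3 <- random_nt(sample(50:120, 1), scenario$pi)
      contig_nt <- paste0(utr5, xeno$alignment[[g]], utr3)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") contig_nt <- revcomp(contig_nt)
      cid <- paste0("contig_", g)
      out[[cid]] <- list(
        rec = data.frame(id = cid, residues = contig_nt,
                         stringsAsFactors = FALSE),
        truth = data.frame(contig = cid, family = "xeno",
                           is_xenolog = TRUE,
                           donor_lineage = sim$events$donor_tip,
                           strand = strand, length = nchar(contig_nt),
                           stringsAsFactors = FALSE))
    }
    out
  })
  for (cid in names(xeno_contigs)) {
    contigs[[cid]] <- xeno_contigs[[cid]]$rec
    truth[[cid]] <- xeno_contigs[[cid]]$truth
  }
  donor_leaves <- intersect(sim$gene_tree$tip.label, sp$donors)
  for (d in donor_leaves) {
    rid <- paste0(d, "_xeno")
    refs[[rid]] <- data.frame(id = rid, residues = xeno$alignment[[d]],
                              species = d, stringsAsFactors = FALSE)
  }

  contig_df <- do.call(rbind, contigs)
  ref_df <- do.call(rbind, refs)
  contig_rec <- sequence_records(contig_df$id, contig_df$residues,
                                 species = sp$parasite, group = "self")
  ref_rec <- annotate_groups(
    sequence_records(ref_df$id, ref_df$residues, species = ref_df$species),
    map)
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  list(contigs = contig_rec, references = ref_rec, taxon_map = map,
       truth = truth_df,
       xeno = c(sim["gene_tree"], sim["host_tree"], sim["parasite_tree"],
                list(events = sim$events, alignment = xeno$alignment,
                     cys_positions = xeno$cys_positions,
                     site_classes = xeno$site_classes,
                     introns = xeno$introns)),
       scenario = scenario)
}

#' Insert a single spliceosomal intron into a coding sequence
#'
#' The intron begins with the canonical donor dinucleotide `GT` and ends
#' with the acceptor `AG`; concatenating the two exons recovers the
#' input CDS exactly.
#'
#' @param cds coding sequence (nt).
#' @param intron_length total intron length, at least 4 nt.
#' @param insert_after 1-based CDS position after which the intron is
#'   inserted; `NULL` picks a random internal position.
#' @param seed integer seed (substream "intron").
#' @return list with `genomic` (string) and `structure` (a
#'   `gene_structure`: exon/intron intervals in 0-based half-open
#'   coordinates, donor and acceptor dinucleotides, intron phase).
#' @export
make_genomic_with_intron <- function(cds, intron_length, insert_after = NULL,
                                     seed = NULL) {
  cds <- toupper(cds)
  if (intron_length < 4L) stop2("intron_length must be at least 4 (GT..AG)")
  n <- nchar(cds)
  if (n < 2L) stop2("cds too short")
  with_stream_seed(seed, "intron", {
    if (is.null(insert_after)) insert_after <- sample(seq_len(n - 1L), 1L)
    if (insert_after < 1L || insert_after >= n) {
      stop2("insert_after must be inside the CDS")
    }
    mid <- if (intron_length > 4L) random_nt(intron_length - 4L) else ""
    intron <- paste0("GT", mid, "AG")
    genomic <- paste0(substring(cds, 1, insert_after), intron,
                      substring(cds, insert_after + 1L, n))
    structure_obj <- gene_structure(
      exons = rbind(c(0L, insert_after),
                    c(insert_after + intron_length, n + intron_length)),
      intron = c(insert_after, insert_after + intron_length),
      phase = insert_after %% 3L,
      donor = "GT", acceptor = "AG")
    list(genomic = genomic, structure = structure_obj)
  })
}

#' Simulate stage-structured reads with known truth counts
#'
#' Per stage, read counts over genes are multinomial with probabilities
#' proportional to `target RPKM x gene length`; reads are exact
#' substrings at uniform positions, from either strand.
#'
#' @param genes named character vector of gene sequences (nt).
#' @param expression_profile gene x stage matrix of target RPKM
#'   (rownames = gene names).
#' @param read_length read length, at most the shortest gene.
#' @param library_sizes per-stage read totals (named as the stages).
#' @param seed integer seed (substream "reads").
#' @param emit_reads when `FALSE` only truth counts are produced (for
#'   deep libraries).
#' @return list with `counts` (gene x stage truth matrix) and `reads`
#'   (per-stage list of sequence-record data.frames, or `NULL`).
#' @export
simulate_stage_reads <- function(genes, expression_profile, read_length,
                                 library_sizes, seed = NULL,
                                 emit_reads = TRUE) {
  if (any(library_sizes <= 0)) stop2("library sizes must be positive")
  if (read_length > min(nchar(genes))) {
    stop2("read_length exceeds the shortest gene")
  }
  stopifnot(nrow(expression_profile) == length(genes),
            ncol(expression_profile) == length(library_sizes))
  with_stream_seed(seed, "reads", {
    lens <- nchar(genes)
    counts <- matrix(0L, length(genes), length(library_sizes),
                     dimnames = list(names(genes), names(library_sizes)))
    reads <- if (emit_reads) list() else NULL
    for (s in seq_along(library_sizes)) {
      w <- expression_profile[, s] * lens
      if (sum(w) <= 0) stop2("all-zero expression profile in stage ", s)
      counts[, s] <- as.integer(rmultinom(1, library_sizes[s], w / sum(w)))
      if (emit_reads) {
        recs <- list()
        for (g in seq_along(genes)) {
          k <- counts[g, s]
          if (k == 0L) next
          starts <- sample.int(lens[g] - read_length + 1L, k, replace = TRUE)
          rs <- substring(genes[g], starts, starts + read_length - 1L)
          flip <- runif(k) < 0.5
          rs[flip] <- revcomp(rs[flip])
          recs[[g]] <- data.frame(
            id = sprintf("%s_s%d_r%d", names(genes)[g], s, seq_len(k)),
            residues = rs, stringsAsFactors = FALSE)
        }
        df <- do.call(rbind, recs)
        reads[[names(library_sizes)[s] %||% as.character(s)]] <-
          sequence_records(df$id, df$residues)
      }
    }
    list(counts = counts, reads = reads)
  })
}
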