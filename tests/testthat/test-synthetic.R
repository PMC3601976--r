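test_that("the simulated gene tree carries the planted transfer and duplication", {
  sc <- sim_scenario(seed = 5)
  sim <- simulate_gene_tree_with_hgt(sc)
  gt <- sim$gene_tree
  expect_true(ape::is.ultrametric(gt, tol = 1e-6))
  ages <- node_ages(gt)
  parasites <- sim$events$parasite_gene_ids
  # transfer node: MRCA of the parasite copies and the recipient donor
  tn <- ape::getMRCA(gt, c(parasites, sim$events$donor_tip))
  expect_equal(ages[tn], sc$transfer_age, tolerance = 1e-6)
  # duplication node at the planted age, containing the focal species
  dup <- sim$events$duplicated_species
  expect_true("Parasite_1" %in% dup)
  dn <- ape::getMRCA(gt, paste0(dup[1], c("_1", "_2")))
  expect_equal(ages[dn], sc$duplication_age, tolerance = 1e-6)
  # parasite copies form a clade nested inside the donor clade
  pm <- ape::getMRCA(gt, parasites)
  ptips <- gt$tip.label[unlist(phangorn::Descendants(gt, pm, "tips"))]
  expect_setequal(ptips, parasites)
})

test_that("duplication_age = 0 leaves one copy per parasite species", {
  sc <- sim_scenario(duplication_age = 0, seed = 5)
  sim <- simulate_gene_tree_with_hgt(sc)
  expect_setequal(sim$events$parasite_gene_ids,
                  sprintf("Parasite_%d", 1:sc$n_parasite_taxa))
})

test_that("scenario validation rejects inconsistent ages", {
  expect_error(sim_scenario(transfer_age = 40, root_age = 39), "transfer_age")
  expect_error(sim_scenario(duplication_age = 20, transfer_age = 16),
               "duplication_age")
  expect_error(sim_scenario(pi = c(A = 1, C = 1, G = 0, T = 0)), "pi")
})

test_that("nucleotide evolution is exact on degenerate and stationary cases", {
  tr <- parse_newick("((A:0,B:0):0,C:0);")
  root <- random_nt(200)
  leaves <- evolve_nt(tr, root, rate = 1, seed = 3)
  expect_true(all(leaves == root))

  # very long branches: pairwise identity approaches sum(pi^2)
  pi <- c(A = 0.4, C = 0.3, G = 0.2, T = 0.1)
  two <- parse_newick("(A:50,B:50);")
  lv <- evolve_nt(two, random_nt(10000), rate = 1, kappa = 2, pi = pi,
                  seed = 4)
  p_same <- mean(strsplit(lv[["A"]], "")[[1]] == strsplit(lv[["B"]], "")[[1]])
  expect_equal(p_same, sum(pi^2),
               tolerance = 3 * sqrt(sum(pi^2) * (1 - sum(pi^2)) / 10000) /
                 sum(pi^2))

  # determinism under a fixed seed
  expect_identical(evolve_nt(two, root, rate = 0.1, seed = 9),
                   evolve_nt(two, root, rate = 0.1, seed = 9))
  expect_error(evolve_nt(two, "", rate = 1), "empty")
})

test_that("codon evolution respects omega classes and excluded residues", {
  two <- parse_newick("(A:2,B:2);")
  root <- random_cds(300, exclude_aa = "C")
  # omega = 0: no amino-acid change can ever occur
  ev0 <- evolve_codon(two, root,
                      omega_classes = data.frame(omega = 0, prop = 1),
                      seed = 6)
  aa <- lapply(ev0$leaves, function(s)
    translate_codons(hgtrace:::codon_split(s)))
  expect_identical(aa[["A"]], aa[["B"]])
  expect_false(identical(ev0$leaves[["A"]], ev0$leaves[["B"]]))  # syn changes

  # excluded amino acid never arises
  evx <- evolve_codon(two, root,
                      omega_classes = data.frame(omega = 1, prop = 1,
                                                 exclude_aa = "C"),
                      seed = 7)
  expect_false(any(grepl("C", vapply(evx$leaves, function(s)
    paste(translate_codons(hgtrace:::codon_split(s)), collapse = ""), ""))))

  expect_error(evolve_codon(two, "ATGTAAATG"), "stop")
  expect_identical(evolve_codon(two, root, seed = 8)$leaves,
                   evolve_codon(two, root, seed = 8)$leaves)
})

test_that("genomic fixtures hold a canonical intron and reconstitute the CDS", {
  g <- make_genomic_with_intron("ATGAAATGA", 6L, insert_after = 3L)
  expect_equal(nchar(g$genomic), 15L)
  expect_equal(substr(g$genomic, 4, 5), "GT")
  expect_equal(substr(g$genomic, 8, 9), "AG")
  ex <- g$structure$exons
  spliced <- paste0(substr(g$genomic, ex[1, 1] + 1, ex[1, 2]),
                    substr(g$genomic, ex[2, 1] + 1, ex[2, 2]))
  expect_equal(spliced, "ATGAAATGA")
  expect_equal(g$structure$phase, 0L)
  expect_error(make_genomic_with_intron("ATGAAA", 3L), "at least 4")
})

test_that("stage reads honor the profile, the seed and the truth counts", {
  genes <- c(g1 = random_nt(300), g2 = random_nt(300))
  prof <- matrix(c(10, 0, 10, 10), 2, 2,
                 dimnames = list(names(genes), c("s1", "s2")))
  sim <- simulate_stage_reads(genes, prof, 50L, c(s1 = 200L, s2 = 200L),
                              seed = 12)
  # g2 silent in stage 1: all stage-1 reads from g1
  expect_equal(unname(sim$counts[, "s1"]), c(200L, 0L))
  expect_equal(sum(sim$counts[, "s2"]), 200L)
  expect_equal(nrow(sim$reads[["s1"]]), 200L)
  # reads are exact substrings of a gene or its reverse complement
  r1 <- sim$reads[["s1"]]$residues[1:20]
  hit <- vapply(r1, function(r) grepl(r, genes[["g1"]], fixed = TRUE) ||
                  grepl(revcomp(r), genes[["g1"]], fixed = TRUE), TRUE)
  expect_true(all(hit))
  sim2 <- simulate_stage_reads(genes, prof, 50L, c(s1 = 200L, s2 = 200L),
                               seed = 12)
  expect_identical(sim$reads[["s2"]]$residues, sim2$reads[["s2"]]$residues)
  expect_error(simulate_stage_reads(genes, prof, 50L, c(s1 = 0L, s2 = 1L)),
               "positive")
})

test_that("only the planted xenologs lack close-relative reference homologs", {
  fx <- small_fixture()
  close_sp <- fx$taxon_map$species[fx$taxon_map$group == "close_relative"]
  ref_fam <- sub("^.*_(bg[0-9]+|xeno)$", "\\1", fx$references$id)
  fam_with_close <- unique(ref_fam[fx$references$species %in% close_sp])
  expect_false("xeno" %in% fam_with_close)
  bg_fams <- unique(fx$truth$family[!fx$truth$is_xenolog])
  expect_true(all(bg_fams %in% fam_with_close))
  # every emitted contig appears exactly once in the truth table
  expect_setequal(fx$truth$contig, fx$contigs$id)
  expect_false(anyDuplicated(fx$truth$contig) > 0)
})
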