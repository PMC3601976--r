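test_that("codon site counts match hand enumeration on canonical codons", {
  expect_equal(codon_site_counts("TTT"), c(S = 1 / 3, N = 8 / 3))
  expect_equal(codon_site_counts("GGG"), c(S = 1, N = 2))
  expect_equal(codon_site_counts("ATG"), c(S = 0, N = 3))
  expect_error(codon_site_counts("TAA"), "stop")
  expect_error(codon_site_counts("ANG"), "ambiguous|invalid")
})

test_that("site counts agree with brute-force enumeration for all 61 sense codons", {
  for (cod in hgtrace:::sense_codons()) {
    expect_equal(codon_site_counts(cod), oracle_codon_sites(cod),
                 tolerance = 1e-12, info = cod)
  }
})

test_that("pairwise NG86 reproduces hand-computed examples", {
  same <- ng86_pairwise("ATGAAA", "ATGAAA")
  expect_equal(same$Nd, 0); expect_equal(same$Sd, 0)
  expect_equal(same$dN, 0); expect_equal(same$dS, 0)
  expect_true(is.na(same$omega))

  ex <- ng86_pairwise("GGGGGG", "GGAGGG")
  expect_equal(ex$Sd, 1); expect_equal(ex$Nd, 0)
  expect_equal(ex$S_sites, 2); expect_equal(ex$N_sites, 4)
  expect_equal(ex$dS, -0.75 * log(1 / 3), tolerance = 1e-12)
  expect_equal(ex$dN, 0)

  expect_error(ng86_pairwise("ATG", "ATGAAA"), "length")
})

test_that("NG86 is symmetric and skips ambiguous codons pairwise", {
  set.seed(21)
  a <- random_cds(200); b <- random_cds(200)
  ab <- ng86_pairwise(a, b); ba <- ng86_pairwise(b, a)
  expect_equal(ab$Nd, ba$Nd); expect_equal(ab$Sd, ba$Sd)
  expect_equal(ab$omega, ba$omega)

  a2 <- paste0("NNN", substring(a, 4))
  expect_equal(ng86_pairwise(a2, b)$n_codons, 199)
})

test_that("parsimony branch counts localize single changes and bound pairwise differences", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  inv <- setNames(rep("ATGGCT", 4), c("A", "B", "C", "D"))
  bc0 <- parsimony_branch_counts(inv, tr)
  expect_true(all(bc0$Sd == 0) && all(bc0$Nd == 0))

  # one synonymous autapomorphy in A (GCT -> GCC, both Ala)
  aut <- inv; aut[["A"]] <- "ATGGCC"
  bc1 <- parsimony_branch_counts(aut, tr)
  expect_equal(bc1$Sd[bc1$branch == "A"], 1)
  expect_equal(bc1$Nd[bc1$branch == "A"], 0)
  expect_equal(sum(bc1$Sd) + sum(bc1$Nd), 1)

  # a nonsynonymous one (GCT -> GTT, Ala -> Val)
  aut2 <- inv; aut2[["B"]] <- "ATGGTT"
  bc2 <- parsimony_branch_counts(aut2, tr)
  expect_equal(bc2$Nd[bc2$branch == "B"], 1)

  # total changes bound below by pairwise differences
  set.seed(9)
  sim <- evolve_codon(tr, random_cds(100),
                      omega_classes = data.frame(omega = 0.5, prop = 1),
                      rate = 0.2, seed = 9)
  bc <- parsimony_branch_counts(sim$leaves, tr)
  total <- sum(bc$Sd) + sum(bc$Nd)
  pair <- ng86_pairwise(sim$leaves[["A"]], sim$leaves[["C"]])
  expect_gte(total + 1e-9, pair$Sd + pair$Nd)

  expect_error(parsimony_branch_counts(inv[1:3], tr), "mismatch")
})

test_that("lineage pooling sums counts, guards the partition, and is order-invariant", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  set.seed(10)
  sim <- evolve_codon(tr, random_cds(150),
                      omega_classes = data.frame(omega = 0.3, prop = 1),
                      rate = 0.3, seed = 10)
  bc <- parsimony_branch_counts(sim$leaves, tr)
  pools <- list(left = c("A", "B"), right = c("C", "D"))
  p1 <- pool_lineages(bc, pools, sim$leaves)
  p2 <- pool_lineages(bc, list(left = c("B", "A"), right = c("D", "C")),
                      sim$leaves)
  expect_equal(p1$Nd, p2$Nd); expect_equal(p1$omega, p2$omega)
  expect_equal(p1$Nd[1], sum(bc$Nd[bc$branch %in% c("A", "B")]))

  expect_error(pool_lineages(bc, list(x = "A", y = c("A", "B")), sim$leaves),
               "more than one pool")
  expect_error(pool_lineages(bc, list(x = "nope"), sim$leaves), "unknown")

  inv <- setNames(rep("ATGGCT", 4), c("A", "B", "C", "D"))
  bz <- parsimony_branch_counts(inv, tr)
  pz <- pool_lineages(bz, pools, inv)
  expect_true(all(is.na(pz$omega)))
  expect_true(all(pz$sd_zero))
})

test_that("the constraint scan ranks pinned cysteine columns in the top decile", {
  # designated construction: cysteine columns at omega 0, everything
  # else neutral, on a tree long enough that neutral columns change
  tr <- parse_newick("(((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2):0.1,(E:0.4,F:0.4):0.2);")
  n_cod <- 100L
  cys <- c(10L, 30L, 50L, 70L, 90L)
  set.seed(14)
  root <- random_cds(n_cod, forced = setNames(rep("TGT", length(cys)), cys),
                     exclude_aa = "C")
  oc <- data.frame(omega = c(0, 1), prop = c(0.05, 0.95),
                   exclude_aa = c(NA, "C"))
  cls <- rep(2L, n_cod); cls[cys] <- 1L
  sim <- evolve_codon(tr, root, omega_classes = oc, site_classes = cls,
                      rate = 1, seed = 14)
  scan <- site_constraint_scan(sim$leaves, tr)
  expect_setequal(scan$site[scan$is_cysteine], cys)
  expect_true(all(is.finite(scan$score)))
  decile <- quantile(scan$score, 0.9)
  expect_true(all(scan$score[cys] >= decile))

  # columns without nonsynonymous changes score by opportunity alone
  inv_idx <- which(scan$obs_N == 0)
  expect_true(length(inv_idx) > 0)
  expect_equal(scan$score[inv_idx],
               log(scan$exp_N[inv_idx] / 0.5), tolerance = 1e-9)
})
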