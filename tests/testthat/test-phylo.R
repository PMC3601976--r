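test_that("JC distances match the closed form and flag saturation", {
  # construct a pair with exactly 30% mismatches
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 30), strrep("A", 70))
  D <- distance_matrix(c(x = a, y = b), "JC")
  expect_equal(D["x", "y"], -0.75 * log(1 - 4 * 0.3 / 3), tolerance = 1e-12)
  expect_equal(D["x", "x"], 0)

  b80 <- paste0(strrep("C", 80), strrep("A", 20))
  D2 <- distance_matrix(c(x = a, y = b80), "JC")
  expect_true(is.na(D2["x", "y"]))
  expect_true(attr(D2, "saturated")["x", "y"])

  # cross-check against ape on a simulated alignment
  set.seed(31)
  tr <- ape::rtree(6)
  aln <- evolve_nt(tr, random_nt(2000), rate = 0.1, kappa = 1, seed = 31)
  D3 <- distance_matrix(aln, "JC")
  m <- do.call(rbind, strsplit(aln, ""))
  rownames(m) <- names(aln)
  Dape <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "JC69",
                                  pairwise.deletion = TRUE))
  expect_equal(D3, Dape[rownames(D3), colnames(D3)], tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(distance_matrix(c(x = "AC--", y = "--CA", z = "GCAA")),
               "no overlapping")
})

test_that("neighbor joining recovers additive trees and the 3-taxon closed form", {
  # additive matrix from a known 4-taxon tree
  tr <- parse_newick("((A:2,B:3):1,(C:4,D:5):2);")
  D <- ape::cophenetic.phylo(tr)
  est <- nj_tree(D)
  expect_equal(ape::dist.topo(est, ape::unroot(tr)), 0, ignore_attr = TRUE)
  expect_equal(sum(est$edge.length), sum(tr$edge.length), tolerance = 1e-9)

  # three taxa: unique star with three-point formula
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  est3 <- nj_tree(D3)
  lens <- setNames(est3$edge.length[match(1:3, est3$edge[, 2])],
                   est3$tip.label)
  expect_equal(lens[["A"]], 1)  # (3 + 4 - 5) / 2
  expect_equal(lens[["B"]], 2)
  expect_equal(lens[["C"]], 3)

  Dbad <- D3; Dbad[1, 2] <- Dbad[2, 1] <- NaN
  expect_error(nj_tree(Dbad), "NA|NaN")

  # property: NJ recovers random additive topologies
  set.seed(17)
  for (i in 1:5) {
    rt <- ape::rtree(7)
    expect_equal(ape::dist.topo(nj_tree(ape::cophenetic.phylo(rt)),
                                ape::unroot(rt)), 0, ignore_attr = TRUE)
  }
})

test_that("pruning likelihood matches exhaustive state enumeration", {
  params <- gtr_params(exchangeabilities = c(1, 2, 1, 1, 2, 1),
                       pi = c(A = .3, C = .2, G = .2, T = .3))
  Q <- gtr_q(params)
  set.seed(41)
  for (i in 1:6) {
    n_leaf <- sample(3:4, 1)
    tr <- ape::rtree(n_leaf)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.6)
    aln <- evolve_nt(tr, random_nt(3), rate = 1, seed = 41 + i)
    if (i == 6) substr(aln[1], 1, 1) <- "N"   # missing data handled too
    got <- felsenstein_loglik(aln, tr, params)
    want <- oracle_site_loglik(aln, tr, Q, params$pi)
    expect_equal(got$site_loglik, want, tolerance = 1e-8)
    expect_equal(got$total, sum(want), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant under re-rooting (reversible model)", {
  set.seed(43)
  tr <- ape::unroot(ape::rtree(5))
  aln <- evolve_nt(tr, random_nt(40), rate = 0.5, seed = 43)
  base <- felsenstein_loglik(aln, tr)$total
  for (og in tr$tip.label[1:3]) {
    rerooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(felsenstein_loglik(aln, rerooted)$total, base,
                 tolerance = 1e-6)
  }
})

test_that("degenerate two-leaf zero-branch case gives log stationary frequency", {
  tr <- parse_newick("(A:0,B:0);")
  params <- gtr_params(pi = c(A = .4, C = .1, G = .2, T = .3))
  out <- felsenstein_loglik(c(A = "A", B = "A"), tr, params)
  expect_equal(out$site_loglik, log(0.4), tolerance = 1e-10)
})

test_that("leaf mismatches are reported with the symmetric difference", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  expect_error(felsenstein_loglik(c(A = "A", B = "C", D = "G"), tr), "C.*D|D.*C")
})

test_that("RELL tests are exact on degenerate input and invariant to site order", {
  sl <- matrix(rnorm(2 * 50), 2, 50, dimnames = list(c("a", "b"), NULL))
  sl[2, ] <- sl[1, ]
  r <- rell_topology_test(sl, n_reps = 500, seed = 1)
  expect_equal(r$p_kh, c(1, 1))
  expect_equal(r$p_sh, c(1, 1))

  # a constant per-site shift makes the worse topology reject
  set.seed(2)
  base <- rnorm(200)
  sl2 <- rbind(A = base, B = base - 10 / 200)
  r2 <- rell_topology_test(sl2, n_reps = 2000, seed = 2)
  expect_true(r2$best[1])
  expect_lt(r2$p_kh[2], 0.01)

  # permuting sites changes nothing
  set.seed(3)
  sl3 <- rbind(A = rnorm(100), B = rnorm(100))
  perm <- sample(100)
  ra <- rell_topology_test(sl3, n_reps = 500, seed = 5)
  rb <- rell_topology_test(sl3[, perm], n_reps = 500, seed = 5)
  expect_equal(ra$p_kh, rb$p_kh)
  expect_equal(ra$p_sh, rb$p_sh)

  expect_error(rell_topology_test(sl[1, , drop = FALSE]), "two topologies")
  expect_warning(rell_topology_test(sl, n_reps = 50, seed = 1), "100")
})

test_that("mean-path-length dating is exact on clock-like trees", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  d <- mpl_dates(tr, "root", 39)
  ab <- mrca_age(d, c("A", "B"))
  expect_equal(ab, 19.5)
  expect_equal(mrca_age(d, c("A", "C")), 39)
  expect_lt(d$tip_depth_cv, 1e-10)

  # non-clock trees still return ages plus a diagnostic
  tr2 <- parse_newick("((A:5,B:5):0.1,C:0.2);")
  expect_warning(d2 <- mpl_dates(tr2, "root", 10), "clamp|clock")
  expect_true(is.finite(d2$tip_depth_cv) && d2$tip_depth_cv > 0)
  expect_error(mpl_dates(parse_newick("(A:0,B:0);"), "root", 10), "zero depth")
})

test_that("outgroup rooting balances the root edge on clock-like data", {
  sc <- sim_scenario(seed = 3)
  sim <- simulate_gene_tree_with_hgt(sc, seed = 3)
  set.seed(3)
  aln <- evolve_nt(sim$gene_tree, random_nt(5000), rate = 0.01, kappa = 1,
                   seed = 30)
  tr <- root_on_outgroup(nj_tree(distance_matrix(aln, "JC")),
                         basal_donor_outgroup(sim))
  d <- mpl_dates(tr, grep("^Donor", names(aln), value = TRUE), 39)
  expect_lt(d$tip_depth_cv, 0.1)
})

test_that("placement support identifies nesting for transferred genes only", {
  fx <- small_fixture()
  groups <- xeno_groups(fx)
  res <- hgt_placement_support(fx$xeno$alignment, groups,
                               n_bootstrap = 100, seed = 2)
  expect_true(res$parasite_monophyly)
  expect_true(res$nested_in_donor)
  expect_gt(res$support, 50)

  # vertically inherited family: the parasite groups with its close
  # relatives, so the enclosing clade is not purely donor
  vt <- hgtrace:::background_species_tree(fx$scenario)
  set.seed(8)
  aln <- evolve_nt(vt, random_nt(900), rate = 0.01, kappa = 1, seed = 80)
  vgroups <- setNames(rep("donor_candidate", length(aln)), names(aln))
  vgroups["Parasite_1"] <- "self"
  vgroups[c("Closerel_1", "Closerel_2")] <- "close_relative"
  vgroups[c("Other_1", "Other_2")] <- "other"
  vres <- hgt_placement_support(aln, vgroups, n_bootstrap = 50, seed = 3)
  expect_false(vres$nested_in_donor)

  expect_error(hgt_placement_support(
    fx$xeno$alignment, setNames(rep("self", length(groups)), names(groups))),
    "outgroup")
})
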