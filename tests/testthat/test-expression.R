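test_that("naive mapping inverts the read simulator and applies the tie rule", {
  set.seed(61)
  genes <- c(g1 = random_nt(300), g2 = random_nt(300))
  prof <- matrix(c(50, 50), 2, 1, dimnames = list(names(genes), "s1"))
  sim <- simulate_stage_reads(genes, prof, 40L, c(s1 = 120L), seed = 61)
  mapped <- naive_map_counts(sim$reads[["s1"]], genes)
  expect_equal(mapped$counts, sim$counts[, "s1"])
  expect_equal(mapped$n_ambiguous, 0L)
  expect_equal(mapped$n_unmapped, 0L)

  # a reverse-complement read still counts
  r <- sequence_records("rc", revcomp(substr(genes[["g1"]], 11, 50)))
  expect_equal(unname(naive_map_counts(r, genes)$counts), c(1L, 0L))

  # identical genes make every read ambiguous
  twin <- c(a = genes[["g1"]], b = genes[["g1"]])
  r2 <- sequence_records("amb", substr(genes[["g1"]], 1, 40))
  m2 <- naive_map_counts(r2, twin)
  expect_equal(sum(m2$counts), 0L)
  expect_equal(m2$n_ambiguous, 1L)

  # mismatch tolerance resolves to the best match
  mut <- substr(genes[["g1"]], 1, 40)
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(mut, 5, 5))[1]
  r3 <- sequence_records("mm", mut)
  expect_equal(unname(naive_map_counts(r3, genes, max_mismatch = 0L)$counts),
               c(0L, 0L))
  expect_equal(unname(naive_map_counts(r3, genes, max_mismatch = 1L)$counts),
               c(1L, 0L))

  expect_error(naive_map_counts(r3, character(0)), "empty")
})

test_that("RPKM follows the count/length/library formula exactly", {
  et <- rpkm_table(c(gene = 10L), c(gene = 1000L), 1e6)
  expect_equal(unname(et$rpkm[1, 1]), 10)
  expect_equal(unname(rpkm_table(c(g = 0L), c(g = 500L), 1e6)$rpkm[1, 1]), 0)
  expect_equal(unname(rpkm_table(c(g = 5L), c(g = 500L), 2e6)$rpkm[1, 1]), 5)
  expect_error(rpkm_table(c(g = 1L), c(g = 500L), 0), "positive")
  expect_error(rpkm_table(c(g = 1L), c(g = 0L), 1e6), "positive")

  # metamorphic: linear in counts, inverse in length and library size
  base <- rpkm_table(c(g = 7L), c(g = 700L), 3e6)$rpkm[1, 1]
  expect_equal(rpkm_table(c(g = 14L), c(g = 700L), 3e6)$rpkm[1, 1], 2 * base)
  expect_equal(rpkm_table(c(g = 7L), c(g = 1400L), 3e6)$rpkm[1, 1], base / 2)
  expect_equal(rpkm_table(c(g = 7L), c(g = 700L), 6e6)$rpkm[1, 1], base / 2)
})

test_that("stage summaries report extremes, folds and infinite-fold flags", {
  counts <- matrix(c(1L, 1000L), 1, 2,
                   dimnames = list("g", c("early", "late")))
  et <- rpkm_table(counts, c(g = 1000L), c(early = 1e6, late = 1e6))
  s <- stage_summary(et)
  expect_equal(s$max_min_fold, 1000)
  expect_equal(s$max_stage, "late")

  const <- rpkm_table(matrix(5L, 1, 3, dimnames = list("g", NULL)),
                      c(g = 100L), rep(1e6, 3))
  sc <- stage_summary(const)
  expect_equal(sc$max_min_fold, 1)
  expect_equal(sc$min_stage, sc$max_stage)  # ties break to stage order

  zero <- rpkm_table(matrix(c(0L, 10L), 1, 2, dimnames = list("g", NULL)),
                     c(g = 100L), rep(1e6, 2))
  sz <- stage_summary(zero)
  expect_true(sz$infinite_fold)
  expect_equal(sz$max_min_fold, Inf)

  expect_error(stage_summary(rpkm_table(matrix(1L, 1, 1), 100L, 1e6)),
               "two stages")
})
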