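# Constructed hit tables exercising each cascade rule, plus the
# end-to-end planted-truth comparison.

screen_map <- function() {
  taxon_group_map(
    species = c("Mimulus", "Lindenbergia", "Medicago", "Vitis", "Solanum"),
    group = c("close_relative", "close_relative", "donor_candidate",
              "donor_candidate", "other"))
}

mk_hit <- function(q, s, species, pident, qstart, qend, bitscore,
                   evalue = 1e-30) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = 100L,
             mismatch = 0L, gapopen = 0L, qstart = qstart, qend = qend,
             sstart = 1L, send = 100L, evalue = evalue,
             bitscore = bitscore, subject_species = species,
             stringsAsFactors = FALSE)
}

test_that("a clean donor-top-hit contig passes all four stages", {
  hits <- mk_hit("c1", "Med1", "Medicago", 80, 100, 459, 200)
  rep <- apply_screen_cascade(hits, c(c1 = 600L), screen_map())
  expect_true(rep$per_contig$candidate)
  expect_equal(unname(rep$funnel),
               c(1L, 1L, 1L, 1L))
})

test_that("stage rules reject on each documented bound", {
  map <- screen_map()
  # identity above 95 fails stage 2
  h <- mk_hit("c1", "Med1", "Medicago", 97, 1, 500, 300)
  r <- apply_screen_cascade(h, c(c1 = 600L), map)
  expect_true(r$per_contig$stage1)
  expect_false(r$per_contig$stage2)
  expect_match(r$per_contig$reason, "identity")

  # identity below 60 fails too; bounds are inclusive
  h$pident <- 59.9
  expect_false(apply_screen_cascade(h, c(c1 = 600L), map)$per_contig$stage2)
  h$pident <- 60
  expect_true(apply_screen_cascade(h, c(c1 = 600L), map)$per_contig$stage2)
  h$pident <- 95
  expect_true(apply_screen_cascade(h, c(c1 = 600L), map)$per_contig$stage2)

  # contig length must exceed 500 strictly
  expect_false(apply_screen_cascade(h, c(c1 = 500L), map)$per_contig$stage2)

  # aligned span must reach half the contig
  short_span <- mk_hit("c1", "Med1", "Medicago", 80, 1, 250, 300)
  expect_false(apply_screen_cascade(short_span, c(c1 = 600L),
                                    map)$per_contig$stage2)

  # a close relative at rank 7 fails stage 3
  hits <- do.call(rbind, c(
    list(mk_hit("c1", "Med_top", "Medicago", 80, 100, 459, 300)),
    lapply(1:5, function(i) mk_hit("c1", paste0("Vit", i), "Vitis",
                                   70, 100, 459, 250 - i)),
    list(mk_hit("c1", "Mim1", "Mimulus", 65, 100, 459, 230)),
    list(mk_hit("c1", "Med_low", "Medicago", 64, 100, 459, 220))))
  r3 <- apply_screen_cascade(hits, c(c1 = 600L), map)
  expect_true(r3$per_contig$stage2)
  expect_false(r3$per_contig$stage3)

  # stage 4: rescued when the donor bit score dominates the close
  # relative's by the ratio threshold, not otherwise
  far <- rbind(mk_hit("c1", "Med1", "Medicago", 80, 100, 459, 300),
               mk_hit("c1", "Mim1", "Mimulus", 55, 100, 459, 100))
  r4 <- apply_screen_cascade(far, c(c1 = 600L), map,
                             screen_thresholds(top_n_close_check = 1L))
  expect_true(r4$per_contig$stage4)
  expect_true(r4$per_contig$rescued)
  near <- rbind(mk_hit("c1", "Med1", "Medicago", 80, 100, 459, 300),
                mk_hit("c1", "Mim1", "Mimulus", 75, 100, 459, 290))
  r4b <- apply_screen_cascade(near, c(c1 = 600L), map,
                              screen_thresholds(top_n_close_check = 1L))
  expect_false(r4b$per_contig$stage4)

  # no hits at all
  r0 <- apply_screen_cascade(near[0, ], c(c1 = 600L), map)
  expect_false(r0$per_contig$stage1)
  expect_equal(r0$per_contig$reason, "no hits")

  # unknown species is an error naming it
  bad <- mk_hit("c1", "x", "Martian", 80, 1, 500, 300)
  expect_error(apply_screen_cascade(bad, c(c1 = 600L), map), "Martian")
})

test_that("the funnel is monotone and the cascade is order-invariant", {
  fx <- small_fixture()
  sc <- run_screen(fx$contigs, fx$references, fx$taxon_map)
  f <- sc$report$funnel
  expect_true(all(diff(f) <= 0))

  # permuting contig order permutes but never changes per-contig outcomes
  perm <- sample(nrow(fx$contigs))
  sc2 <- run_screen(fx$contigs[perm, ], fx$references, fx$taxon_map)
  a <- sc$report$per_contig; b <- sc2$report$per_contig
  b <- b[match(a$contig, b$contig), ]
  expect_equal(a$candidate, b$candidate)
  expect_equal(a$stage3, b$stage3)
  expect_equal(sort(sc$report$candidates), sort(sc2$report$candidates))
})

test_that("the cascade recovers exactly the planted xenologs on the small fixture", {
  fx <- small_fixture()
  sc <- run_screen(fx$contigs, fx$references, fx$taxon_map)
  expect_setequal(sc$report$candidates,
                  fx$truth$contig[fx$truth$is_xenolog])
})

test_that("imported outfmt-6 tables give the same cascade outcome", {
  fx <- small_fixture()
  sc <- run_screen(fx$contigs, fx$references, fx$taxon_map)
  f <- withr::local_tempfile()
  write_hit_table(sc$hits, f)
  back <- read_hit_table(f)
  lens <- setNames(nchar(fx$contigs$residues), fx$contigs$id)
  spmap <- setNames(fx$references$species, fx$references$id)
  rep2 <- apply_screen_cascade(back, lens, fx$taxon_map,
                               subject_species = spmap)
  expect_equal(rep2$per_contig$candidate,
               sc$report$per_contig$candidate)
  expect_equal(rep2$funnel, sc$report$funnel)
})

test_that("an empty contig set yields an all-zero funnel", {
  fx <- small_fixture()
  rep <- apply_screen_cascade(hgtrace:::empty_search_result(),
                              setNames(integer(0), character(0)),
                              fx$taxon_map)
  expect_equal(unname(rep$funnel), rep(0L, 4))
  expect_length(rep$candidates, 0L)
})
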