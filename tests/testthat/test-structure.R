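test_that("ORF finding picks the longest ATG-initiated frame", {
  orf <- find_orf("ATGAAATAA", min_codons = 2L)
  expect_equal(orf$cds, "ATGAAATAA")
  expect_equal(orf$frame, 1L)

  # two ORFs: the longer one wins regardless of order
  set.seed(51)
  mk <- function(n) paste0("ATG", random_cds(n - 2, exclude_aa = "M"), "TAA")
  seqs <- paste0(random_nt(7), mk(40), random_nt(11), mk(60), random_nt(5))
  orf2 <- find_orf(seqs, min_codons = 10L)
  expect_equal(nchar(orf2$cds), 60 * 3)

  expect_error(find_orf(strrep("N", 120)), "no open reading frame")
  expect_error(find_orf("ACGTA"), "short")
})

test_that("intron inference inverts the generator exactly", {
  set.seed(52)
  for (i in 1:50) {
    cds <- random_cds(sample(40:120, 1))
    ilen <- sample(4:200, 1)
    g <- make_genomic_with_intron(cds, ilen)
    st <- infer_intron(g$genomic, cds)
    expect_equal(st$intron, g$structure$intron, info = i)
    expect_equal(st$phase, g$structure$phase)
    expect_equal(st$donor, "GT"); expect_equal(st$acceptor, "AG")
  }
})

test_that("shift-ambiguous introns resolve to the canonical GT..AG solution", {
  # genomic = "AT" + "GTCCAG" + "GAAA": splitting after "ATG" gives the
  # non-canonical intron "TCCAGG"; the canonical solution is after "AT"
  cds <- "ATGAAA"
  genomic <- "ATGTCCAGGAAA"
  st <- infer_intron(genomic, cds)
  expect_equal(st$intron, c(2L, 8L))
  expect_equal(st$donor, "GT"); expect_equal(st$acceptor, "AG")

  expect_error(infer_intron("ATGCCCAAATTT", "GGGGGG"), "not single-intron")
  expect_error(infer_intron("ATGAAA", "ATGAAA"), "not single-intron")
})

test_that("splice-site flags report canonical dinucleotides", {
  g <- make_genomic_with_intron("ATGCCAAAG", 6L, insert_after = 3L)
  fl <- check_splice_sites(g$structure, g$genomic)
  expect_true(fl$donor_canonical && fl$acceptor_canonical)

  noncan <- sub("^ATGGT", "ATGCT", g$genomic)
  fl2 <- check_splice_sites(g$structure, noncan)
  expect_false(fl2$donor_canonical)
  expect_true(fl2$acceptor_canonical)
})

test_that("intron conservation compares homologous insertion points", {
  cds <- random_cds(50)
  ga <- make_genomic_with_intron(cds, 30L, insert_after = 60L, seed = 5)
  # same intron, same position in a second gene
  gb <- list(genomic = ga$genomic, structure = ga$structure)
  aln <- c(a = cds, b = cds)
  res <- intron_conservation(ga$structure, ga$genomic,
                             gb$structure, gb$genomic, aln, "a", "b")
  expect_true(res$same_start)
  expect_equal(res$shared_prefix_len, 30L)

  # introns differing from base 4 onward share a 3 nt prefix
  ib <- paste0(substr(ga$genomic, 61, 63),
               chartr("ACGT", "GTAC", substr(ga$genomic, 64, 90)))
  gb2_genomic <- paste0(substr(cds, 1, 60), ib, substr(cds, 61, 150))
  res2 <- intron_conservation(ga$structure, ga$genomic,
                              ga$structure, gb2_genomic, aln, "a", "b")
  expect_equal(res2$shared_prefix_len, 3L)

  # different codon positions are not the same start
  gc <- make_genomic_with_intron(cds, 30L, insert_after = 61L, seed = 6)
  res3 <- intron_conservation(ga$structure, ga$genomic,
                              gc$structure, gc$genomic, aln, "a", "b")
  expect_false(res3$same_start)

  expect_error(intron_conservation(ga$structure, ga$genomic, gc$structure,
                                   gc$genomic, aln, "a", "zz"), "zz")
})

test_that("GFF3 output converts to 1-based inclusive coordinates", {
  g <- make_genomic_with_intron("ATGAAATGA", 6L, insert_after = 3L)
  f <- withr::local_tempfile()
  write_gff3(list(g$structure), "chr1", f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  fields <- strsplit(lines[-1], "\t")
  expect_equal(vapply(fields, `[`, "", 4), c("1", "10", "4"))   # starts
  expect_equal(vapply(fields, `[`, "", 5), c("3", "15", "9"))   # ends
})

test_that("identity and similarity are computed over ungapped columns", {
  res <- alignment_identity_similarity("MKVI", "MKVI")
  expect_equal(res$percent_identity, 100)
  expect_equal(res$percent_similarity, 100)

  # 10 ungapped columns, one I<->V difference (BLOSUM62 +3)
  res2 <- alignment_identity_similarity("MKAAAAAAQI", "MKAAAAAAQV")
  expect_equal(res2$percent_identity, 90)
  expect_equal(res2$percent_similarity, 100)

  # gapped columns are excluded from the denominator
  res3 <- alignment_identity_similarity("MK-I", "MKV-")
  expect_equal(res3$n_ungapped, 2L)
  expect_error(alignment_identity_similarity("--", "AA"), "ungapped")

  set.seed(53)
  for (i in 1:10) {
    a <- random_peptide(30); b <- random_peptide(30)
    r <- alignment_identity_similarity(a, b)
    expect_lte(r$percent_identity, r$percent_similarity)
    expect_lte(r$percent_similarity, 100)
  }
})

test_that("the scaffold scorer accepts profiled knottins and rejects perturbations", {
  profile <- scaffold_profile()
  recs <- read_fasta(system.file("extdata", "albumin1_knottin_synthetic.fasta",
                                 package = "hgtrace"))
  for (p in recs$residues) {
    expect_true(cysteine_scaffold_score(p, profile)$pass, info = p)
  }

  # one cysteine -> serine: count subscore collapses, score fails
  p1 <- sub("C", "S", recs$residues[1])
  s1 <- cysteine_scaffold_score(p1, profile)
  expect_equal(unname(s1$subscores["count"]), 0)
  expect_false(s1$pass)

  # conservative non-cysteine substitutions keep the score
  p2 <- chartr("ILV", "VIL", recs$residues[1])
  expect_equal(cysteine_scaffold_score(p2, profile)$total,
               cysteine_scaffold_score(recs$residues[1], profile)$total)

  expect_error(cysteine_scaffold_score("CCC", profile), "30")
})
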