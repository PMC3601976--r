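#!/usr/bin/env Rscript
# Gene-structure validation: genomic (introned) copies of the xenologs,
# intron inference and splice motifs, cross-species intron conservation
# with the recipient donor, protein identity/similarity, and the
# cysteine-scaffold (KNOTTIN) score.

library(hgtrace)

cfg <- default_config(seed = 1)
res <- run_pipeline(cfg, stages = c("simulate", "structure"),
                    out_dir = "results/pipeline")

st <- res$structure
for (id in names(st$structures)) {
  s <- st$structures[[id]]
  cat(sprintf("%-14s intron [%d, %d) phase %d  %s..%s\n", id,
              s$intron[1], s$intron[2], s$phase, s$donor, s$acceptor))
}
cat(sprintf("intron position conserved with the donor copy: %s; shared 5' prefix %d nt\n",
            st$conservation$same_start, st$conservation$shared_prefix_len))
cat(sprintf("protein identity %.1f%%, similarity %.1f%% (ungapped columns)\n",
            st$identity_similarity$percent_identity,
            st$identity_similarity$percent_similarity))
for (id in names(st$scaffold)) {
  sc <- st$scaffold[[id]]
  cat(sprintf("%-14s scaffold score %.0f (threshold %.0f): %s\n", id,
              sc$total, sc$threshold, if (sc$pass) "PASS" else "fail"))
}
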