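#!/usr/bin/env Rscript
# Evolutionary-constraint analysis of the xenolog family: parsimony
# branch counts pooled by lineage, pairwise NG86 dN/dS against the
# recipient donor, and the per-site constraint scan flagging cysteines.

library(hgtrace)

cfg <- default_config(seed = 1)
res <- run_pipeline(cfg, stages = c("simulate", "selection"),
                    out_dir = "results/pipeline")

s <- res$selection
cat("pooled lineage counts (dS:dN is the opportunity-corrected ratio):\n")
print(s$pooled, digits = 3)
cat("\npairwise NG86, parasite copy vs recipient donor:\n")
print(s$pairwise)
scan <- s$site_scan
cys <- scan[scan$is_cysteine, ]
cat(sprintf("\ncysteine columns flagged: %d; nonsynonymous changes on them: %g\n",
            nrow(cys), sum(cys$obs_N)))
cat(sprintf("their constraint scores sit at or above the %.0fth percentile\n",
            100 * mean(scan$score <= min(cys$score))))
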