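#!/usr/bin/env Rscript
# Stage 6: over-representation analysis of the network mRNAs.
#
# The mRNAs of the assembled triplets are tested against the synthetic
# annotation gene sets (hypergeometric, BH-corrected, fold enrichment
# = (k/n)/(K/N)). The first annotation set contains all circuit mRNAs by
# construction, so it should surface as the top term.

library(cernet)

run_pipeline(pipeline_config(out_dir = "results/run",
                             sim = simulation_config(lfc_de = 2, seed = 20260930),
                             steps = "enrich"))

res <- read.delim("results/run/enrichment.tsv")
message("top terms:")
print(head(res[, c("term_id", "k", "n", "K", "N", "fold_enrichment",
                   "p_value", "q_value")], 5))
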