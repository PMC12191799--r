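#!/usr/bin/env Rscript
# Stage 4 — function-level view of the significant genes: hypergeometric
# over-representation against the GMT collection, conservative
# deduplication, >4x majority labeling, and Jaccard/average-linkage
# clustering of the enriched functions.

library(ratiosurv)

out <- "results/analysis"
records <- read.delim(file.path(out, "screen.tsv"), stringsAsFactors = FALSE)
sets <- read_gmt(file.path(out, "gene_sets.gmt"))

enriched <- enrich_functions(records, sets, alpha = 0.05)
enriched <- dedup_functions(enriched)
if (nrow(enriched) >= 2L) {
  enriched <- cluster_functions(enriched, k = min(20L, nrow(enriched)))
} else if (nrow(enriched) > 0L) {
  enriched$cluster_id <- 1L
}
write_enrichment_tsv(enriched, file.path(out, "enriched.tsv"))

message(sprintf("found: %d enriched function(s) at BH alpha = 0.05", nrow(enriched)))
if (nrow(enriched) > 0L) {
  print(enriched[, c(
    "function_id", "p_adjusted", "fold_enrichment",
    "n_opcml_plus", "n_genei_plus", "majority_class"
  )])
}
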