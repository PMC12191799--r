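#!/usr/bin/env Rscript
# Stage 5 — literature-relevance triage. Each enriched function gets an
# OVca score (geometric mean of its member genes' citation counts); within
# any cluster of more than four functions only the top four by OVca are
# kept, and the survivors are ranked. Citation counts here are the
# synthetic fixture table from stage 1 — offline stand-ins, not real
# PubMed counts.

library(ratiosurv)

out <- "results/analysis"
enriched_flat <- read.delim(file.path(out, "enriched.tsv"),
  stringsAsFactors = FALSE
)
if (nrow(enriched_flat) == 0L) {
  message("no enriched functions to triage")
  quit(save = "no", status = 0)
}
enriched_flat$member_hits <- I(strsplit(enriched_flat$member_hits, ","))

citations <- read.delim(file.path(out, "citations.tsv"),
  stringsAsFactors = FALSE
)
counts <- fetch_counts(
  unique(unlist(enriched_flat$member_hits)),
  citation_client_fixture(citations)
)

ranked <- triage(enriched_flat, counts, top_n = 30L)
write_enrichment_tsv(ranked, file.path(out, "triage.tsv"))

message(sprintf("found: %d function(s) retained after the cluster cap", nrow(ranked)))
print(ranked[, c("function_id", "p_adjusted", "ovca_score", "majority_class")])
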