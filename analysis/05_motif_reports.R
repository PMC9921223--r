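#!/usr/bin/env Rscript
# Step 5: motif reports for the significant findings.
#
# For each motif flagged in Q1, emits the figure-ready tables: top
# regions by within-motif node strength, the signed strongest-connection
# edge list (chord-plot input), and the prevalence/performance pairs for
# the regression panel.

suppressPackageStartupMessages(library(connectomotif))

cohort <- load_cohort("data/manifest.yaml")
behavior <- read_behavior("data/behavior.tsv")
q1 <- run_q1(cohort, behavior)

sig <- q1$results$motif[q1$results$significant]
if (length(sig) == 0) {
  cat("no significant Q1 motifs to report\n")
} else {
  for (k in sig) {
    rep_k <- report_motif(q1$decomposition, k, q1$behavior_vec)
    stem <- file.path("results", sprintf("motif%02d", k))
    write.table(rep_k$top_regions, paste0(stem, "_top_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rep_k$top_connections, paste0(stem, "_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rep_k$regression_pairs, paste0(stem, "_regression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    print(rep_k)
  }
}
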