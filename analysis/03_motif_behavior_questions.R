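#!/usr/bin/env Rscript
# Step 3: the motif-behavior hypotheses Q1-Q3.
#
#   Q1: do scan-a motif prevalences predict day-1 performance?
#   Q2: do they predict the day-4-minus-day-1 training gain?
#   Q3: does the scan-b-minus-a prevalence change track the gain?
#
# Spearman per motif, Bonferroni over the motif family (28 for Q1/Q2,
# 56 for Q3). Writes one result table per question under results/.

suppressPackageStartupMessages(library(connectomotif))

cohort <- load_cohort("data/manifest.yaml")
behavior <- read_behavior("data/behavior.tsv", "data/spans.tsv")

q1 <- run_q1(cohort, behavior)
q2 <- run_q2(cohort, behavior)
q3 <- run_q3(cohort, behavior)
for (q in list(q1, q2, q3)) write_question(q, "results")

summarize <- function(q) {
  sig <- q$results[q$results$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    cat(sprintf("%s: no motif significant after Bonferroni (family %d)\n",
                q$question, q$results$family_size[1]))
  } else {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf(
        "%s: motif %d significant (rho = %.3f, corrected p = %.4f)\n",
        q$question, sig$motif[i], sig$rho[i], sig$p_corrected[i]))
    }
  }
}
summarize(q1); summarize(q2); summarize(q3)

# span-score side analysis under the same family correction
sc <- run_span_correlations(q1$decomposition, behavior)
write.table(sc, "results/span_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("span correlations: %d significant of %d tests\n",
            sum(sc$significant), nrow(sc)))
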