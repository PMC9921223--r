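#!/usr/bin/env Rscript
# Step 4: Q4, the group-level edgewise change analysis.
#
# One Mann-Whitney U test per connection comparing scans b vs. a and
# c vs. a across subjects, Bonferroni-corrected for the ~17,000
# connections. With the generator's null group-level structure (the
# plasticity signal is subject-specific with zero mean), no connection
# is expected to survive correction.

suppressPackageStartupMessages(library(connectomotif))

cohort <- load_cohort("data/manifest.yaml")
q4 <- run_q4(cohort)
write_question(q4, "results")

for (cmp in intersect(c("b_vs_a", "c_vs_a"), names(q4))) {
  r <- q4[[cmp]]
  cat(sprintf("%s: %d of %d connections significant after Bonferroni\n",
              cmp, nrow(r$significant), r$family_size))
}
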