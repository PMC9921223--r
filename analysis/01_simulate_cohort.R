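#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Generates a synthetic 28-subject cohort on the 185-region parcellation
# (scans a = pre-training, b = post-training, c = 3-week follow-up) with
# two planted network motifs: motif 1's baseline weight drives day-1
# double-embedding performance (latent rho 0.7), motif 2's scan-b-minus-a
# weight change drives the training gain. Writes the cohort, behavioral
# table and manifest under data/.

suppressPackageStartupMessages(library(connectomotif))

seed <- 20260923L
params <- simulation_params(seed = seed)
g <- generate_cohort(params)

manifest <- write_cohort_with_behavior(g$cohort, g$behavior, "data")

cat(sprintf("cohort: %d subjects x scans {%s}, %d regions\n",
            length(g$cohort$subjects),
            paste(g$cohort$scans, collapse = ", "),
            length(g$cohort$parcellation$labels)))
cat(sprintf("manifest: %s\n", manifest))
perf <- performance_vector(g$behavior, g$cohort$subjects, day = 1)
cat(sprintf("day-1 double-embedding performance: %.0f%%..%.0f%% (median %.0f%%)\n",
            100 * min(perf), 100 * max(perf), 100 * median(perf)))
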