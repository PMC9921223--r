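# Small fixtures built in code. Study-scale geometry (185 regions,
# 28 subjects) is reserved for the acceptance suite; unit tests use small
# cohorts so each file runs in seconds.

small_params <- function(..., seed = 1L) {
  simulation_params(n_subjects = 8L, n_regions = 15L, seed = seed, ...)
}

small_cohort <- function(..., seed = 1L) {
  generate_cohort(small_params(..., seed = seed))
}

# a deterministic integer connectivity matrix with labels
toy_matrix <- function(d = 4L, subject = "S01", scan = "a", seed = 99L) {
  set.seed(seed)
  vals <- matrix(sample.int(50L, d * d, replace = TRUE), d, d)
  diag(vals) <- 0
  labels <- LETTERS[seq_len(d)]
  dimnames(vals) <- list(labels, labels)
  connectivity_matrix(vals, subject, scan, "left")
}

# clone one scan's matrices into another scan id (for identical-scan cases)
clone_scan <- function(cohort, from = "a", to = "b") {
  mats <- list()
  for (s in cohort$subjects) {
    m <- cohort_matrix(cohort, s, from)
    mats[[length(mats) + 1L]] <- m
    m2 <- m
    m2$scan <- to
    mats[[length(mats) + 1L]] <- m2
  }
  connectome_cohort(cohort$parcellation, mats,
                    subjects = cohort$subjects, scans = c(from, to))
}
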