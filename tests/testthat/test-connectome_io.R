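test_that("matrix write/load round-trips bit-identically for integer counts", {
  m <- toy_matrix(5L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, path)
  m2 <- load_matrix(path, m$subject, m$scan, m$hemisphere)
  expect_identical(m2$values, m$values)
  expect_identical(rownames(m2$values), LETTERS[1:5])

  # tab-delimited dialect is auto-detected
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path2, sep = "\t")
  expect_identical(load_matrix(path2, "x", "a")$values, m$values)
})

test_that("loader zeroes the diagonal and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("region,A,B", "A,7,2", "B,3,7"), path)
  m <- load_matrix(path, "s", "a")
  expect_equal(diag(m$values), c(A = 0, B = 0))
  expect_equal(m$values["A", "B"], 2)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("region,A,B,C", "A,0,1,2", "B,3,0,4"), bad)
  expect_error(load_matrix(bad, "s", "a"), "square")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("region,A,B", "A,0,-1", "B,3,0"), neg)
  expect_error(load_matrix(neg, "s", "a"), "nonnegative")

  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("region,A,B", "A,0,1", "B,3,0"), ok)
  parc <- parcellation(c("X", "Y"), "left")
  expect_error(load_matrix(ok, "s", "a", parcellation = parc),
               "parcellation")
})

test_that("all-zero rows are accepted (target-only callosal parcels)", {
  vals <- matrix(c(0, 5, 0, 3, 0, 0, 0, 0, 0), 3, byrow = TRUE,
                 dimnames = list(c("P1", "P2", "CC_1"),
                                 c("P1", "P2", "CC_1")))
  expect_silent(m <- connectivity_matrix(vals, "s", "a", "left"))
  expect_equal(unname(m$values["CC_1", ]), c(0, 0, 0))
})

test_that("vectorize emits the documented orders in both modes", {
  C <- matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(as.numeric(vectorize(C, "full")), c(1, 2, 3, 4, 5, 6))
  expect_equal(as.numeric(vectorize(C, "symmetric")), c(2, 3.5, 5))
  im <- attr(vectorize(C, "symmetric"), "index_map")
  expect_equal(im$source, c("A", "A", "B"))
  expect_equal(im$target, c("B", "C", "C"))
})

test_that("feature dimensions follow D(D-1)/2 and D(D-1)", {
  # combinatorial oracle at the 185-region study parcellation
  expect_equal(nrow(feature_index_map(sprintf("r%d", 1:185), "symmetric")),
               185 * 184 / 2)  # 17020
  expect_equal(nrow(feature_index_map(sprintf("r%d", 1:185), "full")),
               185 * 184)      # 34040
})

test_that("symmetric vectorization is invariant under transposition", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- sample(3:8, 1)
    C <- matrix(rpois(d * d, 20), d, d)
    dimnames(C) <- list(letters[1:d], letters[1:d])
    expect_equal(as.numeric(vectorize(C, "symmetric")),
                 as.numeric(vectorize(t(C), "symmetric")))
  }
})

test_that("unvectorize inverts vectorize", {
  C <- toy_matrix(6L)$values
  v <- vectorize(C, "symmetric")
  W <- unvectorize(v)
  expect_equal(W, (C + t(C)) / 2)
  vf <- vectorize(C, "full")
  expect_equal(unvectorize(vf), C)
})

test_that("stacking is scan-major with one column per (subject, scan)", {
  g <- small_cohort()
  st <- stack_cohort(g$cohort, scans = c("a", "b"))
  n <- length(g$cohort$subjects)
  expect_equal(ncol(st$M), 2L * n)
  expect_equal(st$column_index$scan, rep(c("a", "b"), each = n))
  expect_equal(st$column_index$subject,
               rep(g$cohort$subjects, times = 2L))
  # a single (subject, scan) stacks to exactly its feature vector
  st1 <- stack_cohort(g$cohort, scans = "a",
                      subjects = g$cohort$subjects[1L])
  m1 <- cohort_matrix(g$cohort, g$cohort$subjects[1L], "a")
  expect_equal(st1$M[, 1L], as.numeric(vectorize(m1, "symmetric")))
  expect_error(stack_cohort(g$cohort, scans = character(0)), "empty")
  expect_error(stack_cohort(g$cohort, scans = "z"), "unknown scan")
})

test_that("cohort manifest write/load round-trips the whole cohort", {
  g <- small_cohort(scans = c("a", "b"))
  dir <- withr::local_tempdir()
  manifest <- write_cohort_with_behavior(g$cohort, g$behavior, dir)
  c2 <- load_cohort(manifest)
  expect_equal(c2$subjects, g$cohort$subjects)
  expect_equal(c2$scans, g$cohort$scans)
  expect_equal(c2$parcellation$labels, g$cohort$parcellation$labels)
  for (key in names(g$cohort$matrices)) {
    expect_identical(c2$matrices[[key]]$values,
                     g$cohort$matrices[[key]]$values)
  }
  b2 <- read_behavior(file.path(dir, "behavior.tsv"),
                      file.path(dir, "spans.tsv"))
  expect_equal(b2$records, g$behavior$records)
  # manifest lists n_subjects x n_scans matrix files
  mf <- yaml::read_yaml(manifest)
  expect_length(mf$matrices, length(g$cohort$subjects) * 2L)
})
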