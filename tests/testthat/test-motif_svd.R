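test_that("a single column decomposes into itself, normalized", {
  set.seed(1)
  m <- abs(rnorm(12)) + 0.1
  dec <- decompose(matrix(m, ncol = 1))
  expect_equal(n_motifs(dec), 1L)
  expect_equal(dec$singular_values, sqrt(sum(m^2)))
  expect_equal(dec$motifs[, 1], m / sqrt(sum(m^2)))
  expect_equal(as.numeric(dec$weights), 1)
  expect_equal(dec$explained_variance, 1)
})

test_that("motifs are orthonormal and reconstruct M at the retained rank", {
  for (seed in 1:5) {
    set.seed(seed)
    M <- matrix(rnorm(60 * 7), 60, 7)
    dec <- decompose(M)
    G <- crossprod(dec$motifs)
    expect_lt(max(abs(G - diag(n_motifs(dec)))), 1e-10)
    expect_lt(reconstruction_error(dec, M), 1e-10)
    expect_equal(sum(dec$explained_variance), 1, tolerance = 1e-12)
    expect_false(is.unsorted(rev(dec$singular_values)))
  }
})

test_that("singular values match an independent eigen-oracle", {
  # sqrt of eigenvalues of t(M) %*% M, an independent route to sigma
  for (seed in 1:10) {
    set.seed(seed)
    nr <- sample(4:10, 1)
    nc <- sample(2:nr, 1)
    M <- matrix(rnorm(nr * nc), nr, nc)
    dec <- decompose(M)
    ev <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
    oracle <- sqrt(pmax(ev, 0))
    expect_equal(dec$singular_values,
                 oracle[seq_len(n_motifs(dec))], tolerance = 1e-8)
  }
})

test_that("motif count equals the numerical rank of M", {
  set.seed(2)
  M <- matrix(rnorm(40 * 6), 40, 6)  # generic: full column rank
  expect_equal(n_motifs(decompose(M)), 6L)
  # a duplicated column adds no motif
  expect_equal(n_motifs(decompose(cbind(M, M[, 1]))), 6L)
  # all-zero input is a rank-0 decomposition, not an error
  dec0 <- decompose(matrix(0, 10, 3))
  expect_equal(n_motifs(dec0), 0L)
  expect_error(decompose(matrix(numeric(0), 5, 0)), "no columns")
})

test_that("explained variance follows sigma^2 / sum(sigma^2)", {
  expect_equal(explained_variance(c(2, 1)), c(0.8, 0.2))
  expect_equal(explained_variance(5), 1.0)
  expect_equal(explained_variance(c(3, 0)), c(1.0, 0.0))
  expect_error(explained_variance(c(0, 0)), "all-zero")
  expect_error(explained_variance(c(2, -1)), "nonnegative")
})

test_that("prevalence weights scale with rank-1 column magnitudes", {
  set.seed(3)
  u <- rnorm(20)
  cs <- c(1, 2, 3, 5)
  M <- outer(u, cs)
  ci <- data.frame(column = 1:4, subject = sprintf("S%d", 1:4), scan = "a")
  dec <- decompose(M, column_index = ci)
  expect_equal(n_motifs(dec), 1L)
  w <- sapply(sprintf("S%d", 1:4), function(s) prevalence(dec, 1, s, "a"))
  # proportional to the column scalars, up to one global sign
  expect_equal(unname(abs(w / w[1])), cs / cs[1])
  expect_equal(length(unique(sign(w / cs))), 1L)
  expect_error(prevalence(dec, 1, "S9", "a"), "no column")
  expect_error(prevalence(dec, 5, "S1", "a"), "out of range")
})

test_that("prevalence change isolates a planted per-column shift", {
  set.seed(4)
  n <- 6L
  A <- matrix(rnorm(50 * n), 50, n)
  sa <- svd(A)
  u <- sa$u[, 1]
  delta <- 3 * sa$v[, 1]  # shift along v1 keeps u1 a motif of the stack
  B <- A + outer(u, delta)
  subjects <- sprintf("S%d", 1:n)
  ci <- data.frame(column = 1:(2 * n),
                   subject = rep(subjects, 2),
                   scan = rep(c("a", "b"), each = n))
  dec <- decompose(cbind(A, B), column_index = ci)
  k1 <- match_motif(dec, u)$motif
  sgn <- sign(sum(dec$motifs[, k1] * u))
  for (s in seq_len(n)) {
    for (k in seq_len(n_motifs(dec))) {
      ch <- prevalence_change(dec, k, subjects[s])
      if (k == k1) {
        expect_equal(ch, sgn * delta[s] / dec$singular_values[k1],
                     tolerance = 1e-8)
      } else {
        expect_lt(abs(ch), 1e-8)
      }
    }
  }
  # identical scans: every change is exactly zero
  dec2 <- decompose(cbind(A, A), column_index = ci)
  for (k in seq_len(n_motifs(dec2))) {
    expect_equal(prevalence_change(dec2, k, subjects[1]), 0)
  }
})

test_that("the sign convention makes the decomposition deterministic", {
  set.seed(5)
  M <- matrix(rnorm(30 * 5), 30, 5)
  d1 <- decompose(M)
  d2 <- decompose(M)
  expect_identical(d1$motifs, d2$motifs)
  expect_identical(d1$weights, d2$weights)
  for (k in seq_len(n_motifs(d1))) {
    expect_gt(d1$motifs[which.max(abs(d1$motifs[, k])), k], 0)
  }
  # a joint (motif, weight-row) sign flip leaves the reconstruction intact
  expect_lt(reconstruction_error(d1, M), 1e-10)
})

test_that("motif_as_matrix mirrors features back to region space", {
  labels <- c("A", "B", "C")
  im <- feature_index_map(labels, "symmetric")
  v <- c(0.7, 0, sqrt(1 - 0.49))
  dec <- structure(list(motifs = matrix(v, ncol = 1), singular_values = 1,
                        weights = matrix(1, 1, 1),
                        explained_variance = 1,
                        column_index = NULL, index_map = im,
                        mode = "symmetric", centered = FALSE),
                   class = "motif_decomposition")
  W <- motif_as_matrix(dec, 1)
  expect_equal(W["A", "B"], 0.7)
  expect_equal(W["B", "A"], 0.7)
  expect_equal(diag(W), c(A = 0, B = 0, C = 0))
  # unit-norm feature vector mirrors to squared sum 2 in symmetric mode
  expect_equal(sum(W^2), 2)
  expect_error(motif_as_matrix(dec, 3), "out of range")
})

test_that("rank-1 single-column decomposition recovers the symmetrized input", {
  m <- toy_matrix(5L, seed = 11)
  st <- stack_cohort(
    connectome_cohort(parcellation(LETTERS[1:5], "left"), list(m)),
    scans = "a")
  dec <- decompose(st)
  W <- motif_as_matrix(dec, 1)
  S <- (m$values + t(m$values)) / 2
  expect_equal(W * dec$singular_values[1] * dec$weights[1, 1], S)
})

test_that("zero-noise planted cohorts are recovered up to subspace rotation", {
  g <- small_cohort(noise_sd = 0, round_counts = FALSE, seed = 6)
  st <- stack_cohort(g$cohort, scans = "a")
  dec <- decompose(st)
  # columns live in span(base, motif_1, motif_2): rank 3
  expect_equal(n_motifs(dec), 3L)
  truth_basis <- qr.Q(qr(cbind(g$truth$base, g$truth$motifs)))
  principal_cos <- svd(crossprod(dec$motifs, truth_basis))$d
  expect_true(all(abs(principal_cos - 1) < 1e-8))
})

test_that("single planted motif with weights 1,2,3 gives rank 2 (base + motif)", {
  p <- simulation_params(n_subjects = 3L, n_regions = 12L,
                         scans = "a", n_planted_motifs = 1L,
                         behavior_coupling = list(motif = 1L, rho = 0.7),
                         plasticity_coupling = list(motif = 1L, rho = 0),
                         noise_sd = 0, round_counts = FALSE, seed = 7)
  g <- generate_cohort(p, weights_a = matrix(c(1, 2, 3), 3, 1))
  dec <- decompose(stack_cohort(g$cohort, scans = "a"))
  expect_equal(n_motifs(dec), 2L)
})
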