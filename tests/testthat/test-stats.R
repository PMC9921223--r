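test_that("spearman rho matches the rank-difference formula", {
  expect_equal(spearman(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman(1:3, c(6, 5, 4))$rho, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  # no-ties oracle: rho = 1 - 6 sum(d^2) / (n (n^2 - 1))
  d2 <- sum((rank(x) - rank(y))^2)
  expect_equal(spearman(x, y)$rho, 1 - 6 * d2 / (5 * 24))
  expect_equal(spearman(x, y)$rho, 0.8)
})

test_that("exact small-n spearman p agrees with an independent implementation", {
  cases <- list(
    list(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5)),
    list(x = c(3, 1, 4, 1.5, 5, 9), y = c(2, 7, 1, 8, 2.5, 8.1)),
    list(x = 1:7, y = c(2, 4, 1, 7, 6, 3, 5)))
  for (cs in cases) {
    sp <- spearman(cs$x, cs$y)
    expect_equal(sp$method, "exact enumeration")
    ct <- suppressWarnings(
      stats::cor.test(cs$x, cs$y, method = "spearman", exact = TRUE))
    expect_equal(sp$rho, unname(ct$estimate))
    expect_equal(sp$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("large-n spearman p uses the t approximation", {
  set.seed(10)
  x <- rnorm(28); y <- 0.5 * x + rnorm(28)
  sp <- spearman(x, y)
  expect_equal(sp$method, "t approximation")
  rho <- sp$rho
  tt <- rho * sqrt(26 / (1 - rho^2))
  expect_equal(sp$p, 2 * pt(-abs(tt), 26))
})

test_that("spearman respects its invariants and error contracts", {
  set.seed(11)
  x <- rnorm(15); y <- rnorm(15)
  base <- spearman(x, y)
  # invariant under strictly monotone transforms of either argument
  expect_equal(spearman(exp(x), y)$rho, base$rho)
  expect_equal(spearman(x, y^3 + 5 * y)$rho, base$rho)
  expect_equal(spearman(y, x)$rho, base$rho)
  expect_error(spearman(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(spearman(1:3, 1:4), "equal length")
  expect_error(spearman(1:2, 2:1), "n >= 3")
})

test_that("spearman type-I rate at alpha = 0.05 sits in the binomial band", {
  set.seed(12)
  n_sim <- 2000
  hits <- sum(replicate(n_sim, spearman(rnorm(20), rnorm(20))$p < 0.05))
  ci <- qbinom(c(0.0005, 0.9995), n_sim, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.001, 28), 0.028)
  expect_equal(bonferroni(0.01, 56), 0.56)
  expect_equal(bonferroni(0.05, 28), 1.0)
  expect_error(bonferroni(1.2, 4), "\\[0, 1\\]")
  expect_error(bonferroni(-0.1, 4), "\\[0, 1\\]")
  # monotone in both arguments, never above 1
  set.seed(13)
  p <- sort(runif(20))
  adj <- bonferroni(p, 7)
  expect_false(is.unsorted(adj))
  expect_true(all(adj <= 1))
  expect_true(all(bonferroni(p, 10) >= adj))
})

test_that("mann-whitney U and exact p match full enumeration", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney_u(c(2, 4, 6), c(1, 3, 5))$U + 0,
               mann_whitney_u(c(1, 3, 5), c(2, 4, 6))$U * -1 + 9)
  x <- c(1, 3); y <- c(2, 4)
  mw <- mann_whitney_u(x, y)
  expect_equal(mw$method, "exact")
  # enumeration oracle: all C(4,2) assignments of ranks to the x sample
  pooled <- c(x, y)
  r <- rank(pooled)
  obs_U <- sum(r[1:2]) - 3
  Us <- apply(combn(4, 2), 2, function(idx) sum(r[idx]) - 3)
  mu <- 2 * 2 / 2
  p_enum <- mean(abs(Us - mu) >= abs(obs_U - mu))
  expect_equal(mw$p, p_enum)
  expect_equal(mw$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("mann-whitney respects U_x + U_y = n1 n2 and tie handling", {
  set.seed(14)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(9)
    ux <- mann_whitney_u(x, y)$U
    uy <- mann_whitney_u(y, x)$U
    expect_equal(ux + uy, 54)
  }
  same <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney_u(same, same)$U, length(same)^2 / 2)
  # tied data takes the corrected normal approximation
  xt <- c(1, 1, 2, 3); yt <- c(2, 2, 3, 4)
  mwt <- mann_whitney_u(xt, yt)
  expect_equal(mwt$method, "normal approximation")
  wt <- stats::wilcox.test(xt, yt, exact = FALSE, correct = FALSE)
  expect_equal(mwt$p, wt$p.value)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("edgewise test flags exactly a strongly shifted connection", {
  g <- generate_cohort(simulation_params(
    n_subjects = 20L, n_regions = 10L, scans = c("a", "b"),
    n_planted_motifs = 1L,
    behavior_coupling = list(motif = 1L, rho = 0),
    plasticity_coupling = list(motif = 1L, rho = 0), seed = 21))
  cohort <- g$cohort
  # shift one connection in every subject's scan b by 10 pooled SDs
  st <- stack_cohort(cohort, scans = "a")
  pooled_sd <- max(sd(st$M[1, ]), 1)
  for (s in cohort$subjects) {
    key <- paste(s, "b", sep = ":")
    im <- st$index_map[1, ]
    cohort$matrices[[key]]$values[im$i, im$j] <-
      cohort$matrices[[key]]$values[im$i, im$j] + 10 * pooled_sd
    cohort$matrices[[key]]$values[im$j, im$i] <-
      cohort$matrices[[key]]$values[im$j, im$i] + 10 * pooled_sd
  }
  res <- connectionwise_group_test(cohort, "a", "b")
  expect_equal(res$family_size, 45L)
  flagged <- res$significant
  expect_true(nrow(flagged) >= 1)
  expect_equal(flagged$source[1], st$index_map$source[1])
  expect_equal(flagged$target[1], st$index_map$target[1])

  # identical scans: zero significant connections, deterministically
  cl <- clone_scan(g$cohort, "a", "b")
  res0 <- connectionwise_group_test(cl, "a", "b")
  expect_equal(nrow(res0$significant), 0L)
  expect_true(all(res0$results$p_corrected == 1))
})

test_that("edgewise family-wise false positives stay near alpha under the null", {
  fwe <- 0L
  n_seeds <- 40L
  for (seed in seq_len(n_seeds)) {
    g <- generate_null_cohort(simulation_params(
      n_subjects = 10L, n_regions = 8L, scans = c("a", "b"),
      n_planted_motifs = 1L, seed = 500 + seed))
    res <- connectionwise_group_test(g$cohort, "a", "b")
    if (nrow(res$significant) > 0) fwe <- fwe + 1L
  }
  # Bonferroni keeps FWE <= alpha; allow binomial slack at 40 draws
  expect_lte(fwe, qbinom(0.995, n_seeds, 0.05))
})
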