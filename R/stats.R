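# Nonparametric machinery: Spearman correlation, Bonferroni correction,
# Mann-Whitney U, and the edgewise group test. Performance and streamline
# counts cannot be assumed normal, so rank-based tests are used throughout,
# always two-sided.

# all permutations of 1..n as an n! x n matrix (used only for small n)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    idx <- row + seq_len(nrow(sub))
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation with a two-sided p-value
#'
#' Computes rho on average-ranked data (ties get mean ranks). The
#' two-sided p-value is exact — full enumeration over all permutations of
#' one rank vector — for n <= 8, and uses the t-approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2` degrees of freedom for
#' larger samples. The study-scale analyses (n = 28 or 56) always take
#' the t branch, so results are reproducible bit-for-bit given n.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return List with `rho`, `p` (two-sided), `n`, `method`.
#' @examples
#' spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho  # 0.8
#' @export
spearman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("spearman needs n >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in input", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant vector has no rank correlation",
         call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- .permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    # rho for every permutation of y's ranks against the fixed x ranks
    rhos <- as.numeric(matrix(ryc[perms], nrow(perms), n) %*% rxc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact enumeration"
  } else {
    r2 <- min(rho^2, 1)
    if (r2 >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - r2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Bonferroni correction
#'
#' Family-wise error control: `min(1, p * family_size)`.
#'
#' @param p_raw Raw p-value(s) in `[0, 1]`.
#' @param family_size Number of tests in the family (>= 1).
#' @return Corrected p-value(s), capped at 1.
#' @examples
#' bonferroni(0.001, 28)  # 0.028
#' @export
bonferroni <- function(p_raw, family_size) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = FALSE) || anyNA(p_raw)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (family_size < 1L) stop("family_size must be >= 1", call. = FALSE)
  pmin(1, p_raw * family_size)
}

#' Mann-Whitney U test (two-sided)
#'
#' Returns U for the first sample (number of (x, y) pairs with x > y,
#' ties counting one half). The p-value is exact — via the exact null
#' distribution of U, equivalent to enumerating all rank assignments —
#' when `n1 * n2 <= 400` and there are no ties; otherwise the normal
#' approximation with tie correction is used. Thresholds are fixed so
#' results reproduce bit-for-bit given the sample sizes.
#'
#' @param x,y Nonempty numeric vectors.
#' @return List with `U`, `p` (two-sided), `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) {
    stop("mann_whitney_u needs nonempty samples", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values in input", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 * n2 <= 400L) {
    # exact: P(U <= u) from the exact distribution; two-sided by doubling
    # the smaller tail, capped at 1
    lo <- stats::pwilcox(min(U, n1 * n2 - U), n1, n2)
    p <- min(1, 2 * lo)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    if (sigma2 <= 0) {
      # all values tied: no evidence either way
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation"
  }
  list(U = U, p = p, n1 = n1, n2 = n2, method = method)
}

#' Assemble a test-result row
#'
#' @param statistic Test statistic.
#' @param p_raw Raw p-value.
#' @param family_size Bonferroni family size.
#' @param n Sample size.
#' @param alpha Significance level (default 0.05).
#' @return One-row data.frame with `statistic`, `p_raw`, `p_corrected`,
#'   `n`, `family_size`, `significant`.
#' @export
test_result <- function(statistic, p_raw, family_size, n, alpha = 0.05) {
  p_corrected <- bonferroni(p_raw, family_size)
  data.frame(statistic = statistic, p_raw = p_raw,
             p_corrected = p_corrected, n = n,
             family_size = family_size,
             significant = p_corrected < alpha)
}

#' Edgewise group test between two scans
#'
#' The group-level change analysis: one Mann-Whitney U test per
#' vectorized connection, comparing the distribution of that connection's
#' values across subjects at `scan_x` against `scan_y`, Bonferroni-
#' corrected for the number of connections tested (about 16,000 at the
#' 185-region parcellation in symmetric mode). The scans are compared as
#' two groups; a paired Wilcoxon signed-rank variant is available via
#' `paired = TRUE` for sensitivity analysis but is not the default.
#'
#' @param cohort A `connectome_cohort`.
#' @param scan_x,scan_y The two scans to compare.
#' @param alpha Significance level (default 0.05).
#' @param mode Vectorization mode.
#' @param subjects Subjects to include (default: all with both scans).
#' @param paired Use a paired signed-rank test instead (default FALSE).
#' @return List with `results` (data.frame: source, target, statistic,
#'   p_raw, p_corrected, significant), `significant` (the significant
#'   subset), `family_size`, `n_subjects`.
#' @export
connectionwise_group_test <- function(cohort, scan_x = "a", scan_y = "b",
                                      alpha = 0.05,
                                      mode = c("symmetric", "full"),
                                      subjects = NULL, paired = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "connectome_cohort"))
  if (is.null(subjects)) {
    keys <- names(cohort$matrices)
    has <- function(s, scan) paste(s, scan, sep = ":") %in% keys
    subjects <- cohort$subjects[
      vapply(cohort$subjects, has, logical(1L), scan = scan_x) &
      vapply(cohort$subjects, has, logical(1L), scan = scan_y)]
  }
  if (length(subjects) < 3L) {
    warning("fewer than 3 subjects per group: the edgewise test is underpowered")
  }
  sx <- stack_cohort(cohort, scans = scan_x, mode = mode,
                     subjects = subjects)
  sy <- stack_cohort(cohort, scans = scan_y, mode = mode,
                     subjects = subjects)
  p_feat <- nrow(sx$M)
  stat <- numeric(p_feat)
  p_raw <- numeric(p_feat)
  for (f in seq_len(p_feat)) {
    xs <- sx$M[f, ]
    ys <- sy$M[f, ]
    if (paired) {
      d <- ys - xs
      if (all(d == 0)) {
        stat[f] <- 0; p_raw[f] <- 1
      } else {
        w <- stats::wilcox.test(ys, xs, paired = TRUE, exact = FALSE,
                                correct = FALSE)
        stat[f] <- unname(w$statistic); p_raw[f] <- w$p.value
      }
    } else {
      if (all(xs == ys[1L]) && all(ys == ys[1L])) {
        stat[f] <- length(xs) * length(ys) / 2; p_raw[f] <- 1
      } else {
        mw <- mann_whitney_u(xs, ys)
        stat[f] <- mw$U; p_raw[f] <- mw$p
      }
    }
  }
  p_corrected <- bonferroni(p_raw, p_feat)
  results <- data.frame(source = sx$index_map$source,
                        target = sx$index_map$target,
                        statistic = stat, p_raw = p_raw,
                        p_corrected = p_corrected,
                        significant = p_corrected < alpha,
                        stringsAsFactors = FALSE)
  list(results = results,
       significant = results[results$significant, , drop = FALSE],
       family_size = p_feat, n_subjects = length(subjects),
       scan_x = scan_x, scan_y = scan_y, paired = paired)
}
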