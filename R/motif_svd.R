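#' Decompose a stacked connectome matrix into network motifs
#'
#' Thin singular value decomposition `M = U S t(V)` of the stacked
#' feature-by-column matrix. The left singular vectors (columns of `U`)
#' are the orthonormal network motifs: signed patterns of connection
#' weights shared across subjects and scans. The singular values give
#' each motif's share of cross-column variability (explained variance),
#' and the right singular vectors hold the per-column prevalence weights
#' of each motif in each (subject, scan).
#'
#' The decomposition is truncated at the numerical rank: components with
#' `sigma_k <= max(dim(M)) * .Machine$double.eps * sigma_1` are dropped.
#' Singular-vector signs are indeterminate, so each motif is flipped (with
#' its matching weight row) to make its largest-absolute feature entry
#' positive; the decomposition is thereby deterministic given `M`.
#'
#' @param M Numeric matrix, features x columns (tall: at least as many
#'   rows as columns in the connectome regime).
#' @param column_index Optional data.frame mapping columns to
#'   (subject, scan), as produced by [stack_cohort()].
#' @param index_map Optional [feature_index_map()] for mapping motifs back
#'   to region pairs.
#' @param mode Vectorization mode the features came from (affects
#'   [motif_as_matrix()] mirroring).
#' @param center If `TRUE`, subtract the row-wise mean across columns
#'   before decomposing (a PCA-style sensitivity option; the default
#'   analysis decomposes raw stacked counts).
#' @return An object of class `motif_decomposition` with fields `motifs`
#'   (features x rank matrix `U`), `singular_values`, `weights`
#'   (rank x columns matrix, rows of `t(V)` aligned to `M`'s columns),
#'   `explained_variance`, `column_index`, `index_map`, `mode`,
#'   `centered`.
#' @export
decompose <- function(M, column_index = NULL, index_map = NULL,
                      mode = c("symmetric", "full"), center = FALSE) {
  mode <- match.arg(mode)
  if (is.list(M) && !is.null(M$M)) {
    # accept the stack_cohort() bundle directly
    if (is.null(column_index)) column_index <- M$column_index
    if (is.null(index_map)) index_map <- M$index_map
    mode <- M$mode
    M <- M$M
  }
  M <- as.matrix(M)
  if (length(M) == 0L || ncol(M) == 0L) {
    stop("decompose: M has no columns", call. = FALSE)
  }
  if (nrow(M) < ncol(M)) {
    warning("decompose: fewer features than columns; not the tall connectome regime")
  }
  if (center) M <- M - rowMeans(M)
  if (all(M == 0)) {
    out <- structure(list(
      motifs = matrix(0, nrow(M), 0L),
      singular_values = numeric(0),
      weights = matrix(0, 0L, ncol(M)),
      explained_variance = numeric(0),
      column_index = column_index, index_map = index_map,
      mode = mode, centered = center), class = "motif_decomposition")
    return(out)
  }
  s <- svd(M, nu = min(dim(M)), nv = ncol(M))
  tol <- max(dim(M)) * .Machine$double.eps * s$d[1L]
  keep <- s$d > tol
  r <- sum(keep)
  U <- s$u[, seq_len(r), drop = FALSE]
  V <- s$v[, seq_len(r), drop = FALSE]
  d <- s$d[seq_len(r)]
  # sign convention: largest-|entry| feature of each motif is positive
  for (k in seq_len(r)) {
    imax <- which.max(abs(U[, k]))
    if (U[imax, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  structure(list(
    motifs = U,
    singular_values = d,
    weights = t(V),
    explained_variance = explained_variance(d),
    column_index = column_index,
    index_map = index_map,
    mode = mode,
    centered = center), class = "motif_decomposition")
}

#' @export
print.motif_decomposition <- function(x, ...) {
  r <- length(x$singular_values)
  cat(sprintf("<motif_decomposition> %d motifs over %d features x %d columns\n",
              r, nrow(x$motifs), ncol(x$weights)))
  if (r > 0L) {
    cat(sprintf("  top explained variance: %s\n",
                paste(sprintf("%.1f%%",
                              100 * utils::head(x$explained_variance, 3L)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Number of motifs in a decomposition
#' @param dec A `motif_decomposition`.
#' @return Integer numerical rank of the stacked matrix.
#' @export
n_motifs <- function(dec) length(dec$singular_values)

#' Explained-variance fractions of singular values
#'
#' `sigma_k^2 / sum(sigma^2)`: each motif's share of the total variability
#' across the stacked columns.
#'
#' @param singular_values Nonnegative, not all zero.
#' @return Fractions summing to 1.
#' @examples
#' explained_variance(c(2, 1))  # 0.8 0.2
#' @export
explained_variance <- function(singular_values) {
  if (any(singular_values < 0)) {
    stop("singular values must be nonnegative", call. = FALSE)
  }
  total <- sum(singular_values^2)
  if (total == 0) {
    stop("explained variance undefined for all-zero singular values",
         call. = FALSE)
  }
  singular_values^2 / total
}

.column_of <- function(dec, subject, scan) {
  ci <- dec$column_index
  if (is.null(ci)) {
    stop("decomposition carries no column index", call. = FALSE)
  }
  hit <- ci$subject == subject & ci$scan == scan
  if (!any(hit)) {
    stop(sprintf("no column for subject %s, scan %s", subject, scan),
         call. = FALSE)
  }
  ci$column[which(hit)[1L]]
}

#' Motif prevalence in one subject and scan
#'
#' The right-singular-vector entry: how strongly motif `k` is expressed in
#' that column of the stacked matrix.
#'
#' @param dec A `motif_decomposition` with a column index.
#' @param motif Motif number (1 = largest explained variance).
#' @param subject,scan Column key.
#' @return A single weight.
#' @export
prevalence <- function(dec, motif, subject, scan) {
  if (motif < 1L || motif > n_motifs(dec)) {
    stop(sprintf("motif %d out of range (1..%d)", motif, n_motifs(dec)),
         call. = FALSE)
  }
  dec$weights[motif, .column_of(dec, subject, scan)]
}

#' Prevalence weights of one motif across selected columns
#'
#' @param dec A `motif_decomposition` with a column index.
#' @param motif Motif number.
#' @param scan Restrict to one scan (optional).
#' @param subjects Ordered subjects to align to (default: column order).
#' @return Named numeric vector of weights.
#' @export
prevalence_vector <- function(dec, motif, scan = NULL, subjects = NULL) {
  if (motif < 1L || motif > n_motifs(dec)) {
    stop(sprintf("motif %d out of range (1..%d)", motif, n_motifs(dec)),
         call. = FALSE)
  }
  ci <- dec$column_index
  if (is.null(ci)) stop("decomposition carries no column index", call. = FALSE)
  if (!is.null(scan)) ci <- ci[ci$scan == scan, , drop = FALSE]
  if (!is.null(subjects)) {
    idx <- match(as.character(subjects), ci$subject)
    if (anyNA(idx)) {
      stop(sprintf("missing column for subject(s): %s",
                   paste(subjects[is.na(idx)], collapse = ", ")),
           call. = FALSE)
    }
    ci <- ci[idx, , drop = FALSE]
  }
  stats::setNames(dec$weights[motif, ci$column], ci$subject)
}

#' Prevalence change of a motif between two scans
#'
#' For a decomposition over scans a and b jointly, the longitudinal
#' plasticity readout: weight at the later scan minus weight at the
#' earlier one.
#'
#' @param dec A `motif_decomposition` over both scans.
#' @param motif Motif number.
#' @param subject Subject id.
#' @param from,to Scan ids (defaults `"a"` to `"b"`).
#' @return `prevalence(to) - prevalence(from)`.
#' @export
prevalence_change <- function(dec, motif, subject, from = "a", to = "b") {
  prevalence(dec, motif, subject, to) -
    prevalence(dec, motif, subject, from)
}

#' Map a motif back to a signed region-space matrix
#'
#' Inverse of the vectorization: each feature entry is placed at its
#' (source, target) cell, mirrored across the diagonal in symmetric mode.
#' Positive entries are connections that increase with the motif's
#' prevalence, negative ones decrease (both necessarily occur beyond the
#' first motif, by orthogonality).
#'
#' @param dec A `motif_decomposition` with an index map.
#' @param motif Motif number.
#' @return Square signed matrix with region dimnames; its entries'
#'   squared sum is 1 in full mode (unit-norm motif) and 2 in symmetric
#'   mode (each feature mirrored to two cells).
#' @export
motif_as_matrix <- function(dec, motif) {
  if (motif < 1L || motif > n_motifs(dec)) {
    stop(sprintf("motif %d out of range (1..%d)", motif, n_motifs(dec)),
         call. = FALSE)
  }
  if (is.null(dec$index_map)) {
    stop("decomposition carries no feature index map", call. = FALSE)
  }
  unvectorize(dec$motifs[, motif], dec$index_map)
}

#' Relative reconstruction error of a decomposition
#'
#' `||U S t(V) - M|| / ||M||` (Frobenius), a diagnostic that the retained
#' rank reproduces the stacked matrix.
#'
#' @param dec A `motif_decomposition`.
#' @param M The matrix that was decomposed.
#' @return A nonnegative scalar (0 for an exact reconstruction).
#' @export
reconstruction_error <- function(dec, M) {
  M <- if (is.list(M) && !is.null(M$M)) M$M else as.matrix(M)
  if (dec$centered) M <- M - rowMeans(M)
  nrm <- sqrt(sum(M^2))
  if (nrm == 0) return(0)
  Mhat <- dec$motifs %*% (dec$singular_values * dec$weights)
  sqrt(sum((Mhat - M)^2)) / nrm
}

#' Best-matching motif for a reference feature-space vector
#'
#' Utility for validation against planted ground truth: finds the motif
#' with the largest absolute cosine similarity to `reference`.
#'
#' @param dec A `motif_decomposition`.
#' @param reference Numeric vector in the same feature space.
#' @return List with `motif` (index) and `cosine` (absolute cosine
#'   similarity in `[0, 1]`).
#' @export
match_motif <- function(dec, reference) {
  if (n_motifs(dec) == 0L) stop("decomposition has no motifs", call. = FALSE)
  reference <- reference / sqrt(sum(reference^2))
  cosines <- abs(as.numeric(crossprod(dec$motifs, reference)))
  k <- which.max(cosines)
  list(motif = k, cosine = cosines[k])
}
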