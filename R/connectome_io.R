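#' Construct a parcellation
#'
#' A parcellation is the ordered list of region labels that defines the
#' authoritative row/column order of every connectivity matrix in a cohort.
#' The default layout mirrors a single-hemisphere multimodal cortical
#' parcellation (180 cortical parcels) augmented with a five-parcel
#' subdivision of the corpus callosum, giving 185 regions in total.
#'
#' @param labels Character vector of unique region names (length >= 2).
#' @param hemisphere `"left"` or `"right"`.
#' @return An object of class `parcellation`.
#' @examples
#' p <- parcellation(c("A", "B", "C"), "left")
#' length(p$labels)
#' @export
parcellation <- function(labels, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  labels <- as.character(labels)
  if (length(labels) < 2L) {
    stop("parcellation needs at least 2 region labels", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("parcellation labels must be unique", call. = FALSE)
  }
  structure(list(labels = labels, hemisphere = hemisphere),
            class = "parcellation")
}

#' Default 185-region parcellation
#'
#' Generic labels standing in for the 180 cortical parcels of one
#' hemisphere plus the 5 corpus-callosum parcels used as tractography
#' targets. Cortical parcels are named `P001`..`P180`, callosal parcels
#' `CC_1`..`CC_5`. Real analyses substitute the atlas's own label set via
#' [parcellation()].
#'
#' @param hemisphere `"left"` or `"right"`.
#' @param n_cortical Number of cortical parcels (default 180).
#' @param n_callosal Number of corpus-callosum parcels (default 5).
#' @return A `parcellation` of length `n_cortical + n_callosal`.
#' @export
default_parcellation <- function(hemisphere = c("left", "right"),
                                 n_cortical = 180L, n_callosal = 5L) {
  hemisphere <- match.arg(hemisphere)
  labels <- c(sprintf("P%03d", seq_len(n_cortical)),
              if (n_callosal > 0L) paste0("CC_", seq_len(n_callosal)))
  parcellation(labels, hemisphere)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d regions, %s hemisphere\n",
              length(x$labels), x$hemisphere))
  invisible(x)
}

#' Construct a connectivity matrix
#'
#' Wraps a square nonnegative streamline-count matrix with its cohort
#' metadata. Entry `C[i, j]` counts tractography streamlines seeded in
#' region `i` that enter region `j`; the matrix is asymmetric by
#' construction. The diagonal (self-connections, a tractography artifact)
#' is always zeroed. All-zero rows or columns are permitted: callosal
#' parcels are target-only and have no seeded streamlines.
#'
#' @param values Square numeric matrix, entries >= 0, with or without
#'   dimnames. If dimnames are present they must match `labels`.
#' @param subject Subject identifier.
#' @param scan Scan identifier, conventionally `"a"` (pre-training),
#'   `"b"` (post-training), `"c"` (follow-up).
#' @param hemisphere `"left"` or `"right"`.
#' @param labels Region labels fixing row/column order (defaults to the
#'   matrix's own dimnames).
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, subject, scan,
                                hemisphere = c("left", "right"),
                                labels = rownames(values)) {
  hemisphere <- match.arg(hemisphere)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop(sprintf("connectivity matrix must be square, got %d x %d",
                 nrow(values), ncol(values)), call. = FALSE)
  }
  if (is.null(labels)) {
    stop("region labels are required (dimnames or `labels`)", call. = FALSE)
  }
  if (length(labels) != nrow(values)) {
    stop("label count does not match matrix dimension", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    stop("connectivity matrix contains missing values", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("streamline counts must be nonnegative", call. = FALSE)
  }
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, subject = as.character(subject),
                 scan = as.character(scan), hemisphere = hemisphere),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, subject %s, scan %s, %s hemisphere\n",
              nrow(x$values), ncol(x$values), x$subject, x$scan, x$hemisphere))
  invisible(x)
}

# Auto-detect comma vs tab delimiter from the header line.
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a connectivity matrix from delimited text
#'
#' Expects a header row of region labels and one labeled row per region
#' (comma- or tab-delimited, auto-detected). The diagonal is zeroed on
#' load. If `parcellation` is supplied, the file's labels must match it
#' exactly (same set, same order).
#'
#' @param path File path.
#' @param subject,scan,hemisphere Metadata for the returned object.
#' @param parcellation Optional `parcellation` to validate labels against.
#' @return A `connectivity_matrix`.
#' @export
load_matrix <- function(path, subject, scan,
                        hemisphere = c("left", "right"),
                        parcellation = NULL) {
  hemisphere <- match.arg(hemisphere)
  if (!file.exists(path)) {
    stop(sprintf("matrix file not found: %s", path), call. = FALSE)
  }
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels_row <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  labels_col <- colnames(values)
  if (nrow(values) != ncol(values)) {
    stop(sprintf("%s: matrix is not square (%d rows, %d columns)",
                 path, nrow(values), ncol(values)), call. = FALSE)
  }
  if (!identical(labels_row, labels_col)) {
    stop(sprintf("%s: row labels do not match column labels", path),
         call. = FALSE)
  }
  if (!is.null(parcellation) && !identical(labels_row, parcellation$labels)) {
    stop(sprintf("%s: labels do not match the cohort parcellation", path),
         call. = FALSE)
  }
  connectivity_matrix(values, subject, scan, hemisphere, labels = labels_row)
}

#' Write a connectivity matrix as delimited text
#'
#' Inverse of [load_matrix()]: header row of labels, one labeled row per
#' region. Written with full precision so integer counts round-trip
#' bit-identically.
#'
#' @param m A `connectivity_matrix`.
#' @param path Output file path.
#' @param sep Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = ",") {
  stopifnot(inherits(m, "connectivity_matrix"))
  labels <- rownames(m$values)
  lines <- c(paste(c("region", labels), collapse = sep),
             vapply(seq_along(labels), function(i) {
               paste(c(labels[i], format(m$values[i, ], digits = 17,
                                         trim = TRUE, scientific = FALSE)),
                     collapse = sep)
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a connectome cohort
#'
#' @param parcellation The shared `parcellation`.
#' @param matrices List of `connectivity_matrix` objects, one per
#'   (subject, scan); all must share the parcellation's dimension, labels
#'   and hemisphere.
#' @param subjects Optional ordered subject list (default: order of first
#'   appearance in `matrices`).
#' @param scans Optional ordered scan list (default: order of first
#'   appearance).
#' @return An object of class `connectome_cohort` with matrices keyed
#'   `"<subject>:<scan>"`.
#' @export
connectome_cohort <- function(parcellation, matrices,
                              subjects = NULL, scans = NULL) {
  stopifnot(inherits(parcellation, "parcellation"))
  if (length(matrices) == 0L) stop("cohort has no matrices", call. = FALSE)
  keys <- vapply(matrices, function(m) paste(m$subject, m$scan, sep = ":"),
                 character(1L))
  if (anyDuplicated(keys)) {
    stop("duplicate (subject, scan) keys in cohort", call. = FALSE)
  }
  for (m in matrices) {
    if (!inherits(m, "connectivity_matrix")) {
      stop("all cohort elements must be connectivity_matrix objects",
           call. = FALSE)
    }
    if (!identical(rownames(m$values), parcellation$labels)) {
      stop(sprintf("matrix (%s, %s) does not match the cohort parcellation",
                   m$subject, m$scan), call. = FALSE)
    }
    if (!identical(m$hemisphere, parcellation$hemisphere)) {
      stop(sprintf("matrix (%s, %s) hemisphere differs from the parcellation",
                   m$subject, m$scan), call. = FALSE)
    }
  }
  all_subjects <- vapply(matrices, `[[`, character(1L), "subject")
  all_scans <- vapply(matrices, `[[`, character(1L), "scan")
  if (is.null(subjects)) subjects <- unique(all_subjects)
  if (is.null(scans)) scans <- unique(all_scans)
  names(matrices) <- keys
  structure(list(parcellation = parcellation, matrices = matrices,
                 subjects = as.character(subjects),
                 scans = as.character(scans)),
            class = "connectome_cohort")
}

#' @export
print.connectome_cohort <- function(x, ...) {
  cat(sprintf("<connectome_cohort> %d subjects x scans {%s}, %d regions, %s hemisphere\n",
              length(x$subjects), paste(x$scans, collapse = ", "),
              length(x$parcellation$labels), x$parcellation$hemisphere))
  invisible(x)
}

#' Fetch one matrix from a cohort
#'
#' @param cohort A `connectome_cohort`.
#' @param subject,scan Key of the matrix.
#' @return The `connectivity_matrix`.
#' @export
cohort_matrix <- function(cohort, subject, scan) {
  key <- paste(subject, scan, sep = ":")
  m <- cohort$matrices[[key]]
  if (is.null(m)) {
    stop(sprintf("cohort has no matrix for subject %s, scan %s",
                 subject, scan), call. = FALSE)
  }
  m
}

#' Feature-space index map
#'
#' The fixed ordering of region pairs that defines how a matrix is
#' flattened to a feature vector. `"full"` mode takes all off-diagonal
#' entries in row-major order (length `D*(D-1)`); `"symmetric"` mode takes
#' the strict upper triangle in row-major order (length `D*(D-1)/2`).
#'
#' @param labels Region labels.
#' @param mode `"symmetric"` (default) or `"full"`.
#' @return A data.frame with columns `source`, `target` (labels) and
#'   `i`, `j` (1-based indices), one row per feature position.
#' @export
feature_index_map <- function(labels, mode = c("symmetric", "full")) {
  mode <- match.arg(mode)
  d <- length(labels)
  if (mode == "symmetric") {
    i <- rep.int(seq_len(d - 1L), times = (d - 1L):1L)
    j <- unlist(lapply(seq_len(d - 1L), function(k) (k + 1L):d),
                use.names = FALSE)
  } else {
    i <- rep(seq_len(d), each = d - 1L)
    j <- unlist(lapply(seq_len(d), function(k) setdiff(seq_len(d), k)),
                use.names = FALSE)
  }
  data.frame(source = labels[i], target = labels[j], i = i, j = j,
             stringsAsFactors = FALSE)
}

#' Vectorize a connectivity matrix
#'
#' Flattens a matrix to the cohort's canonical feature vector. In
#' `"symmetric"` mode (the default) the matrix is first symmetrized as
#' `(C + t(C)) / 2` — probabilistic-tractography streamline direction is
#' not biologically meaningful — and the strict upper triangle is emitted
#' in row-major order. `"full"` mode emits every off-diagonal entry in
#' row-major order and is retained for sensitivity analyses.
#'
#' @param m A `connectivity_matrix` or plain square matrix.
#' @param mode `"symmetric"` or `"full"`.
#' @param index_map Optional precomputed [feature_index_map()] (saves
#'   recomputation across a cohort).
#' @return A numeric vector with attribute `index_map`.
#' @examples
#' C <- matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, byrow = TRUE,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' vectorize(C, mode = "full")       # 1 2 3 4 5 6
#' vectorize(C, mode = "symmetric")  # 2 3.5 5
#' @export
vectorize <- function(m, mode = c("symmetric", "full"), index_map = NULL) {
  mode <- match.arg(mode)
  values <- if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m)
  if (nrow(values) != ncol(values)) {
    stop("vectorize requires a square matrix", call. = FALSE)
  }
  labels <- rownames(values)
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(nrow(values)))
  if (is.null(index_map)) index_map <- feature_index_map(labels, mode)
  if (mode == "symmetric") {
    values <- (values + t(values)) / 2
  }
  v <- values[cbind(index_map$i, index_map$j)]
  attr(v, "index_map") <- index_map
  attr(v, "mode") <- mode
  v
}

#' Place a feature vector back into region space
#'
#' Inverse of [vectorize()]: entries go to their `(source, target)` cells;
#' in symmetric mode each value is mirrored across the diagonal. The
#' diagonal is zero.
#'
#' @param v Numeric feature vector.
#' @param index_map A [feature_index_map()]; defaults to `v`'s own
#'   attribute.
#' @param labels Region labels (defaults to those in the index map).
#' @return A square numeric matrix with region dimnames.
#' @export
unvectorize <- function(v, index_map = attr(v, "index_map"),
                        labels = NULL) {
  if (is.null(index_map)) {
    stop("an index_map is required to unvectorize", call. = FALSE)
  }
  if (is.null(labels)) labels <- unique(c(index_map$source, index_map$target))
  d <- length(labels)
  out <- matrix(0, d, d, dimnames = list(labels, labels))
  out[cbind(index_map$i, index_map$j)] <- v
  mirrored <- !any(duplicated(paste(pmin(index_map$i, index_map$j),
                                    pmax(index_map$i, index_map$j)))) &&
    all(index_map$i < index_map$j)
  if (mirrored) {
    out[cbind(index_map$j, index_map$i)] <- v
  }
  out
}

#' Stack a cohort into the data matrix M
#'
#' Arranges the selected scans' connectivity matrices as columns of a
#' single feature-by-column matrix, the input to [decompose()]. Columns
#' are ordered scan-major (all subjects for the first requested scan, then
#' the next scan), following the cohort's subject order; the returned
#' column index makes the mapping explicit so downstream weight lookups
#' are unambiguous.
#'
#' @param cohort A `connectome_cohort`.
#' @param scans Character vector of scans to include (subset of
#'   `cohort$scans`).
#' @param mode Vectorization mode, see [vectorize()].
#' @param subjects Optional subject subset (default: all cohort subjects).
#' @param transform `"none"` (default, raw counts) or `"log1p"` for a
#'   robustness transform.
#' @return A list with elements `M` (features x columns matrix),
#'   `column_index` (data.frame column/subject/scan), `index_map`, and
#'   `mode`.
#' @export
stack_cohort <- function(cohort, scans = cohort$scans,
                         mode = c("symmetric", "full"),
                         subjects = cohort$subjects,
                         transform = c("none", "log1p")) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  stopifnot(inherits(cohort, "connectome_cohort"))
  scans <- as.character(scans)
  subjects <- as.character(subjects)
  if (length(scans) == 0L || length(subjects) == 0L) {
    stop("stack_cohort: empty scan or subject selection", call. = FALSE)
  }
  if (!all(scans %in% cohort$scans)) {
    stop("stack_cohort: unknown scan requested", call. = FALSE)
  }
  index_map <- feature_index_map(cohort$parcellation$labels, mode)
  cols <- vector("list", length(scans) * length(subjects))
  column_index <- data.frame(column = integer(0), subject = character(0),
                             scan = character(0), stringsAsFactors = FALSE)
  k <- 0L
  for (scan in scans) {
    for (subject in subjects) {
      k <- k + 1L
      m <- cohort_matrix(cohort, subject, scan)
      cols[[k]] <- as.numeric(vectorize(m, mode, index_map))
      column_index <- rbind(column_index,
                            data.frame(column = k, subject = subject,
                                       scan = scan,
                                       stringsAsFactors = FALSE))
    }
  }
  M <- do.call(cbind, cols)
  if (transform == "log1p") M <- log1p(M)
  list(M = M, column_index = column_index, index_map = index_map,
       mode = mode)
}

#' Write a cohort to disk with a manifest
#'
#' Emits one delimited matrix file per (subject, scan), a parcellation
#' file, and a YAML manifest tying them together in the format
#' [load_cohort()] reads. Integer counts round-trip losslessly.
#'
#' @param cohort A `connectome_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "connectome_cohort"))
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  parc_path <- file.path(dir, "parcellation.txt")
  writeLines(cohort$parcellation$labels, parc_path)
  entries <- lapply(cohort$matrices, function(m) {
    rel <- file.path("matrices",
                     sprintf("%s_%s.csv", m$subject, m$scan))
    write_matrix(m, file.path(dir, rel))
    list(subject = m$subject, scan = m$scan, path = rel)
  })
  manifest <- list(
    parcellation = "parcellation.txt",
    hemisphere = cohort$parcellation$hemisphere,
    subjects = as.list(cohort$subjects),
    scans = as.list(cohort$scans),
    matrices = unname(entries)
  )
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}

#' Load a cohort from a manifest
#'
#' @param manifest_path Path to a YAML manifest written by
#'   [write_cohort()] (paths are resolved relative to the manifest's
#'   directory).
#' @return A `connectome_cohort`.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  }
  manifest <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  labels <- readLines(file.path(base, manifest$parcellation))
  parc <- parcellation(labels, manifest$hemisphere)
  matrices <- lapply(manifest$matrices, function(e) {
    load_matrix(file.path(base, e$path), e$subject, e$scan,
                manifest$hemisphere, parcellation = parc)
  })
  connectome_cohort(parc, matrices,
                    subjects = unlist(manifest$subjects),
                    scans = unlist(manifest$scans))
}
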