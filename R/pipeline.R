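# Orchestration of the four hypotheses over one hemisphere's cohort:
#   Q1  baseline connectivity (scan a) vs. day-1 performance
#   Q2  baseline connectivity (scan a) vs. training gain (day 4 - day 1)
#   Q3  connectivity change (scan b - scan a weights) vs. training gain
#   Q4  group-level edgewise change (b vs. a, c vs. a)
# Q1-Q3 correlate motif prevalences with behavior (Spearman, Bonferroni
# over the number of motifs); Q4 tests every connection (Bonferroni over
# the number of connections).

.motif_question <- function(dec, behavior_vec, alpha) {
  if (stats::sd(behavior_vec) == 0) {
    stop("degenerate input: behavioral vector is constant", call. = FALSE)
  }
  m <- n_motifs(dec)
  rows <- lapply(seq_len(m), function(k) {
    w <- prevalence_vector(dec, k, scan = NULL, subjects = names(behavior_vec))
    if (stats::sd(w) == 0) {
      return(data.frame(motif = k, explained_variance =
                          dec$explained_variance[k],
                        rho = NA_real_, p_raw = NA_real_,
                        p_corrected = NA_real_, n = length(w),
                        family_size = m, significant = FALSE,
                        testable = FALSE))
    }
    sp <- spearman(w, behavior_vec)
    tr <- test_result(sp$rho, sp$p, family_size = m, n = sp$n,
                      alpha = alpha)
    data.frame(motif = k, explained_variance = dec$explained_variance[k],
               rho = tr$statistic, p_raw = tr$p_raw,
               p_corrected = tr$p_corrected, n = tr$n,
               family_size = tr$family_size,
               significant = tr$significant, testable = TRUE)
  })
  do.call(rbind, rows)
}

.complete_subjects <- function(cohort, scans) {
  keys <- names(cohort$matrices)
  ok <- vapply(cohort$subjects, function(s) {
    all(paste(s, scans, sep = ":") %in% keys)
  }, logical(1L))
  dropped <- cohort$subjects[!ok]
  if (length(dropped) > 0L) {
    warning(sprintf("dropping subject(s) missing scan(s) %s: %s",
                    paste(scans, collapse = ","),
                    paste(dropped, collapse = ", ")))
  }
  cohort$subjects[ok]
}

#' Q1: does baseline connectivity predict initial performance?
#'
#' Decomposes scan-a columns only (one motif per subject at full rank)
#' and Spearman-correlates each motif's prevalence weights with day-1
#' performance on double-embedded sentences, Bonferroni-corrected for the
#' number of motifs.
#'
#' @param cohort A `connectome_cohort` with scan a.
#' @param behavior A `behavioral_table`.
#' @param alpha Significance level (default 0.05).
#' @param sentence_type Behavioral variable (default `"double"`; single
#'   embeddings sit near ceiling).
#' @param mode Vectorization mode.
#' @param day Performance day (default 1).
#' @return List with `results` (per-motif data.frame), `decomposition`,
#'   `behavior_vec`, `question = "Q1"`.
#' @export
run_q1 <- function(cohort, behavior, alpha = 0.05,
                   sentence_type = "double",
                   mode = c("symmetric", "full"), day = 1L) {
  mode <- match.arg(mode)
  subjects <- .complete_subjects(cohort, "a")
  st <- stack_cohort(cohort, scans = "a", mode = mode, subjects = subjects)
  dec <- decompose(st)
  perf <- performance_vector(behavior, subjects, day = day,
                             sentence_type = sentence_type)
  results <- .motif_question(dec, perf, alpha)
  list(question = "Q1", results = results, decomposition = dec,
       behavior_vec = perf, alpha = alpha)
}

#' Q2: does baseline connectivity predict the training gain?
#'
#' As [run_q1()] but with the day-4 minus day-1 performance change as the
#' behavioral variable.
#'
#' @inheritParams run_q1
#' @return As [run_q1()], with `question = "Q2"`.
#' @export
run_q2 <- function(cohort, behavior, alpha = 0.05,
                   sentence_type = "double",
                   mode = c("symmetric", "full")) {
  mode <- match.arg(mode)
  subjects <- .complete_subjects(cohort, "a")
  st <- stack_cohort(cohort, scans = "a", mode = mode, subjects = subjects)
  dec <- decompose(st)
  dperf <- performance_change_vector(behavior, subjects, sentence_type)
  results <- .motif_question(dec, dperf, alpha)
  list(question = "Q2", results = results, decomposition = dec,
       behavior_vec = dperf, alpha = alpha)
}

#' Q3: does connectivity change track the training gain?
#'
#' Decomposes scans a and b jointly (two columns per subject, so the
#' motif family doubles), computes each subject's prevalence change
#' (scan b minus scan a) per motif, and Spearman-correlates it with the
#' performance change, Bonferroni-corrected for the number of motifs. If
#' no motif shows any across-subject variation in its prevalence change
#' (scans identical), the analysis reports "no testable change".
#'
#' @inheritParams run_q1
#' @return List with `results`, `decomposition`, `behavior_vec`,
#'   `status` (`"ok"` or `"no testable change"`), `question = "Q3"`.
#' @export
run_q3 <- function(cohort, behavior, alpha = 0.05,
                   sentence_type = "double",
                   mode = c("symmetric", "full")) {
  mode <- match.arg(mode)
  subjects <- .complete_subjects(cohort, c("a", "b"))
  st <- stack_cohort(cohort, scans = c("a", "b"), mode = mode,
                     subjects = subjects)
  dec <- decompose(st)
  dperf <- performance_change_vector(behavior, subjects, sentence_type)
  if (stats::sd(dperf) == 0) {
    stop("degenerate input: performance change is constant", call. = FALSE)
  }
  m <- n_motifs(dec)
  rows <- lapply(seq_len(m), function(k) {
    dw <- vapply(subjects, function(s) {
      prevalence_change(dec, k, s, from = "a", to = "b")
    }, numeric(1L))
    # weights are rows of an orthonormal V, so O(1) entries; changes at
    # floating-point scale mean the scans are numerically identical
    if (stats::sd(dw) == 0 || max(abs(dw)) < 1e-10) {
      return(data.frame(motif = k, explained_variance =
                          dec$explained_variance[k],
                        rho = NA_real_, p_raw = NA_real_,
                        p_corrected = NA_real_, n = length(dw),
                        family_size = m, significant = FALSE,
                        testable = FALSE))
    }
    sp <- spearman(dw, dperf)
    tr <- test_result(sp$rho, sp$p, family_size = m, n = sp$n,
                      alpha = alpha)
    data.frame(motif = k, explained_variance = dec$explained_variance[k],
               rho = tr$statistic, p_raw = tr$p_raw,
               p_corrected = tr$p_corrected, n = tr$n,
               family_size = tr$family_size,
               significant = tr$significant, testable = TRUE)
  })
  results <- do.call(rbind, rows)
  status <- if (all(!results$testable)) "no testable change" else "ok"
  list(question = "Q3", results = results, decomposition = dec,
       behavior_vec = dperf, status = status, alpha = alpha)
}

#' Q4: group-level edgewise connectivity change
#'
#' Runs the edgewise Mann-Whitney comparison for scans b vs. a and, when
#' scan c is present, c vs. a.
#'
#' @param cohort A `connectome_cohort`.
#' @param alpha Significance level.
#' @param mode Vectorization mode.
#' @param paired Use the paired signed-rank variant (default FALSE).
#' @return List with `question = "Q4"` and one
#'   [connectionwise_group_test()] result per comparison
#'   (`b_vs_a`, optionally `c_vs_a`), plus `n_significant` per
#'   comparison.
#' @export
run_q4 <- function(cohort, alpha = 0.05, mode = c("symmetric", "full"),
                   paired = FALSE) {
  mode <- match.arg(mode)
  out <- list(question = "Q4", alpha = alpha)
  out$b_vs_a <- connectionwise_group_test(cohort, "a", "b", alpha, mode,
                                          paired = paired)
  has_c <- any(vapply(cohort$matrices, function(m) m$scan == "c",
                      logical(1L)))
  if (has_c) {
    out$c_vs_a <- connectionwise_group_test(cohort, "a", "c", alpha, mode,
                                            paired = paired)
  } else {
    warning("scan c absent: running b vs. a only")
  }
  out$n_significant <- vapply(
    out[intersect(c("b_vs_a", "c_vs_a"), names(out))],
    function(r) nrow(r$significant), integer(1L))
  out
}

#' Span-score side analysis
#'
#' Spearman correlations of each motif's prevalence with reading span and
#' digit span, under the same Bonferroni family as the main motif tests.
#'
#' @param dec A scan-a `motif_decomposition`.
#' @param behavior A `behavioral_table` with span scores.
#' @param alpha Significance level.
#' @return data.frame with one row per (motif, span).
#' @export
run_span_correlations <- function(dec, behavior, alpha = 0.05) {
  subjects <- dec$column_index$subject
  m <- n_motifs(dec)
  rows <- list()
  for (span in c("reading_span", "digit_span")) {
    sv <- span_vector(behavior, subjects, span)
    for (k in seq_len(m)) {
      w <- prevalence_vector(dec, k, subjects = subjects)
      sp <- spearman(w, sv)
      tr <- test_result(sp$rho, sp$p, family_size = m, n = sp$n,
                        alpha = alpha)
      rows[[length(rows) + 1L]] <-
        data.frame(motif = k, span = span, rho = tr$statistic,
                   p_raw = tr$p_raw, p_corrected = tr$p_corrected,
                   significant = tr$significant)
    }
  }
  do.call(rbind, rows)
}

#' Per-region node strength within a motif
#'
#' Sum of absolute motif weights over all connections incident to each
#' region; the ranking used to name a motif's top areas.
#'
#' @param dec A `motif_decomposition` with an index map.
#' @param motif Motif number.
#' @return Named numeric vector (one entry per region, all >= 0).
#' @export
node_strength <- function(dec, motif) {
  W <- motif_as_matrix(dec, motif)
  if (dec$mode == "symmetric") {
    # mirrored matrix: each incident connection appears once per row
    rowSums(abs(W))
  } else {
    rowSums(abs(W)) + colSums(abs(W))
  }
}

#' Report a motif: top regions, signed edge list, regression pairs
#'
#' Produces the tabular content behind a motif figure: the regions where
#' the motif has highest absolute connectivity, the strongest signed
#' connections (for chord plotting), and the (prevalence, behavior) point
#' pairs for the regression panel. By default the edge list is cut at the
#' smallest set of edges covering half the motif's squared norm, and
#' however many regions those edges touch are reported alongside the
#' `top_k` strongest.
#'
#' @param dec A `motif_decomposition`.
#' @param motif Motif number.
#' @param behavior_vec Optional behavioral vector aligned to the
#'   decomposition's subjects (regression pairs are emitted if given).
#' @param top_k Number of top regions to rank (default 9, clipped to the
#'   region count with a warning).
#' @param edge_fraction Fraction of the motif's squared norm the edge
#'   list must cover (default 0.5); ignored if `edge_count` is given.
#' @param edge_count Absolute number of strongest edges to report.
#' @return An object of class `motif_report`: list with `motif`,
#'   `explained_variance`, `top_regions` (data.frame region/strength),
#'   `top_connections` (data.frame source/target/weight, |weight|
#'   descending), `n_regions_touched`, `regression_pairs`.
#' @export
report_motif <- function(dec, motif, behavior_vec = NULL, top_k = 9L,
                         edge_fraction = 0.5, edge_count = NULL) {
  strengths <- node_strength(dec, motif)
  n_regions <- length(strengths)
  if (top_k > n_regions) {
    warning(sprintf("top_k = %d exceeds region count %d; clipping",
                    top_k, n_regions))
    top_k <- n_regions
  }
  ord <- order(strengths, decreasing = TRUE)
  top_regions <- data.frame(region = names(strengths)[ord][seq_len(top_k)],
                            node_strength = unname(strengths[ord])[seq_len(top_k)],
                            stringsAsFactors = FALSE)
  v <- dec$motifs[, motif]
  im <- dec$index_map
  eord <- order(abs(v), decreasing = TRUE)
  if (is.null(edge_count)) {
    csum <- cumsum(v[eord]^2) / sum(v^2)
    edge_count <- which(csum >= edge_fraction)[1L]
  }
  edge_count <- min(edge_count, length(v))
  sel <- eord[seq_len(edge_count)]
  top_connections <- data.frame(source = im$source[sel],
                                target = im$target[sel],
                                weight = v[sel],
                                stringsAsFactors = FALSE)
  touched <- unique(c(top_connections$source, top_connections$target))
  regression_pairs <- NULL
  if (!is.null(behavior_vec)) {
    w <- prevalence_vector(dec, motif, subjects = names(behavior_vec))
    regression_pairs <- data.frame(subject = names(behavior_vec),
                                   prevalence = unname(w),
                                   behavior = unname(behavior_vec),
                                   stringsAsFactors = FALSE)
  }
  structure(list(motif = motif,
                 explained_variance = dec$explained_variance[motif],
                 top_regions = top_regions,
                 top_connections = top_connections,
                 n_regions_touched = length(touched),
                 regression_pairs = regression_pairs),
            class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("<motif_report> motif %d (%.1f%% variance): %d edges touching %d regions\n",
              x$motif, 100 * x$explained_variance,
              nrow(x$top_connections), x$n_regions_touched))
  cat("  top regions:", paste(utils::head(x$top_regions$region, 5L),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Write question results as delimited tables
#'
#' @param q A result from [run_q1()], [run_q2()], [run_q3()] or
#'   [run_q4()].
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_question <- function(q, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  fmt <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  if (q$question == "Q4") {
    for (cmp in intersect(c("b_vs_a", "c_vs_a"), names(q))) {
      written <- c(written,
                   fmt(q[[cmp]]$significant,
                       sprintf("q4_%s_significant.tsv", cmp)))
    }
  } else {
    written <- c(written,
                 fmt(q$results, sprintf("%s_motifs.tsv",
                                        tolower(q$question))))
  }
  invisible(written)
}
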