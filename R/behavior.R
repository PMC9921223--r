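#' Behavioral table for the sentence-comprehension task
#'
#' Holds per subject x day x sentence-type answer counts from the
#' center-embedded-sentence training task (days 1-4; 33 trials per
#' sentence type per day by design), plus optional per-subject working
#' memory spans. Only first-question answers enter the counts; second
#' questions after a repeated sentence are excluded from scoring.
#'
#' @param records data.frame with columns `subject`, `day` (integer 1-4),
#'   `sentence_type` (`"single"` or `"double"`), `n_correct`,
#'   `n_incorrect`, `n_missed` (nonnegative integers, positive total).
#' @param spans Optional data.frame with columns `subject`,
#'   `reading_span`, `digit_span` (levels reached, forward and backward
#'   already averaged to one real per span).
#' @return An object of class `behavioral_table`.
#' @export
behavioral_table <- function(records, spans = NULL) {
  needed <- c("subject", "day", "sentence_type",
              "n_correct", "n_incorrect", "n_missed")
  if (!all(needed %in% names(records))) {
    stop(sprintf("records must have columns: %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  records <- as.data.frame(records)[needed]
  records$subject <- as.character(records$subject)
  records$day <- as.integer(records$day)
  records$sentence_type <- as.character(records$sentence_type)
  if (!all(records$sentence_type %in% c("single", "double"))) {
    stop("sentence_type must be 'single' or 'double'", call. = FALSE)
  }
  counts <- as.matrix(records[c("n_correct", "n_incorrect", "n_missed")])
  if (anyNA(counts) || any(counts < 0)) {
    stop("answer counts must be nonnegative and complete", call. = FALSE)
  }
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("each record needs at least one answered or missed trial",
         call. = FALSE)
  }
  if (any(totals != 33)) {
    warning(sprintf("%d record(s) deviate from the designed 33 trials/type/day",
                    sum(totals != 33)))
  }
  key <- with(records, paste(subject, day, sentence_type))
  if (anyDuplicated(key)) {
    stop("duplicate (subject, day, sentence_type) records", call. = FALSE)
  }
  if (!is.null(spans)) {
    spans <- as.data.frame(spans)
    spans$subject <- as.character(spans$subject)
  }
  structure(list(records = records, spans = spans),
            class = "behavioral_table")
}

#' @export
print.behavioral_table <- function(x, ...) {
  cat(sprintf("<behavioral_table> %d records, %d subjects%s\n",
              nrow(x$records), length(unique(x$records$subject)),
              if (is.null(x$spans)) "" else ", with span scores"))
  invisible(x)
}

#' Read a behavioral table from delimited text
#'
#' @param path Tab- or comma-delimited file with the record columns of
#'   [behavioral_table()].
#' @param spans_path Optional file with columns `subject`,
#'   `reading_span`, `digit_span`.
#' @return A `behavioral_table`.
#' @export
read_behavior <- function(path, spans_path = NULL) {
  sep <- .detect_sep(path)
  records <- utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
  spans <- NULL
  if (!is.null(spans_path)) {
    spans <- utils::read.table(spans_path, header = TRUE,
                               sep = .detect_sep(spans_path),
                               stringsAsFactors = FALSE)
  }
  behavioral_table(records, spans)
}

#' Write a behavioral table
#'
#' @param table A `behavioral_table`.
#' @param path Output path for the records (tab-delimited).
#' @param spans_path Optional output path for the spans.
#' @return `path`, invisibly.
#' @export
write_behavior <- function(table, path, spans_path = NULL) {
  stopifnot(inherits(table, "behavioral_table"))
  utils::write.table(table$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(spans_path) && !is.null(table$spans)) {
    utils::write.table(table$spans, spans_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Task performance: proportion of correct first answers
#'
#' `n_correct / (n_correct + n_incorrect + n_missed)` — missed answers
#' count against performance exactly like incorrect ones.
#'
#' @param n_correct,n_incorrect,n_missed Nonnegative counts (vectorized).
#' @return Proportion(s) in `[0, 1]`.
#' @examples
#' performance(20, 10, 3)  # 20/33
#' @export
performance <- function(n_correct, n_incorrect, n_missed) {
  total <- n_correct + n_incorrect + n_missed
  if (any(total <= 0)) {
    stop("performance undefined: zero answered + missed trials",
         call. = FALSE)
  }
  n_correct / total
}

.perf_lookup <- function(table, subject, day, sentence_type) {
  r <- table$records
  hit <- r$subject == subject & r$day == day &
    r$sentence_type == sentence_type
  if (!any(hit)) {
    stop(sprintf("no behavioral record for subject %s, day %d, %s embedding",
                 subject, day, sentence_type), call. = FALSE)
  }
  row <- r[which(hit)[1L], ]
  performance(row$n_correct, row$n_incorrect, row$n_missed)
}

#' Training effect: day-4 minus day-1 performance
#'
#' @param table A `behavioral_table`.
#' @param subject Subject id.
#' @param sentence_type `"double"` (default; the analysis variable, since
#'   single embeddings start near ceiling) or `"single"`.
#' @return Performance change in `[-1, 1]`.
#' @export
performance_change <- function(table, subject, sentence_type = "double") {
  stopifnot(inherits(table, "behavioral_table"))
  .perf_lookup(table, subject, 4L, sentence_type) -
    .perf_lookup(table, subject, 1L, sentence_type)
}

#' Performance vector aligned to a subject order
#'
#' @param table A `behavioral_table`.
#' @param subjects Ordered subject ids; the result is aligned to this
#'   order.
#' @param day Day (1-4).
#' @param sentence_type `"double"` or `"single"`.
#' @return Named numeric vector, one entry per subject.
#' @export
performance_vector <- function(table, subjects, day = 1L,
                               sentence_type = "double") {
  stopifnot(inherits(table, "behavioral_table"))
  out <- vapply(as.character(subjects), function(s) {
    .perf_lookup(table, s, as.integer(day), sentence_type)
  }, numeric(1L))
  out
}

#' Performance-change vector aligned to a subject order
#'
#' @inheritParams performance_vector
#' @return Named numeric vector of day-4 minus day-1 performance.
#' @export
performance_change_vector <- function(table, subjects,
                                      sentence_type = "double") {
  vapply(as.character(subjects), function(s) {
    performance_change(table, s, sentence_type)
  }, numeric(1L))
}

#' Span covariate vector aligned to a subject order
#'
#' @param table A `behavioral_table` with spans.
#' @param subjects Ordered subject ids.
#' @param which `"reading_span"` or `"digit_span"`.
#' @return Named numeric vector.
#' @export
span_vector <- function(table, subjects,
                        which = c("reading_span", "digit_span")) {
  which <- match.arg(which)
  if (is.null(table$spans)) {
    stop("behavioral table has no span scores", call. = FALSE)
  }
  idx <- match(as.character(subjects), table$spans$subject)
  if (anyNA(idx)) {
    stop(sprintf("missing span scores for subject(s): %s",
                 paste(subjects[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  stats::setNames(table$spans[[which]][idx], as.character(subjects))
}
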