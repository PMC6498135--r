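# Classification of per-protein binary secretion sequences into the four
# dynamic patterns:
#   ALL_ON  secretion active in every window;
#   ON_OFF  active from the basal window, then permanently off (1..10..0);
#   OFF_ON  silent initially, then permanently on (0..01..1);
#   OTHER   never active, or oscillatory (>= 2 on/off transitions).
# The four labels partition the binary sequences of any length T >= 2.

#' Classify one binary secretion sequence
#'
#' @param calls Integer/logical vector of length >= 2 with entries 0/1; the
#'   first entry is the basal window.
#' @return One of `"ALL_ON"`, `"ON_OFF"`, `"OFF_ON"`, `"OTHER"`.
#' @examples
#' classify_pattern(c(1, 1, 1, 1))  # ALL_ON
#' classify_pattern(c(1, 1, 0, 0))  # ON_OFF
#' classify_pattern(c(0, 1, 0, 1))  # OTHER
#' @export
classify_pattern <- function(calls) {
  calls <- as.integer(calls)
  if (length(calls) < 2L)
    stop("a sequence needs at least 2 windows", call. = FALSE)
  if (anyNA(calls) || any(calls != 0L & calls != 1L))
    stop("calls must be binary (0/1)", call. = FALSE)
  classify_pattern_matrix(matrix(calls, nrow = 1L))[1L]
}

#' Classify many sequences at once
#'
#' @param calls Matrix of 0/1 calls, one sequence per row.
#' @return Character vector of pattern labels, one per row.
#' @export
classify_pattern_matrix <- function(calls) {
  stopifnot(is.matrix(calls), ncol(calls) >= 2L)
  storage.mode(calls) <- "integer"
  if (anyNA(calls) || any(calls != 0L & calls != 1L))
    stop("calls must be binary (0/1)", call. = FALSE)
  n_t <- ncol(calls)
  transitions <- rowSums(abs(calls[, -1L, drop = FALSE] -
                             calls[, -n_t, drop = FALSE]))
  first <- calls[, 1L]
  total <- rowSums(calls)
  out <- rep("OTHER", nrow(calls))
  out[total == n_t] <- "ALL_ON"
  out[transitions == 1L & first == 1L] <- "ON_OFF"
  out[transitions == 1L & first == 0L] <- "OFF_ON"
  out
}

#' Summarise dynamic-pattern fractions for one protein
#'
#' @param courses Complete `cell_courses` (see [complete_courses()]).
#' @param protein Protein name.
#' @return Data frame of class `pattern_summary` with columns
#'   `protein, label, count, fraction`; `n_cells` is stored as an attribute.
#' @export
summarize_patterns <- function(courses, protein) {
  if (nrow(courses) == 0L)
    stop("summary error: no courses supplied", call. = FALSE)
  if (!all(courses$complete))
    stop("pattern summaries use complete courses only", call. = FALSE)
  labels <- classify_pattern_matrix(course_call_matrix(courses, protein))
  counts <- table(factor(labels, levels = pattern_labels()))
  out <- data.frame(protein = protein,
                    label = pattern_labels(),
                    count = as.integer(counts),
                    fraction = as.numeric(counts) / length(labels),
                    stringsAsFactors = FALSE)
  attr(out, "n_cells") <- length(labels)
  class(out) <- c("pattern_summary", "data.frame")
  out
}
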