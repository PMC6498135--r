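# Same-cell time-course assembly.
#
# Adherent cells stay in their microtrough, so identity across windows is
# by well coordinates.  A window contributes to a course only when the well
# holds exactly one cell there (gated records exist only for 1-cell wells);
# a course is complete when every window is single-occupied.

#' Link gated records across time windows into same-cell time courses
#'
#' @param gated Gated single-cell records from [gate_cells()], covering all
#'   windows of one chip.
#' @param n_timepoints Total number of windows; defaults to
#'   `max(time_index) + 1`.
#' @return Data frame of class `cell_courses`: one row per candidate cell
#'   with `cell_id, chip_id, row, col`, per-window `observed_t<t>` flags,
#'   `complete`, and per protein/window `<p>_t<t>_log2` and `<p>_t<t>_call`
#'   columns (NA when the window is missing).  Attributes `panel` and
#'   `n_timepoints` describe the layout.
#' @export
link_time_courses <- function(gated, n_timepoints = NULL) {
  if (is.list(gated) && !is.data.frame(gated)) {
    panels <- lapply(gated, names)
    if (length(unique(vapply(panels, paste, "", collapse = ","))) > 1L)
      stop("schema error: per-window records have inconsistent panels",
           call. = FALSE)
    panel0 <- attr(gated[[1L]], "panel")
    gated <- do.call(rbind, gated)
    attr(gated, "panel") <- panel0
  }
  stopifnot(is.data.frame(gated))
  panel <- attr(gated, "panel")
  if (is.null(panel)) {
    panel <- unique(sub("_(raw|log2|call)$", "",
                        grep("_(raw|log2|call)$", names(gated), value = TRUE)))
  }
  if (length(unique(gated$chip_id)) > 1L)
    stop("records from more than one chip; link one chip at a time",
         call. = FALSE)
  n_t <- if (is.null(n_timepoints)) max(gated$time_index) + 1L
         else as.integer(n_timepoints)
  key <- unique(gated[, c("chip_id", "row", "col")])
  key <- key[order(key$row, key$col), , drop = FALSE]
  courses <- data.frame(
    cell_id = sprintf("%s_r%d_c%d", key$chip_id, key$row, key$col),
    chip_id = key$chip_id, row = key$row, col = key$col,
    stringsAsFactors = FALSE)
  obs <- matrix(FALSE, nrow(courses), n_t)
  for (t in seq_len(n_t) - 1L) {
    gt <- gated[gated$time_index == t, , drop = FALSE]
    idx <- match(paste(courses$row, courses$col), paste(gt$row, gt$col))
    obs[, t + 1L] <- !is.na(idx)
    courses[[sprintf("observed_t%d", t)]] <- !is.na(idx)
    for (p in panel) {
      courses[[sprintf("%s_t%d_log2", p, t)]] <- gt[[paste0(p, "_log2")]][idx]
      courses[[sprintf("%s_t%d_call", p, t)]] <- gt[[paste0(p, "_call")]][idx]
    }
  }
  courses$complete <- rowSums(obs) == n_t
  # stable column order: ids, observed flags, complete, then signals
  sig_cols <- unlist(lapply(seq_len(n_t) - 1L, function(t)
    c(sprintf("%s_t%d_log2", panel, t), sprintf("%s_t%d_call", panel, t))))
  courses <- courses[, c("cell_id", "chip_id", "row", "col",
                         sprintf("observed_t%d", seq_len(n_t) - 1L),
                         "complete", sig_cols)]
  rownames(courses) <- NULL
  attr(courses, "panel") <- panel
  attr(courses, "n_timepoints") <- n_t
  class(courses) <- c("cell_courses", "data.frame")
  courses
}

#' Keep only complete time courses
#'
#' @param courses A `cell_courses` data frame.
#' @return The complete subset, attributes preserved.
#' @export
complete_courses <- function(courses) {
  out <- courses[courses$complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "panel") <- attr(courses, "panel")
  attr(out, "n_timepoints") <- attr(courses, "n_timepoints")
  class(out) <- class(courses)
  out
}

#' Subset courses by row, preserving course metadata
#'
#' @param courses A `cell_courses` data frame.
#' @param idx Row indices (or logical mask).
#' @return The subset with `panel`/`n_timepoints` attributes intact.
#' @export
subset_courses <- function(courses, idx) {
  out <- courses[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "panel") <- attr(courses, "panel")
  attr(out, "n_timepoints") <- attr(courses, "n_timepoints")
  class(out) <- class(courses)
  out
}

#' Per-protein call / signal matrix of a set of courses
#'
#' @param courses A `cell_courses` data frame.
#' @param protein Protein name.
#' @return Integer (calls) or numeric (log2 signal) matrix, cells x windows.
#' @export
course_call_matrix <- function(courses, protein) {
  n_t <- attr(courses, "n_timepoints")
  m <- sapply(seq_len(n_t) - 1L, function(t)
    courses[[sprintf("%s_t%d_call", protein, t)]])
  m <- matrix(as.integer(m), nrow = nrow(courses), ncol = n_t)
  rownames(m) <- courses$cell_id
  colnames(m) <- sprintf("t%d", seq_len(n_t) - 1L)
  m
}

#' @rdname course_call_matrix
#' @export
course_signal_matrix <- function(courses, protein) {
  n_t <- attr(courses, "n_timepoints")
  m <- sapply(seq_len(n_t) - 1L, function(t)
    courses[[sprintf("%s_t%d_log2", protein, t)]])
  m <- matrix(as.numeric(m), nrow = nrow(courses), ncol = n_t)
  rownames(m) <- courses$cell_id
  colnames(m) <- sprintf("t%d", seq_len(n_t) - 1L)
  m
}

#' Per-exchange retention summary
#'
#' For each slide exchange e (between windows e-1 and e), the fraction of
#' cells observed at window e-1 that are still observed at window e.
#'
#' @param courses A `cell_courses` data frame (complete and incomplete).
#' @return Data frame with columns `exchange, n_before, n_after, retention`;
#'   `retention` is NA when no cell was present before the exchange.
#' @export
retention_summary <- function(courses) {
  if (nrow(courses) == 0L) stop("no courses to summarise", call. = FALSE)
  n_t <- attr(courses, "n_timepoints")
  obs <- sapply(seq_len(n_t) - 1L, function(t)
    courses[[sprintf("observed_t%d", t)]])
  obs <- matrix(obs, nrow = nrow(courses))
  data.frame(
    exchange = seq_len(n_t - 1L),
    n_before = sapply(seq_len(n_t - 1L), function(e) sum(obs[, e])),
    n_after = sapply(seq_len(n_t - 1L), function(e) sum(obs[, e] & obs[, e + 1L])),
    retention = sapply(seq_len(n_t - 1L), function(e) {
      nb <- sum(obs[, e])
      if (nb == 0L) NA_real_ else sum(obs[, e] & obs[, e + 1L]) / nb
    })
  )
}
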