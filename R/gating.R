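# Background gating against zero-cell on-chip controls.
#
# Zero-cell wells measure the local optical/antibody background for each
# protein.  The secretion threshold is the zero-cell mean plus 3 standard
# deviations; intensities at or below threshold are set to 0 ("no
# secretion"), and the thresholded values are log2(x+1) transformed.

#' Fit the per-protein background model from zero-cell wells
#'
#' For each protein and time window, computes the sample mean and sample
#' standard deviation (denominator n-1) of the raw intensities of wells
#' with `cell_count == 0`, and the secretion threshold mean + 3 SD.  An
#' optional number of region blocks splits the chip into contiguous column
#' bands that are fitted separately; the default is a single chip-wide
#' block.
#'
#' @param wells Well table (see [simulate_chip()]).
#' @param time_index Window to fit, or `NULL` for every window present.
#' @param region_blocks Number of contiguous column bands fitted
#'   separately (default 1, chip-wide background).
#' @return Data frame of class `gating_model` with columns `time_index,
#'   region, protein, background_mean, background_sd, threshold,
#'   n_zero_wells`; the region column-break points are stored in the
#'   `col_breaks` attribute.
#' @export
fit_background <- function(wells, time_index = NULL, region_blocks = 1L) {
  stopifnot(is.data.frame(wells))
  panel <- setdiff(names(wells), well_key_cols)
  if (length(panel) == 0L) stop("no protein columns in well table",
                                call. = FALSE)
  windows <- if (is.null(time_index)) sort(unique(wells$time_index))
             else as.integer(time_index)
  region_blocks <- max(1L, as.integer(region_blocks))
  breaks <- if (region_blocks == 1L) c(-Inf, Inf) else {
    rng <- range(wells$col)
    unique(c(-Inf, stats::quantile(rng[1]:rng[2],
                                   probs = seq_len(region_blocks - 1L) /
                                     region_blocks),
             Inf))
  }
  rows <- list()
  for (t in windows) {
    wt <- wells[wells$time_index == t, , drop = FALSE]
    region <- findInterval(wt$col, breaks)
    for (r in sort(unique(findInterval(wells$col, breaks)))) {
      zero <- wt[wt$cell_count == 0L & region == r, panel, drop = FALSE]
      if (nrow(zero) < 2L) {
        stop(sprintf(
          "gating error: %d zero-cell well(s) at window %d (region %d); need >= 2 for a background estimate",
          nrow(zero), t, r), call. = FALSE)
      }
      mu <- colMeans(zero)
      sdev <- apply(zero, 2L, stats::sd)
      rows[[length(rows) + 1L]] <- data.frame(
        time_index = t, region = r, protein = panel,
        background_mean = unname(mu), background_sd = unname(sdev),
        threshold = unname(mu + 3 * sdev),
        n_zero_wells = nrow(zero),
        stringsAsFactors = FALSE)
    }
  }
  model <- do.call(rbind, rows)
  rownames(model) <- NULL
  attr(model, "col_breaks") <- breaks
  class(model) <- c("gating_model", "data.frame")
  model
}

#' Gate single-cell wells against the background model
#'
#' Emits one record per well with exactly one cell per window.  Raw values
#' strictly above the threshold are kept and called "secretion" (call 1);
#' values at or below it are zeroed (call 0).  The log2 signal is
#' `log2(gated + 1)`, computed after thresholding.
#'
#' @param wells Well table.
#' @param model Gating model from [fit_background()] covering every window
#'   present in `wells`.
#' @return Data frame with columns `chip_id, time_index, row, col` and, per
#'   protein, `<p>_raw`, `<p>_log2`, `<p>_call`; the panel is stored in the
#'   `panel` attribute.
#' @export
gate_cells <- function(wells, model) {
  stopifnot(is.data.frame(wells), inherits(model, "gating_model"))
  panel <- setdiff(names(wells), well_key_cols)
  missing_w <- setdiff(unique(wells$time_index), model$time_index)
  if (length(missing_w))
    stop("no background model for window(s) ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  breaks <- attr(model, "col_breaks")
  single <- wells[wells$cell_count == 1L, , drop = FALSE]
  out <- single[, c("chip_id", "time_index", "row", "col")]
  region <- findInterval(single$col, breaks)
  for (p in panel) {
    mrows <- model[model$protein == p, , drop = FALSE]
    idx <- match(paste(single$time_index, region),
                 paste(mrows$time_index, mrows$region))
    if (anyNA(idx))
      stop("background model does not cover every (window, region) present",
           call. = FALSE)
    theta <- mrows$threshold[idx]
    raw <- single[[p]]
    gated <- ifelse(raw > theta, raw, 0)
    out[[paste0(p, "_raw")]] <- gated
    out[[paste0(p, "_log2")]] <- log2(gated + 1)
    out[[paste0(p, "_call")]] <- as.integer(gated > 0)
  }
  rownames(out) <- NULL
  attr(out, "panel") <- panel
  out
}
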