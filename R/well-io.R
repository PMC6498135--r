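# Delimited-text I/O for per-well intensity tables and ground truth.
#
# Intensities are written with 17 significant digits so that
# read_well_table(write_well_table(x)) reproduces the doubles exactly.

well_key_cols <- c("chip_id", "time_index", "row", "col", "cell_count")

fmt_double <- function(x) {
  out <- formatC(x, digits = 17, format = "g", width = 1)
  gsub(" ", "", out, fixed = TRUE)
}

#' Write / read a per-well intensity table
#'
#' The table is UTF-8 CSV with header
#' `chip_id,time_index,row,col,cell_count,<protein_1>,...,<protein_K>`, one
#' row per well per time window.  The reader validates the header, rejects
#' negative intensities and duplicated `(chip, time, row, col)` keys, and
#' names the offending line in its error message.
#'
#' @param wells Well table as produced by [simulate_chip()].
#' @param path CSV file path.
#' @return `read_well_table()` returns the well data frame.
#' @export
write_well_table <- function(wells, path) {
  stopifnot(is.data.frame(wells),
            identical(names(wells)[seq_along(well_key_cols)], well_key_cols))
  out <- wells
  for (nm in setdiff(names(out), well_key_cols)) {
    out[[nm]] <- fmt_double(out[[nm]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_well_table
#' @export
read_well_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  n_key <- length(well_key_cols)
  if (ncol(df) < n_key ||
      !identical(names(df)[seq_len(n_key)], well_key_cols)) {
    stop("malformed well-table header: expected columns ",
         paste(well_key_cols, collapse = ","),
         ",<protein...> but found ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  panel <- names(df)[-seq_len(n_key)]
  if (length(panel) == 0L)
    stop("malformed well-table header: no protein intensity columns",
         call. = FALSE)
  if (nrow(df) == 0L) {
    df$chip_id <- character(0)
    return(df)
  }
  for (nm in c("time_index", "row", "col", "cell_count")) {
    df[[nm]] <- as.integer(df[[nm]])
    bad <- which(is.na(df[[nm]]) | df[[nm]] < 0L)
    if (length(bad))
      stop(sprintf("parse error at line %d: invalid `%s`", bad[1] + 1L, nm),
           call. = FALSE)
  }
  for (nm in panel) {
    df[[nm]] <- as.numeric(df[[nm]])
    bad <- which(is.na(df[[nm]]) | df[[nm]] < 0)
    if (length(bad))
      stop(sprintf("parse error at line %d: negative or non-numeric intensity in `%s`",
                   bad[1] + 1L, nm), call. = FALSE)
  }
  key <- paste(df$chip_id, df$time_index, df$row, df$col, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("parse error at line %d: duplicate (chip, time, row, col) key",
                 dup[1] + 1L), call. = FALSE)
  df
}

#' Write / read the simulation ground truth
#'
#' Companion CSV to the well table, keyed by cell id; used for
#' parameter-recovery tests against the generator.
#'
#' @param truth Ground-truth data frame from [simulate_chip()].
#' @param path CSV file path.
#' @return `read_ground_truth()` returns the data frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  hdr <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  classes <- stats::setNames(rep(NA_character_, length(hdr)), hdr)
  classes[grepl("^(cell_id|state)$|^(mode|calls)_", hdr)] <- "character"
  classes[grepl("^present_t", hdr)] <- "logical"
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE,
                        colClasses = classes)
  df
}
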