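# Polyfunctionality: per-cell function counts, the polyfunctionality index
# (PI), and the coupling of stimulated to basal polyfunctionality.
#
# PI = sum_i F_i (i/n)^q with n = 6 and q = 1 by default, where F_i is the
# percentage of cells performing i functions.  Cells are binned
# 0,1,2,3,4,>=5; the pooled top bin enters the sum with weight i = 5.

#' Per-cell function counts at one time window
#'
#' The function count m of a cell is the number of panel proteins called
#' "secretion" in that window.
#'
#' @param courses Complete `cell_courses`.
#' @param window 0-based window index.
#' @return Data frame with `cell_id` and `n_functions`.
#' @export
function_counts <- function(courses, window) {
  if (!all(courses$complete))
    stop("function counts use complete courses only", call. = FALSE)
  panel <- attr(courses, "panel")
  cols <- sprintf("%s_t%d_call", panel, window)
  if (!all(cols %in% names(courses)))
    stop(sprintf("window %d not present in courses", window), call. = FALSE)
  m <- rowSums(as.matrix(courses[, cols, drop = FALSE]))
  data.frame(cell_id = courses$cell_id, n_functions = as.integer(m),
             stringsAsFactors = FALSE)
}

#' Polyfunctionality index of a population
#'
#' Cells are binned by function count into 0, 1, ..., n-2 and a pooled top
#' bin >= n-1 (with the default cutoff n = 6: bins 0,1,2,3,4,>=5).  The
#' index weights each bin's percentage frequency by (i/n)^q, with the
#' pooled bin at i = n-1, so higher-order cells contribute more.  The
#' alternative linear-in-q reading F_i * i / (n*q) is available via
#' `form = "linear_q"`.
#'
#' @param counts Integer vector of per-cell function counts, or the data
#'   frame from [function_counts()].
#' @param n Function-count cutoff (default 6).
#' @param q Positive weight-modulation exponent (default 1, equal weight).
#' @param form `"power"` for F_i (i/n)^q (default) or `"linear_q"` for
#'   F_i i/(n q).
#' @return List of class `pi_result`: `pi`, `n`, `q`, `form`, and a `bins`
#'   data frame (`i, count, frequency` with frequency in percent).
#' @examples
#' # Population split over bins 0..5; frequencies sum to 100
#' polyfunctionality_index(rep(0:5, c(94, 360, 548, 427, 228, 95)))
#' @export
polyfunctionality_index <- function(counts, n = 6L, q = 1,
                                    form = c("power", "linear_q")) {
  form <- match.arg(form)
  if (is.data.frame(counts)) counts <- counts$n_functions
  if (length(counts) == 0L) stop("no cells to index", call. = FALSE)
  if (any(counts < 0) || anyNA(counts))
    stop("function counts must be non-negative", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (q < 0) stop("`q` must be non-negative", call. = FALSE)
  binned <- pmin(as.integer(counts), n - 1L)
  tab <- tabulate(binned + 1L, nbins = n)
  freq <- 100 * tab / length(counts)
  i <- seq_len(n) - 1L
  w <- if (form == "power") (i / n)^q else i / (n * q)
  out <- list(pi = sum(freq * w), n = n, q = q, form = form,
              bins = data.frame(i = i, count = tab, frequency = freq))
  class(out) <- "pi_result"
  out
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf("Polyfunctionality index: %.2f (n = %d, q = %g, %s form)\n",
              x$pi, x$n, x$q, x$form))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Coupling of stimulated to basal polyfunctionality
#'
#' Cells are grouped by basal (window 0) function count into bins
#' 0,1,2,3,4,>=5.  For each stimulated window, the mean stimulated function
#' count per basal bin is regressed (ordinary least squares) on the bin's
#' basal count (the pooled bin uses its within-bin mean basal count).
#' Welch two-sample t-tests compare the stimulated counts of neighbouring
#' basal bins.
#'
#' @param courses Complete `cell_courses` with the basal window at index 0.
#' @param max_bin Basal counts >= `max_bin` are pooled (default 5).
#' @return List of class `basal_coupling_fit` with elements `fits`
#'   (window, slope, intercept, r_squared), `bin_means` (window, bin,
#'   basal_mean, mean_stimulated, n_cells) and `neighbor_tests` (window,
#'   bin_a, bin_b, p_value).
#' @export
basal_coupling <- function(courses, max_bin = 5L) {
  n_t <- attr(courses, "n_timepoints")
  if (n_t < 2L) stop("need at least one stimulated window", call. = FALSE)
  basal <- function_counts(courses, 0L)$n_functions
  bin <- pmin(basal, max_bin)
  occupied <- sort(unique(bin))
  if (length(occupied) < 3L)
    stop("fit error: fewer than 3 non-empty basal bins", call. = FALSE)
  fits <- list(); means <- list(); tests <- list()
  for (t in seq_len(n_t - 1L)) {
    m_t <- function_counts(courses, t)$n_functions
    x <- tapply(basal, bin, mean)          # pooled bin at its mean count
    y <- tapply(m_t, bin, mean)
    n_b <- tapply(m_t, bin, length)
    fit <- stats::lm(y ~ x)
    sse <- sum(stats::residuals(fit)^2)
    sst <- sum((y - mean(y))^2)
    fits[[t]] <- data.frame(
      window = t,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r_squared = if (sst > 0) 1 - sse / sst else NA_real_)
    means[[t]] <- data.frame(
      window = t, bin = as.integer(names(y)),
      basal_mean = as.numeric(x), mean_stimulated = as.numeric(y),
      n_cells = as.integer(n_b))
    pr <- lapply(seq_len(length(occupied) - 1L), function(j) {
      a <- occupied[j]; b <- occupied[j + 1L]
      ga <- m_t[bin == a]; gb <- m_t[bin == b]
      p <- if (length(ga) > 1L && length(gb) > 1L &&
               (stats::var(ga) > 0 || stats::var(gb) > 0))
        stats::t.test(ga, gb)$p.value else NA_real_
      data.frame(window = t, bin_a = a, bin_b = b, p_value = p)
    })
    tests[[t]] <- do.call(rbind, pr)
  }
  out <- list(fits = do.call(rbind, fits),
              bin_means = do.call(rbind, means),
              neighbor_tests = do.call(rbind, tests))
  class(out) <- "basal_coupling_fit"
  out
}

#' @export
print.basal_coupling_fit <- function(x, ...) {
  cat("Binned OLS of mean stimulated on basal polyfunctionality\n")
  print(x$fits, row.names = FALSE)
  invisible(x)
}
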