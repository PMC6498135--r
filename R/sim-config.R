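#' Default 10-plex secreted-protein panel
#'
#' Cytokines and chemokines typical of an LPS-stimulated human macrophage
#' secretion panel measured on an antibody-barcode microtrough chip.
#'
#' @return Character vector of 10 protein names.
#' @export
default_panel <- function() {
  c("CXCL8", "IL6", "CCL2", "TNF", "IL10",
    "CCL4", "CCL3", "IL1B", "GMCSF", "CCL5")
}

#' Dynamic-mode labels used by the generator and classifier
#'
#' The generator distinguishes silent and oscillatory sub-modes of the
#' "other" class; the classifier reports the four observable patterns
#' (see [classify_pattern()]).
#'
#' @name mode_labels
#' @export
generator_modes <- function() {
  c("ALL_ON", "ON_OFF", "OFF_ON", "OTHER_silent", "OTHER_oscillate")
}

#' @rdname mode_labels
#' @export
pattern_labels <- function() {
  c("ALL_ON", "ON_OFF", "OFF_ON", "OTHER")
}

#' Default per-state dynamic-mode probabilities
#'
#' One probability vector over the five generator modes per protein and per
#' latent basal state ("low", "high").  The high-basal state is more active
#' both at rest and after stimulation.  For CCL2, TNF and IL-6 the
#' low/high mixture at the default `state_mix = 0.35` reproduces the
#' population pattern fractions observed for these proteins in LPS-activated
#' macrophages (CCL2 all-on ~71%, TNF on-off ~13.4% vs off-on ~4.7%,
#' IL-6 off-on ~7.1% vs on-off ~0.6%).
#'
#' @param panel Character vector of protein names (default [default_panel()]).
#' @return Named list with `low` and `high` K x 5 probability matrices.
#' @export
default_mode_probs <- function(panel = default_panel()) {
  modes <- generator_modes()
  low <- rbind(
    CXCL8 = c(0.0100, 0.0100, 0.2800, 0.6000, 0.1000),
    IL6   = c(0.0000, 0.0060, 0.0285, 0.9000, 0.0655),
    CCL2  = c(0.5715, 0.1162, 0.1900, 0.0700, 0.0523),
    TNF   = c(0.0050, 0.0446, 0.0185, 0.8000, 0.1319),
    IL10  = c(0.0000, 0.0050, 0.0750, 0.8700, 0.0500),
    CCL4  = c(0.0500, 0.0500, 0.1500, 0.6500, 0.1000),
    CCL3  = c(0.0300, 0.0400, 0.1300, 0.7000, 0.1000),
    IL1B  = c(0.0100, 0.0100, 0.0800, 0.8500, 0.0500),
    GMCSF = c(0.0050, 0.0050, 0.0400, 0.9000, 0.0500),
    CCL5  = c(0.0200, 0.0200, 0.0600, 0.8500, 0.0500)
  )
  high <- rbind(
    CXCL8 = c(0.5000, 0.0200, 0.4500, 0.0100, 0.0200),
    IL6   = c(0.1000, 0.0060, 0.1500, 0.4000, 0.3440),
    CCL2  = c(0.9700, 0.0100, 0.0100, 0.0050, 0.0050),
    TNF   = c(0.3000, 0.3000, 0.1000, 0.0500, 0.2500),
    IL10  = c(0.1500, 0.0100, 0.6000, 0.1400, 0.1000),
    CCL4  = c(0.7500, 0.1000, 0.1000, 0.0200, 0.0300),
    CCL3  = c(0.7000, 0.0800, 0.1500, 0.0200, 0.0500),
    IL1B  = c(0.3500, 0.0500, 0.4000, 0.1000, 0.1000),
    GMCSF = c(0.2500, 0.0500, 0.4000, 0.2000, 0.1000),
    CCL5  = c(0.4000, 0.0500, 0.3500, 0.1000, 0.1000)
  )
  colnames(low) <- colnames(high) <- modes
  default <- default_panel()
  pick <- function(m) {
    out <- m[match(panel, default), , drop = FALSE]
    # proteins outside the default panel get a generic moderately active mix
    miss <- is.na(out[, 1])
    if (any(miss)) out[miss, ] <- rep(c(0.10, 0.05, 0.25, 0.45, 0.15),
                                      each = sum(miss))
    rownames(out) <- panel
    out
  }
  list(low = pick(low), high = pick(high))
}

#' Simulation configuration for the microtrough chip generator
#'
#' Bundles every parameter of the synthetic measurement model: Poisson cell
#' loading, the two latent basal states and their per-protein dynamic-mode
#' probabilities, basal-to-stimulated activation coupling, lognormal
#' secretion signal, truncated-normal optical background, and per-exchange
#' cell retention.
#'
#' @param n_wells Number of microtroughs on the chip (default 18000).
#' @param loading_rate Mean cells per well of the Poisson loading process
#'   (default 0.5, which puts ~30.3% of wells at exactly one cell).
#' @param n_timepoints Number of 2-h assay windows, window 0 being the
#'   pre-stimulation basal window (default 4).
#' @param panel Protein names, length K (default [default_panel()]).
#' @param retention_p Probability a cell survives each antibody-slide
#'   exchange (default 0.56).
#' @param state_mix Proportion of cells in the high-basal latent state
#'   (default 0.35).
#' @param mode_probs List with `low`/`high` K x 5 matrices of mode
#'   probabilities (default [default_mode_probs()]).
#' @param background_mean,background_sd Per-protein truncated-normal
#'   background parameters in photon counts; recycled to length K.
#' @param signal_logmean,signal_logsd Per-protein lognormal secretion-signal
#'   parameters (log photon counts); recycled to length K.
#' @param basal_coupling Logit shift of stimulated-phase activation per
#'   basal-active protein (default 0.5); 0 disables the coupling.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return Object of class `sim_config` (a validated named list).
#' @seealso [simulate_chip()]
#' @export
sim_config <- function(n_wells = 18000L,
                       loading_rate = 0.5,
                       n_timepoints = 4L,
                       panel = default_panel(),
                       retention_p = 0.56,
                       state_mix = 0.35,
                       mode_probs = default_mode_probs(panel),
                       background_mean = c(155, 140, 170, 150, 135,
                                           160, 145, 150, 165, 130),
                       background_sd = 25,
                       signal_logmean = 8.0,
                       signal_logsd = 0.6,
                       basal_coupling = 0.5,
                       seed = NULL) {
  K <- length(panel)
  cfg <- structure(list(
    n_wells = as.integer(n_wells),
    loading_rate = loading_rate,
    n_timepoints = as.integer(n_timepoints),
    panel = as.character(panel),
    retention_p = retention_p,
    state_mix = state_mix,
    mode_probs = mode_probs,
    background_mean = rep_len(background_mean, K),
    background_sd = rep_len(background_sd, K),
    signal_logmean = rep_len(signal_logmean, K),
    signal_logsd = rep_len(signal_logsd, K),
    basal_coupling = basal_coupling,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param config A `sim_config` or compatible named list.
#' @return The validated config, invisibly usable.
#' @export
validate_sim_config <- function(config) {
  stopifnot(is.list(config))
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(config$loading_rate) || config$loading_rate <= 0)
    stop("`loading_rate` must be a positive finite number", call. = FALSE)
  if (!num_ok(config$retention_p) ||
      config$retention_p < 0 || config$retention_p > 1)
    stop("`retention_p` must lie in [0, 1]", call. = FALSE)
  if (!num_ok(config$state_mix) || config$state_mix < 0 || config$state_mix > 1)
    stop("`state_mix` must lie in [0, 1]", call. = FALSE)
  if (config$n_timepoints < 2L)
    stop("`n_timepoints` must be at least 2", call. = FALSE)
  if (config$n_wells < 1L)
    stop("`n_wells` must be positive", call. = FALSE)
  K <- length(config$panel)
  if (K < 1L || anyDuplicated(config$panel))
    stop("`panel` must be a non-empty set of unique protein names",
         call. = FALSE)
  for (nm in c("background_mean", "background_sd",
               "signal_logmean", "signal_logsd")) {
    x <- config[[nm]]
    if (!num_ok(x) || length(x) != K)
      stop(sprintf("`%s` must be finite and of panel length", nm),
           call. = FALSE)
  }
  if (any(config$background_mean < 0) || any(config$background_sd < 0))
    stop("background parameters must be non-negative", call. = FALSE)
  if (any(config$signal_logsd < 0))
    stop("`signal_logsd` must be non-negative", call. = FALSE)
  if (!num_ok(config$basal_coupling))
    stop("`basal_coupling` must be finite", call. = FALSE)
  mp <- config$mode_probs
  if (!is.list(mp) || !all(c("low", "high") %in% names(mp)))
    stop("`mode_probs` must be a list with `low` and `high` matrices",
         call. = FALSE)
  for (st in c("low", "high")) {
    m <- mp[[st]]
    if (!is.matrix(m) || nrow(m) != K || ncol(m) != 5L)
      stop(sprintf("`mode_probs$%s` must be a K x 5 matrix", st),
           call. = FALSE)
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
      stop(sprintf("each row of `mode_probs$%s` must be a probability vector summing to 1", st),
           call. = FALSE)
  }
  config
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML form stores the per-state mode-probability matrices as nested
#' per-protein maps, so configs are human-editable.
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  config <- validate_sim_config(config)
  lst <- unclass(config)
  lst$mode_probs <- lapply(lst$mode_probs, function(m) {
    rows <- lapply(seq_len(nrow(m)), function(i) as.list(stats::setNames(m[i, ], colnames(m))))
    stats::setNames(rows, rownames(m))
  })
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  modes <- generator_modes()
  lst$mode_probs <- lapply(lst$mode_probs, function(st) {
    m <- do.call(rbind, lapply(st, function(r) unlist(r)[modes]))
    rownames(m) <- names(st)
    colnames(m) <- modes
    m[lst$panel, , drop = FALSE]
  })
  cfg <- do.call(sim_config, lst)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Microtrough chip simulation config\n")
  cat(sprintf("  wells: %d  loading rate: %.3g cells/well  windows: %d\n",
              x$n_wells, x$loading_rate, x$n_timepoints))
  cat(sprintf("  panel (K=%d): %s\n", length(x$panel),
              paste(x$panel, collapse = ", ")))
  cat(sprintf("  retention/exchange: %.3g  high-basal fraction: %.3g  coupling: %.3g\n",
              x$retention_p, x$state_mix, x$basal_coupling))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
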