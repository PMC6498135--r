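# Synthetic generator for the sequential microtrough secretion assay.
#
# Measurement model, per chip:
#   * wells are loaded Poisson(loading_rate); bright-field imaging records
#     cell_count per well at every window;
#   * each cell carries a latent basal state (low/high) and, per protein, a
#     dynamic secretion mode drawn from the state's mode probabilities;
#   * raw well intensity = truncated-normal optical background plus, for
#     every resident cell secreting that protein in that window, a lognormal
#     signal draw;
#   * after each window the antibody slide is exchanged; each cell survives
#     the exchange with probability retention_p, and a lost cell vanishes
#     from later bright-field counts and contributes no further signal.

# restore the caller-visible RNG state when the calling function exits
restore_rng_on_exit <- function(envir = parent.frame()) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    expr <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    expr <- quote(if (exists(".Random.seed", envir = globalenv(),
                             inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
}

# normal truncated at zero via inverse-CDF (exact, vectorised)
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

# binary sequences of length T with a fixed first bit and >= 2 transitions
r_oscillating_calls <- function(n, n_timepoints, first_bit) {
  out <- matrix(0L, n, n_timepoints)
  if (n == 0L) return(out)
  out[, 1L] <- first_bit
  todo <- seq_len(n)
  while (length(todo)) {
    rest <- matrix(stats::rbinom(length(todo) * (n_timepoints - 1L), 1L, 0.5),
                   nrow = length(todo))
    cand <- cbind(out[todo, 1L], rest)
    transitions <- rowSums(abs(cand[, -1L, drop = FALSE] -
                               cand[, -ncol(cand), drop = FALSE]))
    ok <- transitions >= 2L
    if (any(ok)) out[todo[ok], ] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  out
}

#' Simulate one sequential secretion chip
#'
#' Generates per-well raw intensity tables for every time window together
#' with the per-cell ground truth (latent state, true dynamic mode per
#' protein, true secretion schedule, retention history).
#'
#' The basal-to-stimulated coupling is generated in two phases so that the
#' realized mode frequencies equal `mode_probs` exactly when
#' `basal_coupling = 0`: phase 1 draws each protein's basal activity from
#' the state's marginal mode probabilities; phase 2 draws the
#' stimulated-phase mode conditionally, shifting the conditional log-odds
#' of the persistently active option (ALL_ON within the basal-active
#' family, OFF_ON within the basal-silent family) by
#' `basal_coupling` x (number of basal-active proteins of that cell).
#'
#' @param config A [sim_config()].
#' @return List with `wells` (data frame, one row per well per window:
#'   `chip_id, time_index, row, col, cell_count`, one raw-intensity column
#'   per panel protein) and `truth` (data frame, one row per simulated
#'   cell: id, well coordinates, latent state, basal-active count, per
#'   protein the true mode and true call string, and per-window presence
#'   flags).
#' @examples
#' sim <- simulate_chip(sim_config(n_wells = 400, seed = 7))
#' table(subset(sim$wells, time_index == 0)$cell_count)
#' @export
simulate_chip <- function(config) {
  config <- validate_sim_config(config)
  if (!is.null(config$seed)) {
    restore_rng_on_exit()
    set.seed(config$seed)
  }
  n_wells <- config$n_wells
  n_t <- config$n_timepoints
  panel <- config$panel
  K <- length(panel)
  modes <- generator_modes()
  grid_cols <- 120L
  well_row <- (seq_len(n_wells) - 1L) %/% grid_cols
  well_col <- (seq_len(n_wells) - 1L) %% grid_cols

  counts0 <- stats::rpois(n_wells, config$loading_rate)
  n_cells <- sum(counts0)
  well_of <- rep.int(seq_len(n_wells), counts0)
  state <- ifelse(stats::runif(n_cells) < config$state_mix, "high", "low")
  is_high <- state == "high"

  # phase 1: family + basal activity per protein
  #   family 1 = basal-active stable (ALL_ON / ON_OFF)
  #   family 2 = basal-silent stable (OFF_ON / silent)
  #   family 3 = oscillatory (random basal bit)
  fam <- matrix(0L, n_cells, K)
  basal <- matrix(0L, n_cells, K)
  probs_for <- function(k) {
    rbind(low = config$mode_probs$low[k, ], high = config$mode_probs$high[k, ])
  }
  for (k in seq_len(K)) {
    p <- probs_for(k)
    f1 <- p[, "ALL_ON"] + p[, "ON_OFF"]
    f2 <- p[, "OFF_ON"] + p[, "OTHER_silent"]
    st <- ifelse(is_high, 2L, 1L)
    u <- stats::runif(n_cells)
    fk <- ifelse(u < f1[st], 1L, ifelse(u < f1[st] + f2[st], 2L, 3L))
    bk <- as.integer(fk == 1L)
    osc <- fk == 3L
    if (any(osc)) bk[osc] <- stats::rbinom(sum(osc), 1L, 0.5)
    fam[, k] <- fk
    basal[, k] <- bk
  }
  basal_count <- rowSums(basal)

  # phase 2: stimulated-phase mode, tilted by the basal-coupling slope
  cpl <- config$basal_coupling
  mode_idx <- matrix(0L, n_cells, K)
  calls <- array(0L, c(n_cells, n_t, K))
  for (k in seq_len(K)) {
    p <- probs_for(k)
    st <- ifelse(is_high, 2L, 1L)
    f1 <- (p[, "ALL_ON"] + p[, "ON_OFF"])[st]
    f2 <- (p[, "OFF_ON"] + p[, "OTHER_silent"])[st]
    cond_all <- ifelse(f1 > 0, p[st, "ALL_ON"] / f1, 0)
    cond_offon <- ifelse(f2 > 0, p[st, "OFF_ON"] / f2, 0)
    p_all <- stats::plogis(stats::qlogis(cond_all) + cpl * basal_count)
    p_offon <- stats::plogis(stats::qlogis(cond_offon) + cpl * basal_count)
    u <- stats::runif(n_cells)
    mk <- integer(n_cells)
    i1 <- fam[, k] == 1L
    i2 <- fam[, k] == 2L
    i3 <- fam[, k] == 3L
    mk[i1] <- ifelse(u[i1] < p_all[i1], 1L, 2L)          # ALL_ON / ON_OFF
    mk[i2] <- ifelse(u[i2] < p_offon[i2], 3L, 4L)        # OFF_ON / silent
    mk[i3] <- 5L
    ck <- matrix(0L, n_cells, n_t)
    ck[mk == 1L, ] <- 1L
    if (any(mk == 2L)) {  # leading ones, uniform switch-off time
      lead <- sample.int(n_t - 1L, sum(mk == 2L), replace = TRUE)
      ck[mk == 2L, ] <- outer(lead, seq_len(n_t), ">=") + 0L
    }
    if (any(mk == 3L)) {  # leading zeros, uniform switch-on time
      zeros <- sample.int(n_t - 1L, sum(mk == 3L), replace = TRUE)
      ck[mk == 3L, ] <- outer(zeros, seq_len(n_t), "<") + 0L
    }
    if (any(mk == 5L)) {
      if (n_t >= 3L) {
        ck[mk == 5L, ] <- r_oscillating_calls(sum(mk == 5L), n_t,
                                              basal[mk == 5L, k])
      } else {
        mk[mk == 5L] <- 4L  # oscillation needs >= 3 windows
      }
    }
    mode_idx[, k] <- mk
    calls[, , k] <- ck
  }

  # retention through slide exchanges
  present <- matrix(TRUE, n_cells, n_t)
  for (t in seq_len(n_t - 1L)) {
    present[, t + 1L] <- present[, t] &
      (stats::runif(n_cells) < config$retention_p)
  }

  # well intensities: background + sum of resident secreting cells
  intens <- array(0, c(n_wells, n_t, K))
  for (k in seq_len(K)) {
    bg <- matrix(rtnorm0(n_wells * n_t, config$background_mean[k],
                         config$background_sd[k]),
                 n_wells, n_t)
    wsum <- matrix(0, n_wells, n_t)
    if (n_cells > 0L) {
      sig <- matrix(0, n_cells, n_t)
      act <- (calls[, , k] == 1L) & present
      n_act <- sum(act)
      if (n_act > 0L) {
        sig[act] <- stats::rlnorm(n_act, config$signal_logmean[k],
                                  config$signal_logsd[k])
      }
      agg <- rowsum(sig, group = well_of)
      wsum[as.integer(rownames(agg)), ] <- agg
    }
    intens[, , k] <- bg + wsum
  }

  occ <- matrix(0L, n_wells, n_t)
  if (n_cells > 0L) {
    pc <- rowsum(present + 0L, group = well_of)
    occ[as.integer(rownames(pc)), ] <- pc
  }

  wells <- data.frame(
    chip_id = "chip1",
    time_index = rep(0:(n_t - 1L), each = n_wells),
    row = rep(well_row, n_t),
    col = rep(well_col, n_t),
    cell_count = as.vector(occ),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(K)) wells[[panel[k]]] <- as.vector(intens[, , k])

  within_well <- sequence(counts0)
  truth <- data.frame(
    cell_id = if (n_cells > 0L)
      sprintf("c_r%d_c%d_%d", well_row[well_of], well_col[well_of],
              within_well) else character(0),
    row = well_row[well_of],
    col = well_col[well_of],
    state = state,
    basal_count = basal_count,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(K)) {
    truth[[paste0("mode_", panel[k])]] <- modes[mode_idx[, k]]
    truth[[paste0("calls_", panel[k])]] <- if (n_cells > 0L)
      apply(calls[, , k, drop = FALSE], 1L, paste0, collapse = "")
    else character(0)
  }
  for (t in seq_len(n_t)) {
    truth[[sprintf("present_t%d", t - 1L)]] <- present[, t]
  }

  list(wells = wells, truth = truth, config = config)
}
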