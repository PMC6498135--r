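# Shared fixtures: small generator configs and a sim -> gate -> track
# convenience wrapper.  All fixtures are built in code at test time.

# mode probabilities with the three study proteins pinned to their
# population pattern fractions, identical in both states (used with
# basal_coupling = 0 to isolate classification recovery)
recovery_mode_probs <- function(panel = default_panel()) {
  mp <- default_mode_probs(panel)
  pinned <- rbind(
    CCL2 = c(0.711, 0.079, 0.100, 0.060, 0.050),
    TNF  = c(0.050, 0.134, 0.047, 0.469, 0.300),
    IL6  = c(0.040, 0.006, 0.071, 0.583, 0.300))
  for (st in c("low", "high")) {
    for (p in rownames(pinned)) mp[[st]][p, ] <- pinned[p, ]
  }
  mp
}

recovery_config <- function(seed, n_wells = 8000L, ...) {
  sim_config(n_wells = n_wells, retention_p = 1, basal_coupling = 0,
             mode_probs = recovery_mode_probs(), seed = seed, ...)
}

# run simulate -> fit -> gate -> link and return pieces
run_to_courses <- function(config) {
  sim <- simulate_chip(config)
  model <- fit_background(sim$wells)
  gated <- gate_cells(sim$wells, model)
  courses <- link_time_courses(gated, n_timepoints = config$n_timepoints)
  list(sim = sim, model = model, gated = gated, courses = courses,
       complete = complete_courses(courses))
}

# latent state of each course's cell, looked up in the ground truth
truth_states <- function(courses, truth) {
  truth$state[match(paste(courses$row, courses$col),
                    paste(truth$row, truth$col))]
}

# fraction of cells whose cluster label matches the latent state, after
# the best of the two label alignments
state_recovery <- function(labels, states) {
  tb <- table(labels, states)
  max(sum(diag(tb)), tb[1, 2] + tb[2, 1]) / length(states)
}

# independent regex oracle for the pattern classifier
regex_pattern_oracle <- function(calls) {
  s <- paste(calls, collapse = "")
  if (grepl("^1+$", s)) "ALL_ON"
  else if (grepl("^1+0+$", s)) "ON_OFF"
  else if (grepl("^0+1+$", s)) "OFF_ON"
  else "OTHER"
}

# tiny hand-built well table: 3 wells x K proteins at one window
toy_wells <- function(panel = c("A", "B")) {
  df <- data.frame(chip_id = "chip1", time_index = 0L,
                   row = c(0L, 0L, 1L), col = c(0L, 1L, 0L),
                   cell_count = c(0L, 1L, 2L), stringsAsFactors = FALSE)
  for (p in panel) df[[p]] <- c(100, 250, 300)
  df
}
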