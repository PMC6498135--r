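# Zero-cell background fitting and threshold gating.

test_that("background mean/SD/threshold match hand-computed values", {
  wells <- data.frame(chip_id = "chip1", time_index = 0L,
                      row = 0:3, col = 0L,
                      cell_count = c(0L, 0L, 0L, 1L),
                      P = c(90, 100, 110, 500))
  model <- fit_background(wells, time_index = 0L)
  expect_equal(model$background_mean, 100)
  expect_equal(model$background_sd, 10)   # sample SD, denominator n-1
  expect_equal(model$threshold, 130)
  expect_equal(model$n_zero_wells, 3L)

  # identical controls collapse the threshold onto the constant
  wells$P[wells$cell_count == 0L] <- 42
  model <- fit_background(wells, time_index = 0L)
  expect_equal(model$threshold, 42)
})

test_that("background fitting requires at least two zero-cell wells", {
  wells <- toy_wells()
  wells$cell_count <- c(1L, 1L, 2L)
  expect_error(fit_background(wells, 0L), "gating error")
})

test_that("fitted background recovers the generator's noise parameters", {
  cfg <- sim_config(n_wells = 12000L, seed = 55)
  sim <- simulate_chip(cfg)
  model <- fit_background(sim$wells, time_index = 0L)
  for (k in seq_along(cfg$panel)) {
    row <- model[model$protein == cfg$panel[k], ]
    n0 <- row$n_zero_wells
    se_mean <- cfg$background_sd[k] / sqrt(n0)
    se_sd <- cfg$background_sd[k] / sqrt(2 * (n0 - 1))
    expect_lt(abs(row$background_mean - cfg$background_mean[k]), 3 * se_mean)
    expect_lt(abs(row$background_sd - cfg$background_sd[k]), 3 * se_sd)
  }
})

test_that("gating zeroes at-or-below-threshold values and keeps the rest", {
  wells <- data.frame(chip_id = "chip1", time_index = 0L,
                      row = 0:4, col = 0L,
                      cell_count = c(0L, 0L, 0L, 1L, 1L),
                      P = c(100, 130, 160, 129, 255))
  # controls {100,130,160}: mean 130, sd 30 -> threshold 220
  model <- fit_background(wells, 0L)
  expect_equal(model$threshold, 220)
  wells$P[4:5] <- c(129, 255)
  gated <- gate_cells(wells, model)
  expect_equal(nrow(gated), 2L)
  expect_equal(gated$P_raw, c(0, 255))
  expect_equal(gated$P_log2, c(0, 8))    # log2(255 + 1)
  expect_equal(gated$P_call, c(0L, 1L))

  # a value exactly at threshold is "no secretion"
  wells$P[4] <- 220
  gated <- gate_cells(wells, model)
  expect_equal(gated$P_call[1], 0L)

  # multi-cell wells never emit records
  wells$cell_count[5] <- 2L
  gated <- gate_cells(wells, model)
  expect_equal(nrow(gated), 1L)
})

test_that("gating is idempotent and monotone", {
  cfg <- sim_config(n_wells = 1500L, seed = 77)
  sim <- simulate_chip(cfg)
  model <- fit_background(sim$wells)
  g1 <- gate_cells(sim$wells, model)

  # feed the gated raw values back through the same thresholds
  regated <- sim$wells[sim$wells$cell_count == 1L, ]
  for (p in cfg$panel) regated[[p]] <- g1[[paste0(p, "_raw")]]
  g2 <- gate_cells(regated, model)
  for (p in cfg$panel) {
    expect_equal(g2[[paste0(p, "_raw")]], g1[[paste0(p, "_raw")]])
    expect_equal(g2[[paste0(p, "_call")]], g1[[paste0(p, "_call")]])
  }

  # monotone: raising a raw value never lowers the gated value or call
  theta <- model$threshold[model$time_index == 0L][1]
  p1 <- cfg$panel[1]
  w <- sim$wells[sim$wells$time_index == 0L & sim$wells$cell_count == 1L, ][1, ]
  grid <- sort(c(0, theta / 2, theta - 1, theta, theta + 1e-6, theta * 2))
  gated_raw <- vapply(grid, function(r) {
    w[[p1]] <- r
    gate_cells(w, model)[[paste0(p1, "_raw")]]
  }, 0)
  expect_true(all(diff(gated_raw) >= 0))
  expect_true(all(gated_raw %in% c(0, grid)))
})

test_that("false-positive calls on secretion-free chips stay at the 3-sigma tail rate", {
  mp <- default_mode_probs()
  for (st in c("low", "high")) {
    mp[[st]][, ] <- 0
    mp[[st]][, "OTHER_silent"] <- 1
  }
  cfg <- sim_config(n_wells = 18000L, loading_rate = 0.5, mode_probs = mp,
                    retention_p = 1, basal_coupling = 0, seed = 202)
  sim <- simulate_chip(cfg)
  model <- fit_background(sim$wells)
  gated <- gate_cells(sim$wells, model)
  n_rec <- nrow(gated)
  expect_gt(n_rec, 5000 * 4)
  for (p in cfg$panel) {
    fp <- mean(gated[[paste0(p, "_call")]])
    expect_lte(fp, 0.002)   # normal upper tail beyond mean + 3 SD, with slack
  }
})

test_that("region-blocked background fits cover every well", {
  cfg <- sim_config(n_wells = 6000L, seed = 404)
  sim <- simulate_chip(cfg)
  model <- fit_background(sim$wells, region_blocks = 3L)
  expect_equal(length(unique(model$region)), 3L)
  gated <- gate_cells(sim$wells, model)
  expect_equal(nrow(gated), sum(sim$wells$cell_count == 1L))
})
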