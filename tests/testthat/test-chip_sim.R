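# Generator: Poisson loading, retention, mode frequencies, determinism,
# and well-table round trips.

test_that("well occupancy follows the Poisson loading distribution", {
  cfg <- sim_config(n_wells = 18000L, loading_rate = 0.5, seed = 101)
  sim <- simulate_chip(cfg)
  w0 <- sim$wells[sim$wells$time_index == 0L, ]
  expect_equal(nrow(w0), 18000L)

  # single-cell fraction vs the analytic lambda * exp(-lambda)
  p1 <- 0.5 * exp(-0.5)
  frac1 <- mean(w0$cell_count == 1L)
  expect_lt(abs(frac1 - p1), 3 * sqrt(p1 * (1 - p1) / 18000))

  # full histogram for counts 0..5 within 3 sigma multinomial error
  for (j in 0:5) {
    pj <- dpois(j, 0.5)
    fj <- mean(w0$cell_count == j)
    expect_lt(abs(fj - pj), 3 * sqrt(pj * (1 - pj) / 18000) + 1e-12)
  }
})

test_that("no cell is lost when retention is 1 and all are kept through T windows", {
  cfg <- sim_config(n_wells = 1000L, retention_p = 1, seed = 7)
  sim <- simulate_chip(cfg)
  pres <- as.matrix(sim$truth[, grep("^present_t", names(sim$truth))])
  expect_true(all(pres))
  # bright-field counts constant across windows
  counts <- tapply(sim$wells$cell_count, sim$wells$time_index, sum)
  expect_true(all(counts == counts[[1]]))
})

test_that("observed per-exchange retention matches retention_p", {
  cfg <- sim_config(n_wells = 6000L, retention_p = 0.56, seed = 31)
  sim <- simulate_chip(cfg)
  pres <- as.matrix(sim$truth[, grep("^present_t", names(sim$truth))])
  for (e in 1:3) {
    before <- sum(pres[, e])
    kept <- sum(pres[, e] & pres[, e + 1])
    expect_gt(before, 500)
    expect_lt(abs(kept / before - 0.56),
              3 * sqrt(0.56 * 0.44 / before))
  }
})

test_that("realized mode frequencies match mode_probs when coupling is off", {
  cfg <- recovery_config(seed = 17, n_wells = 6000L)
  sim <- simulate_chip(cfg)
  n <- nrow(sim$truth)
  expect_gt(n, 1500)
  nominal <- list(
    CCL2 = c(ALL_ON = 0.711, ON_OFF = 0.079, OFF_ON = 0.100,
             OTHER_silent = 0.060, OTHER_oscillate = 0.050),
    TNF = c(ALL_ON = 0.050, ON_OFF = 0.134, OFF_ON = 0.047,
            OTHER_silent = 0.469, OTHER_oscillate = 0.300))
  for (p in names(nominal)) {
    realized <- table(sim$truth[[paste0("mode_", p)]]) / n
    for (m in names(nominal[[p]])) {
      pm <- nominal[[p]][[m]]
      rm_ <- if (m %in% names(realized)) realized[[m]] else 0
      expect_lt(abs(rm_ - pm), 3 * sqrt(pm * (1 - pm) / n) + 1e-12)
    }
  }
})

test_that("ground-truth call sequences are consistent with the recorded mode", {
  cfg <- sim_config(n_wells = 1500L, seed = 23)
  sim <- simulate_chip(cfg)
  for (p in c("CCL2", "TNF", "GMCSF")) {
    calls <- sim$truth[[paste0("calls_", p)]]
    mode <- sim$truth[[paste0("mode_", p)]]
    lab <- vapply(strsplit(calls, ""),
                  function(x) regex_pattern_oracle(as.integer(x)), "")
    expect_true(all(lab[mode == "ALL_ON"] == "ALL_ON"))
    expect_true(all(lab[mode == "ON_OFF"] == "ON_OFF"))
    expect_true(all(lab[mode == "OFF_ON"] == "OFF_ON"))
    expect_true(all(lab[mode %in% c("OTHER_silent", "OTHER_oscillate")] ==
                      "OTHER"))
    # silent means silent; oscillatory means >= 2 transitions
    expect_true(all(calls[mode == "OTHER_silent"] == "0000"))
    trans <- vapply(strsplit(calls[mode == "OTHER_oscillate"], ""),
                    function(x) sum(abs(diff(as.integer(x)))), 0)
    expect_true(all(trans >= 2))
  }
})

test_that("the same seed reproduces the simulation bit for bit", {
  cfg <- sim_config(n_wells = 800L, seed = 99)
  a <- simulate_chip(cfg)
  b <- simulate_chip(cfg)
  expect_identical(a$wells, b$wells)
  expect_identical(a$truth, b$truth)
  # and the global RNG state of the session is left untouched
  set.seed(1); before <- .Random.seed
  invisible(simulate_chip(cfg))
  expect_identical(before, .Random.seed)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(loading_rate = -1), "loading_rate")
  expect_error(sim_config(loading_rate = NaN), "loading_rate")
  expect_error(sim_config(retention_p = 1.2), "retention_p")
  expect_error(sim_config(n_timepoints = 1), "n_timepoints")
  expect_error(sim_config(background_sd = -5), "non-negative")
  bad <- default_mode_probs()
  bad$low[1, ] <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(sim_config(mode_probs = bad), "summing to 1")
})

test_that("well tables round-trip through CSV exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  sim <- simulate_chip(sim_config(n_wells = 300L, seed = 3))
  write_well_table(sim$wells, path)
  back <- read_well_table(path)
  expect_equal(back, sim$wells)
  expect_identical(names(back), names(sim$wells))

  # hand-written wells parse literally
  toy <- toy_wells()
  write_well_table(toy, path)
  expect_equal(read_well_table(path), toy)

  # empty table -> header-only file -> empty table
  write_well_table(toy[0, ], path)
  empty <- read_well_table(path)
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty), names(toy))
})

test_that("malformed well tables are rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chip,oops", "x,1"), path)
  expect_error(read_well_table(path), "header")

  writeLines(c("chip_id,time_index,row,col,cell_count,A",
               "chip1,0,0,0,1,50",
               "chip1,0,0,1,1,-3"), path)
  expect_error(read_well_table(path), "line 3.*negative")

  writeLines(c("chip_id,time_index,row,col,cell_count,A",
               "chip1,0,0,0,1,50",
               "chip1,0,0,0,2,60"), path)
  expect_error(read_well_table(path), "line 3.*duplicate")
})

test_that("configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- sim_config(n_wells = 500L, retention_p = 0.8, seed = 12)
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$mode_probs, cfg$mode_probs)
  expect_equal(back$retention_p, cfg$retention_p)
  expect_identical(simulate_chip(back)$wells, simulate_chip(cfg)$wells)
})
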