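test_that("random initialization produces valid, reproducible populations", {
  cfg <- sim_config(1, "minB", n_init = 1, seed = 1)
  st <- withr::with_seed(1, init_population(cfg))
  expect_identical(validate_state(st), character(0))

  cfg2 <- sim_config(1, "minB", n_init = 500, seed = 9)
  a <- withr::with_seed(9, init_population(cfg2))
  b <- withr::with_seed(9, init_population(cfg2))
  expect_identical(a$comp, b$comp)
  expect_identical(a$sites, b$sites)
  # mean chromosome number per cell falls inside the uniform {1,2,3} range
  m <- nrow(a$comp) / nrow(a$cells)
  expect_gt(m, 1); expect_lt(m, 3)
  expect_equal(m, 2, tolerance = 0.1)
})

test_that("a zero-horizon run returns the initial state untouched", {
  run <- run_simulation(sim_config(1, "WT", t_max = 0, n_init = 15, seed = 2))
  expect_equal(nrow(run$events), 0)
  expect_equal(length(unique(run$snapshots$t_min)), 1)
  expect_equal(nrow(run$snapshots), 15)
  expect_equal(run$series$n_cells, 15)
})

test_that("identical seed and config reproduce the event log byte for byte", {
  cfg <- sim_config(3, "minB", t_max = 120, n_init = 30, seed = 77)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_events(r1$events, f1)
  write_events(r2$events, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(r1$series, r2$series)
})

test_that("the invariants hold along a run", {
  run <- run_m3_minb(seed = 1)
  st <- run$final_state
  expect_identical(validate_state(st), character(0))
  expect_true(all(diff(run$series$minicell_count) >= 0))
  expect_true(all(diff(run$series$t_min) > 0))
  # non-polar division conserves chromosome-containing length: total length
  # only ever changes by growth, so per-step log-increments stay positive
  expect_true(all(diff(log(run$series$total_length_nm)) > 0))
})

test_that("bulk growth of a model-1 WT culture doubles every ~75 min", {
  run <- run_m1_wt(seed = 1)
  fit <- fit_bulk_doubling(run$series, c(100, 300))
  expect_equal(fit$doubling_time_min, 75, tolerance = 2 / 75)
  expect_gt(fit$r_squared, 0.999)
})

test_that("steady-state length distribution is independent of n_init", {
  r_small <- run_simulation(sim_config(1, "WT", t_max = 300, n_init = 100,
                                       seed = 21))
  r_big <- run_m1_wt(seed = 1)   # n_init = 200
  ls <- final_snap(r_small)$length_nm
  lb <- final_snap(r_big)$length_nm
  ks <- suppressWarnings(stats::ks.test(ls, lb)$statistic)
  expect_lt(ks, 0.05)
})

test_that("with blocking off and equal polar params, models 2 and 3 agree", {
  p <- div_params(n_block_target = 0, w_polar_mean = 35, w_polar_sd = 25)
  r2 <- run_simulation(sim_config(2, "minB", t_max = 250, n_init = 60,
                                  seed = 31, params = p))
  r3 <- run_simulation(sim_config(3, "minB", t_max = 250, n_init = 60,
                                  seed = 32, params = p))
  w2 <- with(as_tracking(r2), division_t - site_appeared_t)
  w3 <- with(as_tracking(r3), division_t - site_appeared_t)
  expect_gt(length(w2), 1000)
  ks <- suppressWarnings(stats::ks.test(w2, w3))
  expect_gt(ks$p.value, 0.01)
})

test_that("the compartment cap aborts with a partial result", {
  cfg <- sim_config(1, "WT", t_max = 200, n_init = 50, seed = 4,
                    max_compartments = 60)
  expect_warning(run <- run_simulation(cfg), "cap")
  expect_true(run$aborted)
  expect_lt(max(run$series$t_min), 200)
})

test_that("the shared doubling-time variant still grows at the bulk rate", {
  run <- run_simulation(sim_config(1, "WT", t_max = 250, n_init = 60,
                                   seed = 6, shared_Td = TRUE))
  fit <- fit_bulk_doubling(run$series, c(100, 250))
  expect_equal(fit$doubling_time_min, 75, tolerance = 0.02)
})
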