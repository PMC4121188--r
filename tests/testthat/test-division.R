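test_that("waiting-time assignment uses the right distribution per model", {
  p <- div_params()
  # model 4 / WT: wild-type normal for every kind
  w <- withr::with_seed(1, assign_waiting_time(2e4, "nonpolar", 4, "minB", p))
  expect_equal(mean(w), 17.7, tolerance = 0.01)
  expect_equal(stats::sd(w), 11.9, tolerance = 0.02)
  # model 3: polar sites draw from the non-polar distribution (identical
  # generator, so identical draws at the same seed)
  wp <- withr::with_seed(2, assign_waiting_time(1000, "polar", 3, "minB", p))
  wn <- withr::with_seed(2, assign_waiting_time(1000, "nonpolar", 3, "minB", p))
  expect_identical(wp, wn)
  # models 1-2: polar and non-polar differ
  w1p <- withr::with_seed(3, assign_waiting_time(2000, "polar", 1, "minB", p))
  expect_equal(mean(w1p), param(p, "w_polar_mean"), tolerance = 0.1)
  # zero spread collapses to the mean exactly
  pz <- div_params(w_wt_sd = 0)
  expect_identical(assign_waiting_time(5, "nonpolar", 4, "WT", pz),
                   rep(17.7, 5))
})

test_that("progression rate implements machinery competition", {
  p <- div_params()
  expect_equal(progression_rate(4000, 3, 1, "minB"), 1)   # models 1-3: unit
  expect_equal(progression_rate(9999, 7, 2, "WT"), 1)
  # model 4 reference WT geometry: one compartment of length Lc, one site
  expect_equal(progression_rate(param(p, "Lc"), 1, 4, "WT", 1, p), 1)
  # doubling the number of competing sites halves the rate
  f1 <- progression_rate(8000, 2, 4, "minB", 1, p)
  f2 <- progression_rate(8000, 4, 4, "minB", 1, p)
  expect_equal(f2, f1 / 2)
  # doubling FtsZ doubles the rate
  expect_equal(progression_rate(8000, 2, 4, "minB", 2, p), 2 * f1)
  expect_error(progression_rate(8000, 0, 4, "minB"), "n_sites")
})

test_that("models 1-3 progression is an exact countdown", {
  st <- toy_state(t_w = 10)
  st$comp$T_seg <- c(500, 500)  # keep segregation out of the way
  for (i in 1:9) {
    st <- advance_progression(st, 1)
    st <- execute_divisions(st)
    expect_equal(nrow(st$cells), 1)  # not divided yet
  }
  st <- advance_progression(st, 1)
  st <- execute_divisions(st)        # completes exactly at t_w = 10 steps
  expect_equal(nrow(st$cells), 2)
})

test_that("a blocked site accumulates no progression", {
  st <- toy_state(strain = "minB", model = 3)
  st$sites <- rbind(st$sites, data.frame(
    cell_id = 1L, kind = "polar_old", boundary = NA_integer_, blocked = TRUE,
    t_w = NA_real_, s = 0, appeared_at = 0))
  st2 <- advance_progression(st, 5)
  expect_equal(st2$sites$s[st2$sites$blocked], 0)
  expect_equal(st2$sites$s[!st2$sites$blocked], 5)
})

test_that("model-4 progression at constant f = 1/2 doubles realized waiting", {
  p <- div_params()
  # WT geometry with L = Lc/2 and one site gives f = 1/2; freeze growth
  st <- toy_state(L1 = param(p, "Lc") / 4, L2 = param(p, "Lc") / 4,
                  strain = "WT", model = 4, t_w = 10)
  st$comp$T_seg <- c(500, 500)
  steps <- 0
  while (nrow(st$cells) == 1 && steps < 100) {
    st <- advance_progression(st, 1)
    st <- execute_divisions(st)
    steps <- steps + 1
  }
  expect_equal(steps, 20)  # 2 * t_w
})

test_that("non-polar division partitions compartments and conserves length", {
  st <- toy_state(1000, 1500, t_w = 5)
  st$comp$T_seg <- c(500, 500)
  st$sites$s <- 5   # completed
  st2 <- execute_divisions(st)
  expect_equal(nrow(st2$cells), 2)
  expect_equal(sort(st2$cells$length), c(1000, 1500))
  expect_equal(sum(st2$cells$length), 2500)            # conservation
  expect_equal(st2$cells$parent_id, c(1L, 1L))
  expect_equal(st2$cells$L0, st2$cells$length)         # birth length reset
  ev <- do.call(rbind, st2$events)
  expect_equal(nrow(ev), 1)                            # exactly one record
  expect_equal(ev$event, "division")
  expect_identical(validate_state(st2), character(0))
})

test_that("polar division produces a minicell and re-arms the pole", {
  st <- toy_state(strain = "minB", model = 1, t_w = 500)
  st$comp$T_seg <- c(500, 500)
  pole <- data.frame(cell_id = 1L, kind = "polar_old", boundary = NA_integer_,
                     blocked = FALSE, t_w = 3, s = 3, appeared_at = 0)
  st$sites <- rbind(st$sites, pole)
  st$t <- 12
  st2 <- withr::with_seed(1, execute_divisions(st))
  expect_equal(nrow(st2$cells), 1)                     # cell count unchanged
  expect_equal(st2$minicell_count, 1L)
  expect_equal(st2$cells$length, 2500)                 # length unchanged
  re <- st2$sites[st2$sites$kind == "polar_old", ]
  expect_equal(re$s, 0)                                # progression reset
  expect_equal(re$appeared_at, 0)                      # formation time kept
  expect_false(re$t_w == 3)                            # fresh waiting time
  ev <- do.call(rbind, st2$events)
  expect_equal(ev$event, "minicell")
  expect_equal(ev$site_class, "polar_old")
})

test_that("sites carried into daughters keep their waiting time and progress", {
  st <- toy_state(1000, 1500, t_w = 4)
  # three compartments, two sites; divide at boundary 1
  st$comp <- rbind(st$comp, data.frame(cell_id = 1L, pos = 3L, L_start = 700,
                                       Td = 75, tau = 0, T_seg = 500,
                                       length = 700))
  st$comp$T_seg <- 500
  st$cells$length <- 3200
  st$sites <- data.frame(cell_id = 1L, kind = "nonpolar", boundary = 1:2,
                         blocked = FALSE, t_w = c(4, 33), s = c(4, 7),
                         appeared_at = 0)
  st2 <- execute_divisions(st)
  expect_equal(nrow(st2$cells), 2)
  # the surviving site lives in daughter B; reversal maps boundary 2 -> 1,
  # with t_w and s carried over unchanged
  s2 <- st2$sites
  expect_equal(nrow(s2), 1)
  expect_equal(s2$boundary, 1L)
  expect_equal(s2$t_w, 33)
  expect_equal(s2$s, 7)
  expect_identical(validate_state(st2), character(0))
})

test_that("realized waiting times are monotone in model-4 competition", {
  # non-decreasing in the number of competing sites at fixed length,
  # non-increasing in length at fixed site number (frozen geometry)
  p <- div_params()
  realized <- function(L, n_sites) {
    f <- progression_rate(L, n_sites, 4, "minB", 1, p)
    10 / f   # time for s to reach t_w = 10 at constant rate f
  }
  L <- 8000
  waits_n <- vapply(1:6, function(n) realized(L, n), numeric(1))
  expect_true(all(diff(waits_n) >= 0))
  waits_L <- vapply(seq(3000, 20000, by = 1000),
                    function(l) realized(l, 3), numeric(1))
  expect_true(all(diff(waits_L) <= 0))
})
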