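make_tracking <- function(division_class, site_appeared_t, division_t,
                          cell_id = seq_along(division_t),
                          parent_id = NA_integer_, birth_t = 0,
                          birth_length_nm = 2500,
                          division_length_nm = 5000, n_clusters = 1L) {
  tibble::tibble(cell_id = cell_id, parent_id = parent_id, birth_t = birth_t,
                 division_t = division_t, birth_length_nm = birth_length_nm,
                 division_length_nm = division_length_nm,
                 division_class = division_class,
                 site_appeared_t = site_appeared_t, n_clusters = n_clusters)
}

test_that("waiting-time summary recovers the generating distribution", {
  w <- withr::with_seed(5, stats::rnorm(1e4, 17.7, 11.9))
  tr <- make_tracking("nonpolar", site_appeared_t = 0, division_t = w)
  s <- waiting_time_summary(tr)
  sem <- 11.9 / sqrt(1e4)
  expect_lt(abs(s$mean_min - 17.7), 2 * sem)
  expect_equal(s$sd_min, 11.9, tolerance = 0.05)
  expect_equal(s$n, 1e4L)
})

test_that("a site appearing at division has zero waiting time", {
  tr <- make_tracking("nonpolar", site_appeared_t = 42, division_t = 42)
  s <- waiting_time_summary(tr)
  expect_equal(s$mean_min, 0)
  h <- waiting_time_distribution(tr)
  expect_equal(sum(h$count), 1)
})

test_that("per-class summaries match a filter-then-aggregate oracle", {
  tr <- withr::with_seed(8, dplyr::bind_rows(
    make_tracking("nonpolar", 0, stats::rnorm(500, 30, 5)),
    make_tracking("polar_old", 0, stats::rnorm(300, 60, 10)),
    make_tracking("polar_new", 0, stats::rnorm(200, 55, 12))
  ))
  s <- waiting_time_summary(tr)
  # brute-force recomputation per class
  w_np <- tr$division_t[tr$division_class == "nonpolar"]
  w_p <- tr$division_t[tr$division_class != "nonpolar"]
  expect_equal(s$mean_min[s$site_class == "nonpolar"], mean(w_np))
  expect_equal(s$mean_min[s$site_class == "polar"], mean(w_p))
  expect_equal(s$sd_min[s$site_class == "polar"], stats::sd(w_p))
  # class filter narrows to one class
  s1 <- waiting_time_summary(tr, site_class = "polar_new")
  expect_equal(s1$n, 200L)
})

test_that("censoring excludes and counts events outside the window", {
  tr <- make_tracking("nonpolar", 0, c(10, 50, 300))
  s <- waiting_time_summary(tr, window = c(0, 213))
  expect_equal(s$n, 2L)
  expect_equal(s$n_censored, 1L)
  # empty selection is flagged, not an error
  e <- waiting_time_summary(tr[0, ])
  expect_true(isTRUE(attr(e, "empty")))
})

test_that("length distribution excludes minicells and normalizes its CDF", {
  snap <- tibble::tibble(length_nm = c(rep(4000, 5), 300, 250),
                         is_minicell = c(rep(FALSE, 5), TRUE, TRUE))
  h <- length_distribution(snap)
  expect_equal(sum(h$count), 5)                 # counts = cells - minicells
  expect_equal(attr(h, "n_excluded"), 2L)
  cdf <- attr(h, "cdf")
  expect_equal(max(cdf$cdf), 1)                 # reaches 1
  expect_true(all(diff(cdf$cdf) >= 0))          # monotone
  # all cells at one length: a single step
  expect_equal(unique(cdf$length_nm), 4000)
  expect_equal(length_cdf(snap)$cdf, cdf$cdf)
})

test_that("sites per length matches direct computation", {
  snaps <- tibble::tibble(
    t_min = c(0, 0, 10, 10), length_nm = c(4000, 6000, 4000, 6000),
    n_sites_active = c(1L, 2L, 0L, 0L))
  s <- sites_per_length(snaps)
  expect_equal(s$sites_per_nm, c(3 / 10000, 0))
  one <- sites_per_length(tibble::tibble(t_min = 0, length_nm = 5000,
                                         n_sites_active = 1L))
  expect_equal(one$sites_per_nm, 1 / 5000)
})

test_that("blocking depresses the site density relative to model 1", {
  r1 <- run_simulation(sim_config(1, "minB", t_max = 200, n_init = 40,
                                  seed = 51))
  r3 <- run_simulation(sim_config(3, "minB", t_max = 200, n_init = 40,
                                  seed = 51))
  s1 <- sites_per_length(r1$snapshots)
  s3 <- sites_per_length(r3$snapshots)
  joined <- dplyr::inner_join(s1, s3, by = "t_min", suffix = c("_m1", "_m3"))
  # after burn-in the blocked model always offers fewer sites per length
  late <- joined[joined$t_min >= 50, ]
  expect_true(all(late$sites_per_nm_m3 <= late$sites_per_nm_m1))
})

test_that("expected cluster number is length over starting length", {
  expect_equal(expected_cluster_number(2500, 2500), 1)
  expect_equal(expected_cluster_number(10000, 2500), 4)
  L <- seq(2500, 20000, by = 500)
  expect_equal(expected_cluster_number(L, 2500),
               vapply(L, function(x) x / 2500, numeric(1)))
  expect_warning(expected_cluster_number(1000, 2500), "below 1")
})

test_that("cluster-offset fit is the exact mean residual", {
  exact <- fit_cluster_offset(data.frame(n_exp = c(3, 5), n_obs = c(1, 3)))
  expect_equal(exact$offset, 2)
  zero <- fit_cluster_offset(data.frame(n_exp = 1:5, n_obs = 1:5))
  expect_equal(zero$offset, 0)
  expect_error(fit_cluster_offset(data.frame(n_exp = 1, n_obs = 1)), "2")
  # estimator consistency against a generic least-squares oracle
  set.seed(13)
  n_exp <- stats::runif(500, 3, 8)
  n_obs <- n_exp - 2 + stats::rnorm(500, 0, 0.1)
  fit <- fit_cluster_offset(data.frame(n_exp = n_exp, n_obs = n_obs))
  ls <- stats::lm(I(n_exp - n_obs) ~ 1)       # intercept-only least squares
  expect_equal(fit$offset, unname(stats::coef(ls)[1]))
  expect_equal(fit$offset, 2, tolerance = 0.01)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n, 500)
})

test_that("interdivision distribution matches brute force", {
  tr <- make_tracking("nonpolar", 0, division_t = rep(75, 10),
                      birth_t = rep(0, 10))
  h <- interdivision_distribution(tr)
  expect_equal(nrow(h), 1)                     # point mass at 75
  expect_equal(h$count, 10L)
  expect_equal(h$bin_lo, 75)
  expect_equal(nrow(interdivision_distribution(tr[0, ])), 0)
  tr2 <- make_tracking("nonpolar", 0, division_t = c(60, 75, 90),
                       birth_t = c(0, 5, 10))
  h2 <- interdivision_distribution(tr2)
  expect_equal(sum(h2$count * h2$bin_mid) / sum(h2$count),
               mean(c(60, 70, 80)), tolerance = 0.1)
})

test_that("hand-built lineage covers all five division-history types", {
  # cell 1 divides non-polar at t=100 -> cells 2 and 3
  # cell 2: polar (old pole) at 130, then polar old-pole again at 150,
  #         then polar new-pole at 165, then non-polar at 180 -> 4, 5
  # cell 3: non-polar at 190 -> 6, 7
  tr <- tibble::tibble(
    cell_id = c(1L, 2L, 2L, 2L, 2L, 3L),
    parent_id = c(NA, 1L, 2L, 2L, 2L, 1L),
    birth_t = c(0, 100, 100, 100, 100, 100),
    division_t = c(100, 130, 150, 165, 180, 190),
    birth_length_nm = 2500, division_length_nm = 5000,
    division_class = c("nonpolar", "polar_old", "polar_old", "polar_new",
                       "nonpolar", "nonpolar"),
    site_appeared_t = c(50, 100, 130, 100, 160, 120),
    n_clusters = 1L
  )
  tr$parent_id[3:5] <- 1L   # lineage parent stays cell 1
  h <- classify_division_history(tr)
  get <- function(f, s) h$n[h$first_class == f & h$second_class == s]
  expect_equal(get("nonpolar", "polar"), 1L)    # 100 -> 130 (cell 2)
  expect_equal(get("polar", "old_pole"), 1L)    # 130 -> 150
  expect_equal(get("polar", "new_pole"), 1L)    # 150 -> 165
  expect_equal(get("polar", "nonpolar"), 1L)    # 165 -> 180
  expect_equal(get("nonpolar", "nonpolar"), 1L) # 100 -> 190 (cell 3)
  # inter-division times: direct check for one category
  expect_equal(h$dt_mean_min[h$first_class == "polar" &
                               h$second_class == "old_pole"], 20)
  # percentages within each first-division row sum to 100
  sums <- tapply(h$pct, h$first_class, sum, na.rm = TRUE)
  expect_true(all(abs(sums - 100) < 0.1))
  expect_equal(attr(h, "n_orphans"), 1L)        # cell 1 has no predecessor
})

test_that("a table with no linked pairs tallies to all zero", {
  tr <- make_tracking("nonpolar", 0, division_t = c(10, 20),
                      cell_id = c(1L, 2L), parent_id = NA_integer_)
  h <- classify_division_history(tr)
  expect_true(all(h$n == 0))
  expect_equal(attr(h, "n_orphans"), 2L)
})
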