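#' Run the population simulation
#'
#' Advances an initialized population from `t = 0` to `t_max` in steps of
#' `dt`, applying the stages in fixed order: growth and replication-timer
#' ticking ([grow_and_tick()]), chromosome segregation with optional
#' blocking ([segregate_step()]), division-site progression
#' ([advance_progression()]) and division execution
#' ([execute_divisions()]). The RNG is seeded from `config$seed`, so an
#' identical configuration yields identical output.
#'
#' @param config A [sim_config()] (or [scenario_config()]).
#' @return An object of class `mindivsim_run`: a list with
#'   * `config`: the configuration;
#'   * `events`: tibble of division / minicell (and optionally
#'     segregation) events;
#'   * `snapshots`: tibble of per-cell population snapshots taken every
#'     `snapshot_every` minutes plus the final state;
#'   * `series`: per-step population time series (`t_min`,
#'     `total_length_nm`, `n_cells`, `n_compartments`, `n_sites_active`,
#'     `n_sites_blocked`, `minicell_count`);
#'   * `final_state`: the `sim_state` at the end;
#'   * `aborted`: `TRUE` if the compartment cap stopped the run early.
#' @examples
#' run <- run_simulation(sim_config(model_variant = 1, strain = "WT",
#'                                  t_max = 120, n_init = 20, seed = 1))
#' glance(run)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  st <- init_population(config)
  dt <- config$dt
  n_steps <- floor(config$t_max / dt + 1e-9)
  series <- vector("list", n_steps + 1L)
  snaps <- list(snapshot_state(st))
  series[[1]] <- series_row(st)
  next_snap <- config$snapshot_every
  aborted <- FALSE

  for (step in seq_len(n_steps)) {
    st <- grow_and_tick(st, dt)
    st$t <- st$t + dt
    st <- segregate_step(st)
    st <- advance_progression(st, dt)
    st <- execute_divisions(st)
    series[[step + 1L]] <- series_row(st)
    if (st$t + 1e-9 >= next_snap) {
      snaps[[length(snaps) + 1L]] <- snapshot_state(st)
      next_snap <- next_snap + config$snapshot_every
    }
    if (nrow(st$comp) > config$max_compartments) {
      warning("compartment cap exceeded at t = ", st$t,
              " min; returning partial run", call. = FALSE)
      aborted <- TRUE
      break
    }
  }
  if (snaps[[length(snaps)]]$t_min[1] != st$t || nrow(snaps[[length(snaps)]]) == 0) {
    snaps[[length(snaps) + 1L]] <- snapshot_state(st)
  }
  events <- if (length(st$events) > 0) {
    tibble::as_tibble(do.call(rbind, st$events))
  } else {
    empty_events()
  }
  structure(
    list(config = config,
         events = events,
         snapshots = tibble::as_tibble(do.call(rbind, snaps)),
         series = tibble::as_tibble(do.call(rbind, series)),
         final_state = st,
         aborted = aborted),
    class = "mindivsim_run"
  )
}

empty_events <- function() {
  tibble::tibble(
    t_min = numeric(0), event = character(0), cell_id = integer(0),
    parent_id = integer(0), site_class = character(0),
    site_appeared_t = numeric(0), birth_t = numeric(0),
    birth_length_nm = numeric(0), cell_length_nm = numeric(0),
    n_compartments = integer(0), daughter1_id = integer(0),
    daughter2_id = integer(0), daughter1_length_nm = numeric(0),
    daughter2_length_nm = numeric(0)
  )
}

series_row <- function(st) {
  data.frame(
    t_min = st$t,
    total_length_nm = sum(st$comp$length),
    n_cells = nrow(st$cells),
    n_compartments = nrow(st$comp),
    n_sites_active = sum(!st$sites$blocked),
    n_sites_blocked = sum(st$sites$blocked),
    minicell_count = st$minicell_count
  )
}

#' @export
print.mindivsim_run <- function(x, ...) {
  cfg <- x$config
  fin <- x$series[nrow(x$series), ]
  cat("<mindivsim_run> model", cfg$model_variant, cfg$strain,
      "| t =", fin$t_min, "min |", fin$n_cells, "cells |",
      fin$minicell_count, "minicells |",
      sum(x$events$event == "division"), "divisions\n")
  invisible(x)
}

#' Convert a run's event log to a lineage tracking table
#'
#' Produces the table format consumed by the observables layer, one row
#' per division event: `cell_id`, `parent_id`, `birth_t`, `division_t`,
#' `birth_length_nm`, `division_length_nm`, `division_class`
#' (`nonpolar`, `polar_old`, `polar_new`), `site_appeared_t` and
#' `n_clusters` (compartment count at division, i.e. visible chromosome
#' clusters).
#'
#' @param run A `mindivsim_run` (or its `events` tibble).
#' @return A tibble of class `tracking_table`.
#' @export
as_tracking <- function(run) {
  ev <- if (inherits(run, "mindivsim_run")) run$events else run
  ev <- dplyr::filter(ev, .data$event %in% c("division", "minicell"))
  out <- tibble::tibble(
    cell_id = ev$cell_id,
    parent_id = ev$parent_id,
    birth_t = ev$birth_t,
    division_t = ev$t_min,
    birth_length_nm = ev$birth_length_nm,
    division_length_nm = ev$cell_length_nm,
    division_class = ev$site_class,
    site_appeared_t = ev$site_appeared_t,
    n_clusters = ev$n_compartments
  )
  class(out) <- c("tracking_table", class(out))
  out
}

#' Fit the bulk (culture) doubling time
#'
#' Fits a straight line to `log2(total length)` versus time over a window
#' and reports its inverse slope: the population doubling time of the
#' culture, which for exponentially growing single cells with doubling
#' times around 75 min is itself close to 75 min.
#'
#' @param series A run's `series` tibble (or any data frame with `t_min`
#'   and `total_length_nm`).
#' @param window Length-2 numeric: fit window in minutes. Defaults to the
#'   final 200 minutes of the series.
#' @return A one-row tibble: `doubling_time_min`, `slope`, `r_squared`,
#'   `n_points`.
#' @export
fit_bulk_doubling <- function(series, window = NULL) {
  if (is.null(window)) {
    tmax <- max(series$t_min)
    window <- c(max(0, tmax - 200), tmax)
  }
  d <- dplyr::filter(series, .data$t_min >= window[1], .data$t_min <= window[2])
  if (nrow(d) < 3) stop("need at least 3 points in the fit window", call. = FALSE)
  fit <- stats::lm(log2(total_length_nm) ~ t_min, data = d)
  sl <- stats::coef(fit)[["t_min"]]
  tibble::tibble(
    doubling_time_min = 1 / sl,
    slope = sl,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_points = nrow(d)
  )
}

#' Time-averaged blocked sites per cell
#'
#' Averages `n_sites_blocked / n_cells` over a time window of a run's
#' series — the statistic maintained near the blocking target by the
#' re-randomized threshold rule in minB- models 2-4.
#'
#' @param series A run's `series` tibble.
#' @param window Length-2 numeric window in minutes (default: final 200).
#' @return A one-row tibble: `mean_blocked_per_cell`, `window_start`,
#'   `window_end`, `n_points`.
#' @export
blocked_sites_summary <- function(series, window = NULL) {
  if (is.null(window)) {
    tmax <- max(series$t_min)
    window <- c(max(0, tmax - 200), tmax)
  }
  d <- dplyr::filter(series, .data$t_min >= window[1], .data$t_min <= window[2])
  tibble::tibble(
    mean_blocked_per_cell = mean(d$n_sites_blocked / d$n_cells),
    window_start = window[1], window_end = window[2], n_points = nrow(d)
  )
}
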