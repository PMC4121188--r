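#' Division waiting-time summary
#'
#' The division waiting time is the interval between the appearance of a
#' division site (first visible chromosome separation, or pole formation
#' for polar sites) and the division event at that site:
#' `division_t - site_appeared_t`. Events whose division falls outside the
#' analysis window are right-censored by the finite observation time and
#' are excluded (and counted), mirroring the experimental measurement.
#'
#' @param tracking A tracking table (see [as_tracking()],
#'   [generate_tracking()]).
#' @param site_class Optional filter: `"nonpolar"`, `"polar"` (matches both
#'   pole identities), `"polar_old"` or `"polar_new"`.
#' @param window Optional length-2 analysis window in minutes; events
#'   dividing after `window[2]` are censored out.
#' @return A tibble with one row per class present: `site_class`, `n`,
#'   `mean_min`, `sd_min`, `n_censored`.
#' @export
waiting_time_summary <- function(tracking, site_class = NULL, window = NULL) {
  d <- filter_class(tracking, site_class)
  n_cens <- 0L
  if (!is.null(window)) {
    cens <- d$division_t > window[2] | d$division_t < window[1]
    n_cens <- sum(cens)
    d <- d[!cens, , drop = FALSE]
  }
  if (nrow(d) == 0) {
    out <- tibble::tibble(site_class = character(0), n = integer(0),
                          mean_min = numeric(0), sd_min = numeric(0),
                          n_censored = integer(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  d |>
    dplyr::mutate(waiting = .data$division_t - .data$site_appeared_t,
                  cls = class_group(.data$division_class)) |>
    dplyr::group_by(site_class = .data$cls) |>
    dplyr::summarise(n = dplyr::n(), mean_min = mean(.data$waiting),
                     sd_min = stats::sd(.data$waiting), .groups = "drop") |>
    dplyr::mutate(n_censored = n_cens)
}

#' Division waiting-time histogram
#'
#' @inheritParams waiting_time_summary
#' @param binwidth Histogram bin width, minutes (default 5).
#' @return A tibble: `site_class`, `bin_lo`, `bin_mid`, `count`.
#' @export
waiting_time_distribution <- function(tracking, site_class = NULL,
                                      binwidth = 5, window = NULL) {
  d <- filter_class(tracking, site_class)
  if (!is.null(window)) {
    d <- d[d$division_t <= window[2] & d$division_t >= window[1], , drop = FALSE]
  }
  if (nrow(d) == 0) {
    out <- tibble::tibble(site_class = character(0), bin_lo = numeric(0),
                          bin_mid = numeric(0), count = integer(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  d |>
    dplyr::mutate(waiting = .data$division_t - .data$site_appeared_t,
                  cls = class_group(.data$division_class),
                  bin_lo = floor(.data$waiting / binwidth) * binwidth) |>
    dplyr::count(site_class = .data$cls, .data$bin_lo, name = "count") |>
    dplyr::mutate(bin_mid = .data$bin_lo + binwidth / 2, .after = "bin_lo")
}

filter_class <- function(tracking, site_class) {
  if (is.null(site_class)) return(tracking)
  keep <- if (identical(site_class, "polar")) {
    tracking$division_class %in% c("polar_old", "polar_new")
  } else {
    tracking$division_class == site_class
  }
  tracking[keep, , drop = FALSE]
}

class_group <- function(x) ifelse(x == "nonpolar", "nonpolar", "polar")

#' Inter-division time histogram
#'
#' Distribution of `division_t - birth_t` across division events.
#'
#' @inheritParams waiting_time_distribution
#' @return A tibble: `bin_lo`, `bin_mid`, `count`, plus attributes-free
#'   summary columns are available via [waiting_time_summary()]-style
#'   aggregation by the caller.
#' @export
interdivision_distribution <- function(tracking, binwidth = 5) {
  if (nrow(tracking) == 0) {
    return(tibble::tibble(bin_lo = numeric(0), bin_mid = numeric(0),
                          count = integer(0)))
  }
  tracking |>
    dplyr::mutate(idt = .data$division_t - .data$birth_t,
                  bin_lo = floor(.data$idt / binwidth) * binwidth) |>
    dplyr::count(.data$bin_lo, name = "count") |>
    dplyr::mutate(bin_mid = .data$bin_lo + binwidth / 2, .after = "bin_lo")
}

#' Cell length distribution and empirical CDF
#'
#' Minicells are excluded (they are counted but not sized, matching the
#' experimental analysis). The CDF is right-continuous and reaches 1 at
#' the maximum length.
#'
#' @param snapshot A snapshot tibble (one row per cell with `length_nm`
#'   and optionally `is_minicell`).
#' @param binwidth Histogram bin width, nm (default 500).
#' @return A list-free tibble of histogram bins (`bin_lo`, `bin_mid`,
#'   `count`) with the empirical CDF attached as attribute `"cdf"` — a
#'   tibble (`length_nm`, `cdf`) — and `n_excluded` minicells as attribute.
#' @export
length_distribution <- function(snapshot, binwidth = 500) {
  if (nrow(snapshot) == 0) stop("empty snapshot", call. = FALSE)
  mini <- if ("is_minicell" %in% names(snapshot)) snapshot$is_minicell else FALSE
  d <- snapshot[!mini, , drop = FALSE]
  hist <- d |>
    dplyr::mutate(bin_lo = floor(.data$length_nm / binwidth) * binwidth) |>
    dplyr::count(.data$bin_lo, name = "count") |>
    dplyr::mutate(bin_mid = .data$bin_lo + binwidth / 2, .after = "bin_lo")
  x <- sort(d$length_nm)
  cdf <- tibble::tibble(length_nm = x, cdf = seq_along(x) / length(x))
  attr(hist, "cdf") <- cdf
  attr(hist, "n_excluded") <- sum(mini)
  hist
}

#' Empirical CDF of cell lengths
#'
#' Convenience accessor for the CDF computed by [length_distribution()].
#'
#' @inheritParams length_distribution
#' @return A tibble (`length_nm`, `cdf`), right-continuous, reaching 1.
#' @export
length_cdf <- function(snapshot, binwidth = 500) {
  attr(length_distribution(snapshot, binwidth), "cdf")
}

#' Active division sites per unit cell length over time
#'
#' For each snapshot time, the total number of active (unblocked,
#' appeared) division sites divided by the total chromosome-containing
#' cell length — the population statistic whose depression in minB- cells
#' reveals the segregation defect.
#'
#' @param snapshots A snapshots tibble (multiple `t_min` values; columns
#'   `n_sites_active`, `length_nm`, optionally `is_minicell`).
#' @return A tibble: `t_min`, `sites_per_nm`.
#' @export
sites_per_length <- function(snapshots) {
  mini <- if ("is_minicell" %in% names(snapshots)) snapshots$is_minicell else FALSE
  snapshots[!mini, , drop = FALSE] |>
    dplyr::group_by(.data$t_min) |>
    dplyr::summarise(sites_per_nm = sum(.data$n_sites_active) /
                       sum(.data$length_nm), .groups = "drop")
}

#' Expected number of chromosome clusters for a cell length
#'
#' A cell of length `L` is expected to hold `L / L0` chromosomes, where
#' `L0` is the starting (newborn compartment) length. Comparing this with
#' the observed cluster count reveals boundaries at which segregation has
#' failed.
#'
#' @param L Cell length(s), nm.
#' @param L0 Starting length, nm.
#' @return `L / L0`; values below 1 (cells shorter than `L0`) are returned
#'   with a warning.
#' @export
expected_cluster_number <- function(L, L0) {
  if (any(L0 <= 0)) stop("L0 must be > 0", call. = FALSE)
  if (any(L <= 0)) stop("L must be > 0", call. = FALSE)
  out <- L / L0
  if (any(out < 1)) warning("expected cluster number below 1 for some cells",
                            call. = FALSE)
  out
}

#' Fit the offset between expected and observed cluster numbers
#'
#' Least-squares fit of `N_obs = N_exp - b` with the slope fixed at 1, so
#' the offset is exactly the mean residual `b = mean(N_exp - N_obs)`. An
#' offset of about 2 reproduces the finding that on average segregation
#' fails at two potential division sites per cell.
#'
#' @param clusters A data frame with columns `n_exp` and `n_obs`
#'   (at least 2 rows).
#' @return An object of class `cluster_offset_fit`; use [tidy()] /
#'   [glance()] or `$offset`.
#' @examples
#' fit_cluster_offset(data.frame(n_exp = c(3, 5), n_obs = c(1, 3)))$offset
#' @export
fit_cluster_offset <- function(clusters) {
  if (!all(c("n_exp", "n_obs") %in% names(clusters))) {
    stop("clusters needs columns n_exp and n_obs", call. = FALSE)
  }
  if (nrow(clusters) < 2) stop("need at least 2 cluster pairs", call. = FALSE)
  res <- clusters$n_exp - clusters$n_obs
  structure(
    list(offset = mean(res), se = stats::sd(res) / sqrt(length(res)),
         residual_sd = stats::sd(res), n = nrow(clusters)),
    class = "cluster_offset_fit"
  )
}

#' @export
print.cluster_offset_fit <- function(x, ...) {
  cat(sprintf("<cluster_offset_fit> N_obs = N_exp - b, b = %.3f (se %.3f, n = %d)\n",
              x$offset, x$se, x$n))
  invisible(x)
}

#' Classify successive division events into the five history types
#'
#' Each division event is paired with the previous division in its
#' lineage: for a cell born from a non-polar division, that is the
#' parent's division; for a cell that already budded off minicells, it is
#' the cell's own previous (polar) event. Pairs are tallied into the five
#' categories defined by the location of the two successive divisions —
#' polar then old-pole, polar then non-polar, polar then new-pole,
#' non-polar then polar, non-polar then non-polar — together with the mean
#' and SD of the time between the two events. Events with no observed
#' predecessor are excluded and counted.
#'
#' @param tracking A tracking table.
#' @param window Optional length-2 analysis window in minutes: both events
#'   of a pair must fall inside it.
#' @return A tibble with columns `first_class`, `second_class`, `n`,
#'   `pct` (percentage within each `first_class` row), `dt_mean_min`,
#'   `dt_sd_min`; attribute `n_orphans` counts excluded events.
#' @export
classify_division_history <- function(tracking, window = NULL) {
  lv_first <- c("polar", "nonpolar")
  lv_second <- c("old_pole", "nonpolar", "new_pole", "polar")
  if (!is.null(window)) {
    tracking <- tracking[tracking$division_t >= window[1] &
                           tracking$division_t <= window[2], , drop = FALSE]
  }
  d <- tracking[order(tracking$cell_id, tracking$division_t), , drop = FALSE]
  n <- nrow(d)
  if (n == 0) return(empty_history())

  # previous event of the same cell (polar chains)
  same_prev_t <- rep(NA_real_, n)
  same_prev_class <- rep(NA_character_, n)
  if (n > 1) {
    same_cell <- d$cell_id[-1] == d$cell_id[-n]
    same_prev_t[-1][same_cell] <- d$division_t[-n][same_cell]
    same_prev_class[-1][same_cell] <- d$division_class[-n][same_cell]
  }
  # creating event: the parent's non-polar division at this cell's birth
  parent_key <- paste(d$parent_id, round(d$birth_t, 6))
  pk_all <- paste(d$cell_id, round(d$division_t, 6))
  par_idx <- match(parent_key, pk_all)

  first_t <- ifelse(!is.na(same_prev_t), same_prev_t, d$division_t[par_idx])
  first_class_raw <- ifelse(!is.na(same_prev_class), same_prev_class,
                            d$division_class[par_idx])
  ok <- !is.na(first_t)
  n_orphans <- sum(!ok)
  if (!any(ok)) return(empty_history(n_orphans))
  dd <- d[ok, , drop = FALSE]
  first_class <- ifelse(first_class_raw[ok] == "nonpolar", "nonpolar", "polar")
  second_class <- dplyr::case_when(
    first_class == "polar" & dd$division_class == "polar_old" ~ "old_pole",
    first_class == "polar" & dd$division_class == "polar_new" ~ "new_pole",
    first_class == "polar" ~ "nonpolar",
    dd$division_class == "nonpolar" ~ "nonpolar",
    TRUE ~ "polar"
  )
  res <- tibble::tibble(
    first_class = factor(first_class, lv_first),
    second_class = factor(second_class, lv_second),
    dt = dd$division_t - first_t[ok]
  ) |>
    dplyr::group_by(.data$first_class, .data$second_class, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), dt_mean_min = mean(.data$dt),
                     dt_sd_min = stats::sd(.data$dt), .groups = "drop_last") |>
    dplyr::mutate(pct = 100 * .data$n / sum(pmax(.data$n, 0), na.rm = TRUE)) |>
    dplyr::ungroup()
  # keep only the five defined categories
  res <- res[(res$first_class == "polar" &
                res$second_class %in% c("old_pole", "nonpolar", "new_pole")) |
               (res$first_class == "nonpolar" &
                  res$second_class %in% c("polar", "nonpolar")), , drop = FALSE]
  res$first_class <- as.character(res$first_class)
  res$second_class <- as.character(res$second_class)
  res$pct[is.nan(res$pct)] <- NA_real_
  attr(res, "n_orphans") <- n_orphans
  res
}

empty_history <- function(n_orphans = 0L) {
  out <- tibble::tibble(
    first_class = c("polar", "polar", "polar", "nonpolar", "nonpolar"),
    second_class = c("old_pole", "nonpolar", "new_pole", "polar", "nonpolar"),
    n = 0L, dt_mean_min = NA_real_, dt_sd_min = NA_real_, pct = NA_real_
  )
  attr(out, "n_orphans") <- n_orphans
  out
}
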