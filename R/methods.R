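#' Tidiers for simulation runs and fits
#'
#' `tidy()` on a run returns its event log; `glance()` a one-row summary
#' including the fitted bulk doubling time. For a cluster-offset fit,
#' `tidy()` gives the single estimated term and `glance()` the fit-level
#' summary.
#'
#' @param x A `mindivsim_run` or `cluster_offset_fit`.
#' @param ... Unused.
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @export
tidy.mindivsim_run <- function(x, ...) x$events

#' @rdname tidiers
#' @export
glance.mindivsim_run <- function(x, ...) {
  fin <- x$series[nrow(x$series), ]
  doubling <- tryCatch(fit_bulk_doubling(x$series)$doubling_time_min,
                       error = function(e) NA_real_)
  tibble::tibble(
    model_variant = x$config$model_variant,
    strain = x$config$strain,
    t_final_min = fin$t_min,
    n_cells = fin$n_cells,
    n_compartments = fin$n_compartments,
    minicell_count = fin$minicell_count,
    n_divisions = sum(x$events$event == "division"),
    mean_blocked_per_cell = fin$n_sites_blocked / fin$n_cells,
    doubling_time_min = doubling,
    aborted = x$aborted
  )
}

#' @rdname tidiers
#' @export
tidy.cluster_offset_fit <- function(x, ...) {
  tibble::tibble(term = "offset", estimate = x$offset, std.error = x$se)
}

#' @rdname tidiers
#' @export
glance.cluster_offset_fit <- function(x, ...) {
  tibble::tibble(offset = x$offset, std.error = x$se,
                 residual_sd = x$residual_sd, n = x$n)
}
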