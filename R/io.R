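#' Read and write tracking tables and event logs
#'
#' Plain CSV with a versioned comment header (`# mindivsim <kind> v1`).
#' Round-trips are lossless for the precision written (full double
#' precision via readr); decimal parsing is locale-independent. Missing
#' required columns and malformed rows raise errors naming the column or
#' line.
#'
#' @param x A tracking table or events tibble.
#' @param path File path.
#' @name tracking_io
NULL

TRACKING_COLS <- c("cell_id", "parent_id", "birth_t", "division_t",
                   "birth_length_nm", "division_length_nm",
                   "division_class", "site_appeared_t", "n_clusters")
EVENT_COLS <- c("t_min", "event", "cell_id", "parent_id", "site_class",
                "site_appeared_t", "birth_t", "birth_length_nm",
                "cell_length_nm", "n_compartments", "daughter1_id",
                "daughter2_id", "daughter1_length_nm", "daughter2_length_nm")

write_versioned_csv <- function(x, path, tag) {
  writeLines(paste0("# mindivsim ", tag, " v1"), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_versioned_csv <- function(path, required, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- suppressWarnings(
    readr::read_csv(path, comment = "#", col_types = col_types,
                    locale = readr::locale(decimal_mark = "."),
                    progress = FALSE, show_col_types = FALSE))
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("malformed value at line ", probs$row[1], ", column ", probs$col[1],
         call. = FALSE)
  }
  out
}

#' @rdname tracking_io
#' @export
write_tracking <- function(x, path) {
  write_versioned_csv(x[, TRACKING_COLS], path, "tracking")
}

#' @rdname tracking_io
#' @export
read_tracking <- function(path) {
  out <- read_versioned_csv(path, TRACKING_COLS, readr::cols(
    cell_id = "i", parent_id = "i", birth_t = "d", division_t = "d",
    birth_length_nm = "d", division_length_nm = "d", division_class = "c",
    site_appeared_t = "d", n_clusters = "i"))
  class(out) <- c("tracking_table", class(out))
  out
}

#' @rdname tracking_io
#' @export
write_events <- function(x, path) {
  write_versioned_csv(x[, EVENT_COLS], path, "events")
}

#' @rdname tracking_io
#' @export
read_events <- function(path) {
  read_versioned_csv(path, EVENT_COLS, readr::cols(
    t_min = "d", event = "c", cell_id = "i", parent_id = "i",
    site_class = "c", site_appeared_t = "d", birth_t = "d",
    birth_length_nm = "d", cell_length_nm = "d", n_compartments = "i",
    daughter1_id = "i", daughter2_id = "i", daughter1_length_nm = "d",
    daughter2_length_nm = "d"))
}

#' Write a run's outputs to a directory
#'
#' Writes `events.csv`, `snapshots.csv`, `series.csv` and `summary.json`
#' (the fully resolved configuration, seed and closing counts — enough to
#' reproduce the run byte-identically).
#'
#' @param run A `mindivsim_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_events(run$events, file.path(dir, "events.csv"))
  write_versioned_csv(run$snapshots, file.path(dir, "snapshots.csv"), "snapshots")
  write_versioned_csv(run$series, file.path(dir, "series.csv"), "series")
  cfg <- run$config
  summary <- list(
    model_variant = cfg$model_variant, strain = cfg$strain,
    ftsz_factor = cfg$ftsz_factor, dt = cfg$dt, t_max = cfg$t_max,
    n_init = cfg$n_init, seed = cfg$seed, shared_Td = cfg$shared_Td,
    snapshot_every = cfg$snapshot_every,
    params = stats::setNames(as.list(cfg$params$value), cfg$params$name),
    n_cells_final = run$series$n_cells[nrow(run$series)],
    minicell_count = run$series$minicell_count[nrow(run$series)],
    n_divisions = sum(run$events$event == "division"),
    aborted = run$aborted
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
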