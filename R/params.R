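#' Distribution parameters for the cell-cycle simulator
#'
#' Bundles every distributional constant used by the four model variants.
#' Units are minutes for times and nanometres for lengths. The doubling-time
#' and wild-type waiting-time normals are the experimentally measured ones
#' (75 +/- 15 min and 17.7 +/- 11.9 min); the remaining defaults are
#' documented stand-ins chosen once (see the methods vignette) and are meant
#' to be overridden when better estimates are available.
#'
#' @param Td_mean,Td_sd Doubling-time normal, minutes.
#' @param w_wt_mean,w_wt_sd Wild-type division waiting-time normal, minutes.
#'   Used for both site kinds in model 4 and for model 1 applied to WT.
#' @param w_nonpolar_mean,w_nonpolar_sd Waiting-time normal assigned to
#'   non-polar sites of minB- cells in models 1-3, minutes.
#' @param w_polar_mean,w_polar_sd Waiting-time normal assigned to polar sites
#'   of minB- cells in models 1-2, minutes (model 3 uses the non-polar one).
#' @param L0_mean,L0_sd Newborn compartment length normal, nm.
#' @param Lc Reference chromosome (compartment) size, nm; enters the
#'   machinery-competition rate of model 4.
#' @param delta_sd Standard deviation of the division-site placement noise,
#'   nm. Draws are rejected until the resulting daughter deviates at most
#'   10% from half the parent length.
#' @param n_block_target Mean number of blocked potential division sites per
#'   cell maintained by the re-randomized threshold rule (minB- models 2-4).
#' @param c_rate Rate constant of the machinery-competition law, calibrated
#'   so that a reference WT geometry (one compartment of length `Lc`, one
#'   active site) progresses at unit rate.
#'
#' @return A tibble with one row per parameter (`name`, `value`), of class
#'   `div_params`. Most users pass it around as an opaque object.
#' @examples
#' p <- div_params(Td_mean = 60)
#' param(p, "Td_mean")
#' @export
div_params <- function(Td_mean = 75, Td_sd = 15,
                       w_wt_mean = 17.7, w_wt_sd = 11.9,
                       w_nonpolar_mean = 35, w_nonpolar_sd = 25,
                       w_polar_mean = 65, w_polar_sd = 45,
                       L0_mean = 2500, L0_sd = 250,
                       Lc = 2500,
                       delta_sd = 100,
                       n_block_target = 2,
                       c_rate = 2) {
  vals <- c(
    Td_mean = Td_mean, Td_sd = Td_sd,
    w_wt_mean = w_wt_mean, w_wt_sd = w_wt_sd,
    w_nonpolar_mean = w_nonpolar_mean, w_nonpolar_sd = w_nonpolar_sd,
    w_polar_mean = w_polar_mean, w_polar_sd = w_polar_sd,
    L0_mean = L0_mean, L0_sd = L0_sd,
    Lc = Lc, delta_sd = delta_sd,
    n_block_target = n_block_target, c_rate = c_rate
  )
  sds <- vals[grepl("_sd$", names(vals))]
  if (any(sds < 0)) {
    stop("standard deviations must be >= 0: ",
         paste(names(sds)[sds < 0], collapse = ", "), call. = FALSE)
  }
  means <- vals[c("Td_mean", "w_wt_mean", "w_nonpolar_mean", "w_polar_mean",
                  "L0_mean", "Lc")]
  if (any(means <= 0)) {
    stop("means and lengths must be > 0: ",
         paste(names(means)[means <= 0], collapse = ", "), call. = FALSE)
  }
  if (n_block_target < 0) stop("n_block_target must be >= 0", call. = FALSE)
  out <- tibble::tibble(name = names(vals), value = unname(vals))
  class(out) <- c("div_params", class(out))
  out
}

#' Look up a parameter value by name
#'
#' @param params A [div_params()] tibble.
#' @param name Parameter name.
#' @return The numeric value.
#' @export
param <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: ", name, call. = FALSE)
  params$value[[i]]
}

#' Simulation run configuration
#'
#' @param model_variant Which model to run: 1 (assigned waiting times only),
#'   2 (plus segregation-defect blocking), 3 (blocking, polar sites drawing
#'   from the non-polar waiting distribution), or 4 (blocking plus
#'   competition of sites for division machinery).
#' @param strain `"WT"` (Min system present: polar sites never assemble,
#'   no segregation defect) or `"minB"` (polar sites active, blocking on for
#'   models 2-4).
#' @param ftsz_factor Multiplier on the division-machinery level (model 4);
#'   2 emulates a two-fold FtsZ overexpression.
#' @param dt Time step, minutes.
#' @param t_max Simulated horizon, minutes.
#' @param n_init Number of randomly initialized cells at t = 0.
#' @param seed Integer seed; identical seed + config gives identical output.
#' @param params A [div_params()] object.
#' @param shared_Td If `TRUE`, every compartment in the culture uses
#'   `Td_mean` instead of an individual doubling-time draw.
#' @param snapshot_every Minutes between per-cell population snapshots
#'   (the final state is always snapshotted).
#' @param log_segregation Record segregation events in the event log.
#' @param max_compartments Abort (with partial output) if the population
#'   exceeds this many compartments.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(model_variant = 1, strain = "WT", t_max = 150, n_init = 50, seed = 1)
#' @export
sim_config <- function(model_variant = 1,
                       strain = c("WT", "minB"),
                       ftsz_factor = 1,
                       dt = 1,
                       t_max = 300,
                       n_init = 1000,
                       seed = 1L,
                       params = div_params(),
                       shared_Td = FALSE,
                       snapshot_every = 10,
                       log_segregation = FALSE,
                       max_compartments = 1e6) {
  strain <- match.arg(strain)
  if (!model_variant %in% 1:4) stop("model_variant must be 1, 2, 3 or 4", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (t_max < 0) stop("t_max must be >= 0", call. = FALSE)
  if (n_init < 1) stop("n_init must be >= 1", call. = FALSE)
  if (ftsz_factor <= 0) stop("ftsz_factor must be > 0", call. = FALSE)
  if (!inherits(params, "div_params")) stop("params must be a div_params() object", call. = FALSE)
  structure(
    list(model_variant = as.integer(model_variant), strain = strain,
         ftsz_factor = ftsz_factor, dt = dt, t_max = t_max,
         n_init = as.integer(n_init), seed = as.integer(seed),
         params = params, shared_Td = isTRUE(shared_Td),
         snapshot_every = snapshot_every,
         log_segregation = isTRUE(log_segregation),
         max_compartments = max_compartments),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> model", x$model_variant, "| strain", x$strain,
      "| ftsz", x$ftsz_factor, "| dt", x$dt, "min | t_max", x$t_max,
      "min | n_init", x$n_init, "| seed", x$seed, "\n")
  invisible(x)
}

#' Named experimental scenarios
#'
#' Resolves the three scenarios the models are compared under into full
#' configurations: `"wt"` (model 4, machinery confined to half the cell,
#' poles inactive), `"minB"` (Min deletion; model selectable), and
#' `"minB_2xftsz"` (minB- with a two-fold FtsZ level and a reduced blocking
#' target, default 1, reflecting the observed decrease in inter-septum
#' distance).
#'
#' @param name Scenario name.
#' @param model_variant Model to use for the `"minB"` scenario (the other
#'   two are model-4 constructs).
#' @param n_block_2xftsz Blocking target used under doubled FtsZ.
#' @param ... Passed on to [sim_config()] (e.g. `seed`, `t_max`, `n_init`).
#' @return A `sim_config`.
#' @examples
#' scenario_config("wt", seed = 1, t_max = 100, n_init = 20)
#' @export
scenario_config <- function(name, model_variant = 4, n_block_2xftsz = 1, ...) {
  dots <- list(...)
  params <- dots$params %||% div_params()
  dots$params <- NULL
  build <- function(model, strain, ftsz, params) {
    do.call(sim_config, c(list(model_variant = model, strain = strain,
                               ftsz_factor = ftsz, params = params), dots))
  }
  switch(name,
    wt = build(4L, "WT", 1, params),
    minB = build(model_variant, "minB", 1, params),
    minB_2xftsz = {
      params$value[params$name == "n_block_target"] <- n_block_2xftsz
      build(4L, "minB", 2, params)
    },
    stop("unknown scenario: ", name, call. = FALSE)
  )
}

#' Load a simulation configuration from JSON
#'
#' The file is a flat JSON object whose keys mirror the arguments of
#' [sim_config()] and the parameter names of [div_params()]. Missing keys
#' take their defaults; unknown keys are an error naming the key; invalid
#' values produce an error naming the field. An empty file yields the full
#' default configuration.
#'
#' @param path Path to a JSON file.
#' @return A `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (nchar(trimws(txt)) == 0) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)
  cfg_keys <- c("model_variant", "strain", "ftsz_factor", "dt", "t_max",
                "n_init", "seed", "shared_Td", "snapshot_every",
                "log_segregation", "max_compartments")
  par_keys <- div_params()$name
  unknown <- setdiff(names(raw), c(cfg_keys, par_keys))
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  par_args <- raw[intersect(names(raw), par_keys)]
  params <- tryCatch(do.call(div_params, par_args),
                     error = function(e) stop("invalid parameter: ",
                                              conditionMessage(e), call. = FALSE))
  cfg_args <- raw[intersect(names(raw), cfg_keys)]
  cfg_args$params <- params
  tryCatch(do.call(sim_config, cfg_args),
           error = function(e) stop("invalid configuration: ",
                                    conditionMessage(e), call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
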