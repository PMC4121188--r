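#' Construct a simulation state
#'
#' Low-level constructor, mostly useful in tests. A state bundles three
#' tables plus scalars:
#'
#' * `cells`: one row per chromosome-containing cell (`cell_id`,
#'   `parent_id`, `L0` birth length nm, `born_at` min, `length` current
#'   cached length nm).
#' * `comp`: one row per compartment, ordered old pole to new pole within a
#'   cell (`cell_id`, `pos`, `L_start`, `Td`, `tau`, `T_seg`, `length`).
#' * `sites`: one row per potential division site (`cell_id`, `kind` in
#'   `polar_old`/`polar_new`/`nonpolar`, `boundary` — for an active
#'   non-polar site the boundary index (number of compartments to its
#'   left), for a blocked non-polar record the position of the merged
#'   compartment it lives in, `NA` for polar sites —, `blocked`, `t_w`
#'   assigned waiting time (NA while blocked), `s` progression,
#'   `appeared_at` formation time).
#'
#' Minicells are not represented as rows; only their count is tracked.
#'
#' @param cells,comp,sites Data frames as described above.
#' @param t Current simulation time, minutes.
#' @param minicell_count Number of minicells produced so far.
#' @param config The `sim_config` governing the run.
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(cells, comp, sites, t = 0, minicell_count = 0L,
                      config = sim_config(n_init = 1)) {
  structure(
    list(t = t, minicell_count = as.integer(minicell_count),
         next_id = max(c(0L, cells$cell_id)) + 1L,
         cells = as.data.frame(cells), comp = as.data.frame(comp),
         sites = as.data.frame(sites),
         events = list(), config = config),
    class = "sim_state"
  )
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state> t =", x$t, "min |", nrow(x$cells), "cells |",
      nrow(x$comp), "compartments |", sum(!x$sites$blocked), "active sites |",
      sum(x$sites$blocked), "blocked |", x$minicell_count, "minicells\n")
  invisible(x)
}

empty_sites <- function() {
  data.frame(cell_id = integer(0), kind = character(0), boundary = integer(0),
             blocked = logical(0), t_w = numeric(0), s = numeric(0),
             appeared_at = numeric(0))
}

#' Initialize a random population
#'
#' Creates `n_init` cells with a chromosome (compartment) number drawn
#' uniformly from 1 to 3. Each compartment gets a newborn length from the
#' configured normal and is aged by a uniform random fraction of its own
#' doubling time, with the replication timer set to the remaining time to
#' doubling. Non-polar sites exist at every compartment boundary; minB-
#' cells additionally carry one old-pole and one new-pole site. All sites
#' start unblocked with freshly assigned waiting times.
#'
#' Uses the current RNG state; wrap in [withr::with_seed()] (or call via
#' [run_simulation()], which seeds from the config) for reproducibility.
#'
#' @param config A [sim_config()].
#' @return A `sim_state`.
#' @export
init_population <- function(config) {
  p <- config$params
  n <- config$n_init
  k <- sample(1:3, n, replace = TRUE)
  cell_id <- rep.int(seq_len(n), k)
  m <- length(cell_id)
  L0 <- rnorm_pos(m, param(p, "L0_mean"), param(p, "L0_sd"))
  Td <- assign_doubling_time(m, p, shared = config$shared_Td)
  u <- stats::runif(m)
  tau <- u * Td
  len <- L0 * 2^u
  comp <- data.frame(
    cell_id = cell_id,
    pos = sequence(k),
    L_start = L0, Td = Td, tau = tau,
    T_seg = replication_time(len, 2 * L0, Td),
    length = len
  )
  cells <- data.frame(cell_id = seq_len(n), parent_id = NA_integer_,
                      L0 = NA_real_, born_at = 0, length = NA_real_)
  cells$length <- cell_lengths(comp, cells$cell_id)
  cells$L0 <- cells$length

  # non-polar sites at internal boundaries
  nb <- pmax(k - 1L, 0L)
  np_cell <- rep.int(seq_len(n), nb)
  np <- data.frame(cell_id = np_cell,
                   kind = rep("nonpolar", length(np_cell)),
                   boundary = sequence(nb),
                   blocked = rep(FALSE, length(np_cell)),
                   t_w = assign_waiting_time(length(np_cell), "nonpolar",
                                             config$model_variant,
                                             config$strain, p),
                   s = rep(0, length(np_cell)),
                   appeared_at = rep(0, length(np_cell)))
  sites <- np
  if (config$strain == "minB") {
    pol <- data.frame(
      cell_id = rep(seq_len(n), 2L),
      kind = rep(c("polar_old", "polar_new"), each = n),
      boundary = NA_integer_, blocked = FALSE, t_w = NA_real_,
      s = 0, appeared_at = 0
    )
    pol <- pol[order(pol$cell_id, pol$kind), , drop = FALSE]
    pol$t_w <- assign_waiting_time(nrow(pol), "polar", config$model_variant,
                                   config$strain, p)
    sites <- rbind(np, pol)
  }
  sites <- sites[order(sites$cell_id, sites$kind, sites$boundary), , drop = FALSE]
  rownames(sites) <- NULL
  sim_state(cells, comp, sites, t = 0, minicell_count = 0L, config = config)
}

#' Check the structural invariants of a simulation state
#'
#' Reports (rather than raises) violations of the state invariants: cached
#' cell lengths must equal the sum of compartment lengths; the number of
#' active non-polar sites must be one less than the number of compartments;
#' minB- cells carry exactly one old-pole and one new-pole site; lengths
#' are positive; ages, timers and progression are non-negative.
#'
#' @param state A `sim_state`.
#' @return A character vector of violation descriptions; empty when the
#'   state is consistent.
#' @export
validate_state <- function(state) {
  out <- character(0)
  cells <- state$cells; comp <- state$comp; sites <- state$sites
  lens <- cell_lengths(comp, cells$cell_id)
  bad <- which(abs(lens - cells$length) > 1e-6 * pmax(lens, 1))
  for (i in bad) {
    out <- c(out, sprintf(
      "cell %d: recorded length %.6g != sum of compartment lengths %.6g",
      cells$cell_id[i], cells$length[i], lens[i]))
  }
  if (any(comp$length <= 0)) out <- c(out, "non-positive compartment length")
  if (any(comp$tau < 0)) out <- c(out, "negative compartment age")
  if (any(comp$T_seg < 0)) out <- c(out, "negative replication timer")
  if (nrow(sites) > 0 && any(sites$s < 0)) out <- c(out, "negative site progression")

  ncomp <- table(factor(comp$cell_id, levels = cells$cell_id))
  active_np <- sites[!sites$blocked & sites$kind == "nonpolar", , drop = FALSE]
  nnp <- table(factor(active_np$cell_id, levels = cells$cell_id))
  bad <- which(as.integer(nnp) != as.integer(ncomp) - 1L)
  for (i in bad) {
    out <- c(out, sprintf(
      "cell %d: %d active non-polar sites for %d compartments (expected %d)",
      cells$cell_id[i], as.integer(nnp)[i], as.integer(ncomp)[i],
      as.integer(ncomp)[i] - 1L))
  }
  if (state$config$strain == "minB") {
    for (kk in c("polar_old", "polar_new")) {
      np_k <- table(factor(sites$cell_id[sites$kind == kk], levels = cells$cell_id))
      bad <- which(as.integer(np_k) != 1L)
      for (i in bad) {
        out <- c(out, sprintf("cell %d: %d %s sites (expected 1)",
                              cells$cell_id[i], as.integer(np_k)[i], kk))
      }
    }
  }
  if (state$minicell_count < 0) out <- c(out, "negative minicell count")
  out
}

#' Tabulate a population snapshot
#'
#' @param state A `sim_state`.
#' @return A tibble with one row per chromosome-containing cell: `t_min`,
#'   `cell_id`, `parent_id`, `born_at`, `L0_nm`, `length_nm`,
#'   `n_compartments`, `n_sites_active`, `n_sites_blocked`, `is_minicell`
#'   (always `FALSE` for simulator output; minicells are only counted).
#' @export
snapshot_state <- function(state) {
  cells <- state$cells
  ncomp <- tabulate_by(state$comp$cell_id, cells$cell_id)
  act <- state$sites[!state$sites$blocked, , drop = FALSE]
  blk <- state$sites[state$sites$blocked, , drop = FALSE]
  tibble::tibble(
    t_min = state$t,
    cell_id = cells$cell_id,
    parent_id = cells$parent_id,
    born_at = cells$born_at,
    L0_nm = cells$L0,
    length_nm = cells$length,
    n_compartments = ncomp,
    n_sites_active = tabulate_by(act$cell_id, cells$cell_id),
    n_sites_blocked = tabulate_by(blk$cell_id, cells$cell_id),
    is_minicell = FALSE
  )
}

tabulate_by <- function(ids, levels) {
  as.integer(table(factor(ids, levels = levels)))
}
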