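#' Generate a synthetic lineage tracking table
#'
#' Emulates microscopy-derived single-cell tracking records with the
#' statistical structure the simulator assumes: exponential growth with
#' doubling times from the configured normal, per-class division waiting
#' times from the configured normals, placement noise capped at 10% of the
#' half length, and observed chromosome-cluster counts offset from the
#' expected number by the blocking target plus rounding noise. Events
#' whose division falls past the observation window are right-censored
#' (dropped and counted in attribute `n_censored`), mirroring the finite
#' experimental observation time.
#'
#' Each founder cell is observed for `n_generations` rounds: in the
#' `"minB"` preset a cell may first bud off minicells at its old and/or
#' new pole (each with probability `p_polar`) before dividing at a
#' non-polar site into two daughters; in the `"wt"` preset all divisions
#' are non-polar with wild-type waiting times.
#'
#' @param n_cells Number of founder cells.
#' @param params A [div_params()] object.
#' @param preset `"wt"` or `"minB"`: which waiting-time distributions and
#'   cluster structure to emulate.
#' @param window_min Observation window, minutes (default 213).
#' @param n_generations Lineage depth (default 2).
#' @param p_polar Per-pole probability of a minicell event before the
#'   non-polar division (minB preset; default 0.35).
#' @param cluster_noise_sd SD of the counting noise added before rounding
#'   the observed cluster number (default 0.1; set 0 for a fully
#'   deterministic table when all distribution SDs are 0).
#' @param seed Optional integer seed (explicit, no global state assumed).
#' @return A `tracking_table` tibble; attributes `n_censored` and
#'   `params`.
#' @examples
#' tr <- generate_tracking(50, preset = "wt", seed = 1)
#' waiting_time_summary(tr)
#' @export
generate_tracking <- function(n_cells, params = div_params(),
                              preset = c("minB", "wt"), window_min = 213,
                              n_generations = 2, p_polar = 0.35,
                              cluster_noise_sd = 0.1, seed = NULL) {
  preset <- match.arg(preset)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_tracking(
      n_cells, params, preset, window_min, n_generations, p_polar,
      cluster_noise_sd, seed = NULL)))
  }
  p <- params
  strain <- if (preset == "wt") "WT" else "minB"
  # model 1 parameterization: measured per-class waiting normals for minB-,
  # the wild-type normal for WT
  draw_wait <- function(n, kind) assign_waiting_time(n, kind, 1L, strain, p)
  rows <- list()
  n_censored <- 0L
  next_id <- n_cells + 1L

  gen <- list(tibble::tibble(
    cell_id = seq_len(n_cells),
    parent_id = NA_integer_,
    birth_t = seq(0, 30, length.out = n_cells),
    birth_length_nm = rnorm_pos(n_cells,
                                if (preset == "minB") 2 * param(p, "L0_mean")
                                else param(p, "L0_mean"),
                                param(p, "L0_sd"))
  ))

  for (g in seq_len(n_generations)) {
    cur <- gen[[g]]
    if (nrow(cur) == 0) break
    Td <- assign_doubling_time(nrow(cur), p)
    # polar (minicell) events before the non-polar division
    if (preset == "minB") {
      for (pole in c("polar_old", "polar_new")) {
        has <- stats::runif(nrow(cur)) < p_polar
        if (any(has)) {
          w <- draw_wait(sum(has), "polar")
          div_t <- cur$birth_t[has] + pmax(w, 0)
          len <- cur$birth_length_nm[has] * 2^((div_t - cur$birth_t[has]) / Td[has])
          keep <- div_t <= window_min
          n_censored <- n_censored + sum(!keep)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            cell_id = cur$cell_id[has][keep],
            parent_id = cur$parent_id[has][keep],
            birth_t = cur$birth_t[has][keep],
            division_t = div_t[keep],
            birth_length_nm = cur$birth_length_nm[has][keep],
            division_length_nm = len[keep],
            division_class = pole,
            site_appeared_t = cur$birth_t[has][keep],
            n_clusters = cluster_count(len[keep], p, preset, cluster_noise_sd)
          )
        }
      }
    }
    # non-polar division: site appears once the cell has doubled; the
    # waiting draw is used as-is so the observed waits keep the stated
    # normal moments (a few percent are marginally negative, mirroring
    # scoring noise in when a separation first becomes visible)
    site_t <- cur$birth_t + Td
    w <- draw_wait(nrow(cur), "nonpolar")
    div_t <- site_t + w
    div_len <- cur$birth_length_nm * 2^((div_t - cur$birth_t) / Td)
    keep <- div_t <= window_min
    n_censored <- n_censored + sum(!keep)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cell_id = cur$cell_id[keep], parent_id = cur$parent_id[keep],
      birth_t = cur$birth_t[keep], division_t = div_t[keep],
      birth_length_nm = cur$birth_length_nm[keep],
      division_length_nm = div_len[keep],
      division_class = "nonpolar", site_appeared_t = site_t[keep],
      n_clusters = cluster_count(div_len[keep], p, preset, cluster_noise_sd)
    )
    # daughters with capped placement noise
    nk <- sum(keep)
    if (nk > 0 && g < n_generations) {
      halves <- split_lengths(div_len[keep], param(p, "delta_sd"))
      ids <- next_id + seq_len(2L * nk) - 1L
      next_id <- next_id + 2L * nk
      gen[[g + 1L]] <- tibble::tibble(
        cell_id = ids,
        parent_id = rep(cur$cell_id[keep], 2L),
        birth_t = rep(div_t[keep], 2L),
        birth_length_nm = c(halves$L1, halves$L2)
      )
    } else if (g < n_generations) {
      gen[[g + 1L]] <- gen[[g]][0, ]
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$cell_id, out$division_t), , drop = FALSE]
  class(out) <- c("tracking_table", class(out))
  attr(out, "n_censored") <- n_censored
  attr(out, "params") <- params
  out
}

# observed cluster count: expected number minus the blocking offset plus
# rounding noise, never below 1
cluster_count <- function(len, params, preset, noise_sd = 0.1) {
  if (length(len) == 0) return(integer(0))
  n_exp <- len / param(params, "L0_mean")
  off <- if (preset == "minB") param(params, "n_block_target") else 0
  noise <- if (noise_sd > 0) stats::rnorm(length(len), 0, noise_sd) else 0
  pmax(1L, as.integer(round(n_exp - off + noise)))
}

#' Generate a synthetic population snapshot
#'
#' Cell lengths are drawn from a configurable normal mixture (emulating
#' the broad minB- length distribution with its filamentous tail, or a
#' narrow wild-type one), with an optional minicell fraction. Per-cell
#' active site counts follow the expected chromosome number minus the
#' blocking offset.
#'
#' @param n_cells Number of cells.
#' @param params A [div_params()] object.
#' @param mixture A data frame with columns `mean`, `sd`, `weight` (nm);
#'   default: a three-component minB--like mixture at 1x, 2x and 4x the
#'   newborn length.
#' @param minicell_fraction Fraction of rows that are minicells
#'   (`is_minicell = TRUE`, short, no chromosome).
#' @param seed Optional integer seed.
#' @return A snapshot tibble (`t_min`, `cell_id`, `length_nm`,
#'   `n_compartments`, `n_sites_active`, `is_minicell`).
#' @export
generate_snapshot <- function(n_cells, params = div_params(), mixture = NULL,
                              minicell_fraction = 0, seed = NULL) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_snapshot(
      n_cells, params, mixture, minicell_fraction, seed = NULL)))
  }
  L0 <- param(params, "L0_mean")
  if (is.null(mixture)) {
    mixture <- data.frame(mean = L0 * c(1, 2, 4), sd = L0 * c(0.15, 0.3, 0.6),
                          weight = c(0.5, 0.3, 0.2))
  }
  wgt <- mixture$weight / sum(mixture$weight)
  comp <- sample.int(nrow(mixture), n_cells, replace = TRUE, prob = wgt)
  len <- rnorm_pos(n_cells, mixture$mean[comp], mixture$sd[comp])
  mini <- stats::runif(n_cells) < minicell_fraction
  len[mini] <- rnorm_pos(sum(mini), 400, 80)
  ncomp <- pmax(1L, as.integer(round(len / L0)))
  nsites <- pmax(0L, ncomp - 1L -
                   stats::rbinom(n_cells, 2, 0.5))
  ncomp[mini] <- 0L
  nsites[mini] <- 0L
  tibble::tibble(
    t_min = 0, cell_id = seq_len(n_cells), length_nm = len,
    n_compartments = ncomp, n_sites_active = nsites, is_minicell = mini
  )
}
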