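#' Assign a division waiting time to a site
#'
#' Each (unblocked) potential division site receives a waiting time drawn
#' from a normal distribution; division completes once the site's
#' progression variable reaches it. Which normal is used depends on the
#' model variant and strain:
#'
#' * model 4, or any model applied to WT: the wild-type distribution
#'   (17.7 +/- 11.9 min) for every site kind;
#' * model 3 (minB-): the non-polar distribution for every site kind
#'   (polar and non-polar sites are a priori equivalent);
#' * models 1-2 (minB-): the measured polar distribution for polar sites
#'   and the non-polar distribution for non-polar sites.
#'
#' Draws are not truncated: the measured distributions are reported as
#' normals with these moments, and truncating would distort both. A
#' non-positive assigned waiting time simply completes at the first
#' progression step (waiting ~ 0).
#'
#' @param n Number of draws.
#' @param site_kind `"polar"`, `"polar_old"`, `"polar_new"` or
#'   `"nonpolar"`; scalar or length-`n` vector.
#' @param model_variant 1-4.
#' @param strain `"WT"` or `"minB"`.
#' @param params A [div_params()] object.
#' @return Numeric vector of waiting times, minutes.
#' @examples
#' withr::with_seed(1, mean(assign_waiting_time(1e4, "nonpolar", 4, "WT")))
#' @export
assign_waiting_time <- function(n, site_kind, model_variant, strain,
                                params = div_params()) {
  if (n == 0) return(numeric(0))
  kind <- rep_len(ifelse(site_kind == "nonpolar", "nonpolar", "polar"), n)
  if (strain == "WT" || model_variant == 4L) {
    m <- param(params, "w_wt_mean"); s <- param(params, "w_wt_sd")
    return(stats::rnorm(n, m, s))
  }
  if (model_variant == 3L) {
    return(stats::rnorm(n, param(params, "w_nonpolar_mean"),
                        param(params, "w_nonpolar_sd")))
  }
  mu <- ifelse(kind == "polar", param(params, "w_polar_mean"),
               param(params, "w_nonpolar_mean"))
  sd <- ifelse(kind == "polar", param(params, "w_polar_sd"),
               param(params, "w_nonpolar_sd"))
  stats::rnorm(n, mu, sd)
}

#' Progression rate of the division machinery at a site
#'
#' In models 1-3 every active site progresses at unit rate, so the realized
#' waiting time equals the assigned one. Model 4 makes sites compete for a
#' limited pool of division machinery whose amount scales with cell length:
#' for minB- cells `f = ftsz_factor * c * L / (n_sites * Lc)`, and for WT
#' cells, where the Min oscillations confine the machinery to roughly half
#' the cell around midcell, `f = c * (L/2) / (n_sites * Lc)`. The constant
#' `c` (default 2) is calibrated so that the reference WT geometry — one
#' compartment of length `Lc` with a single active site — progresses at
#' `f = 1` and hence reproduces the measured WT waiting-time distribution.
#'
#' @param L Cell length(s), nm.
#' @param n_sites Number of active (unblocked) potential division sites in
#'   the cell, at least 1. Poles count in minB- cells but not in WT.
#' @param model_variant 1-4.
#' @param strain `"WT"` or `"minB"`.
#' @param ftsz_factor Division-machinery (FtsZ) level multiplier.
#' @param params A [div_params()] object.
#' @return Dimensionless rate(s) `f`.
#' @examples
#' progression_rate(2500, 1, 4, "WT", 1)   # reference geometry: 1
#' @export
progression_rate <- function(L, n_sites, model_variant, strain,
                             ftsz_factor = 1, params = div_params()) {
  if (any(L <= 0)) stop("L must be > 0", call. = FALSE)
  if (any(n_sites < 1)) stop("n_sites must be >= 1", call. = FALSE)
  if (model_variant != 4L) return(rep_len(1, max(length(L), length(n_sites))))
  cc <- param(params, "c_rate")
  Lc <- param(params, "Lc")
  L_eff <- if (strain == "WT") L / 2 else ftsz_factor * L
  cc * L_eff / (n_sites * Lc)
}

#' Advance division-site progression by one step
#'
#' Every active site's progression advances by `f * dt`, with `f` from
#' [progression_rate()] recomputed each step from the current cell length
#' and current number of active sites (both change as the cell grows and
#' as sites appear or disappear). Blocked sites do not progress.
#'
#' @param state A `sim_state`.
#' @param dt Step width, minutes.
#' @return The updated state; completed sites (`s >= t_w`) are picked up by
#'   [execute_divisions()].
#' @export
advance_progression <- function(state, dt) {
  sites <- state$sites
  act <- which(!sites$blocked)
  if (length(act) == 0) return(state)
  cfg <- state$config
  if (cfg$model_variant == 4L) {
    n_per_cell <- table(sites$cell_id[act])
    cells <- state$cells
    i <- match(sites$cell_id[act], cells$cell_id)
    L <- cells$length[i]
    n_sites <- as.integer(n_per_cell[as.character(sites$cell_id[act])])
    f <- progression_rate(L, n_sites, 4L, cfg$strain, cfg$ftsz_factor,
                          cfg$params)
  } else {
    f <- 1
  }
  sites$s[act] <- sites$s[act] + f * dt
  state$sites <- sites
  state
}

#' Execute completed division events
#'
#' Sites whose progression has reached their assigned waiting time divide.
#' A polar division pinches off a minicell: the minicell count increases,
#' the cell's length and compartments are unchanged (minicells are much
#' smaller and are only counted), and the pole is re-armed with a freshly
#' assigned waiting time while keeping its formation time. A non-polar
#' division splits the cell at the compartment boundary into two daughters
#' whose lengths are the compartment sums on each side; each daughter's
#' birth length and time are reset, carried-over sites keep their assigned
#' waiting time and progression, and the septum becomes each daughter's
#' new pole (which in minB- cells enters the blocking lottery as a new
#' potential site). At most one non-polar division per cell is executed
#' per step (any further completed site divides in a later step, an error
#' of at most `dt`); cells are processed in `cell_id` order.
#'
#' @param state A `sim_state`.
#' @return The updated state with division/minicell events appended to the
#'   event log.
#' @export
execute_divisions <- function(state) {
  sites <- state$sites
  done <- which(!sites$blocked & !is.na(sites$t_w) & sites$s >= sites$t_w)
  if (length(done) == 0) return(state)
  cfg <- state$config
  p <- cfg$params

  polar_done <- done[sites$kind[done] != "nonpolar"]
  np_done <- done[sites$kind[done] == "nonpolar"]

  # ---- polar divisions: minicells --------------------------------------
  if (length(polar_done) > 0) {
    polar_done <- polar_done[order(sites$cell_id[polar_done],
                                   sites$kind[polar_done])]
    cells <- state$cells
    i <- match(sites$cell_id[polar_done], cells$cell_id)
    ncomp <- tabulate_by(state$comp$cell_id, cells$cell_id)
    ev <- data.frame(
      t_min = state$t, event = "minicell",
      cell_id = sites$cell_id[polar_done],
      parent_id = cells$parent_id[i],
      site_class = sites$kind[polar_done],
      site_appeared_t = sites$appeared_at[polar_done],
      birth_t = cells$born_at[i], birth_length_nm = cells$L0[i],
      cell_length_nm = cells$length[i],
      n_compartments = ncomp[i],
      daughter1_id = NA_integer_, daughter2_id = NA_integer_,
      daughter1_length_nm = NA_real_, daughter2_length_nm = NA_real_)
    state <- log_events(state, ev)
    state$minicell_count <- state$minicell_count + length(polar_done)
    # re-arm: fresh waiting time, progression reset, formation time kept
    sites$t_w[polar_done] <- assign_waiting_time(
      length(polar_done), "polar", cfg$model_variant, cfg$strain, p)
    sites$s[polar_done] <- 0
    state$sites <- sites
  }

  # ---- non-polar divisions: one per cell per step ----------------------
  if (length(np_done) == 0) return(state)
  excess <- sites$s[np_done] - sites$t_w[np_done]
  ord <- order(sites$cell_id[np_done], -excess, sites$boundary[np_done])
  np_done <- np_done[ord]
  np_done <- np_done[!duplicated(sites$cell_id[np_done])]
  np_done <- np_done[order(sites$cell_id[np_done])]

  cp <- state$comp
  cells <- state$cells
  sites <- state$sites
  div_cells <- sites$cell_id[np_done]          # ascending, unique
  ndiv <- length(div_cells)
  k_vec <- sites$boundary[np_done]
  nid <- state$next_id
  idA <- nid + 2L * (seq_len(ndiv) - 1L)
  idB <- idA + 1L
  state$next_id <- nid + 2L * ndiv

  # ---- compartments ----------------------------------------------------
  sel <- cp$cell_id %in% div_cells
  cpd <- cp[sel, , drop = FALSE]
  m <- match(cpd$cell_id, div_cells)
  n_per <- tabulate(m, ndiv)
  left <- cpd$pos <= k_vec[m]
  cpd$cell_id <- ifelse(left, idA[m], idB[m])
  # daughter B is reversed so compartments stay ordered old pole -> new
  cpd$pos <- ifelse(left, cpd$pos, n_per[m] - cpd$pos + 1L)
  LA <- as.numeric(rowsum(cpd$length * left, m, reorder = TRUE))
  LB <- as.numeric(rowsum(cpd$length * !left, m, reorder = TRUE))

  # ---- sites -----------------------------------------------------------
  sel_s <- sites$cell_id %in% div_cells
  ssd <- sites[sel_s, , drop = FALSE]
  m2 <- match(ssd$cell_id, div_cells)
  k2 <- k_vec[m2]; n2 <- n_per[m2]
  is_np <- ssd$kind == "nonpolar"
  septum <- is_np & !ssd$blocked & ssd$boundary == k2
  site_app <- sites$appeared_at[np_done]
  ssd <- ssd[!septum, , drop = FALSE]
  m2 <- m2[!septum]; k2 <- k2[!septum]; n2 <- n2[!septum]
  is_np <- is_np[!septum]
  toA <- (is_np & ((!ssd$blocked & ssd$boundary < k2) |
                     (ssd$blocked & ssd$boundary <= k2))) |
    ssd$kind == "polar_old"
  ssd$cell_id <- ifelse(toA, idA[m2], idB[m2])
  # reindex daughter-B boundaries after reversal: active j -> n - j,
  # attached blocked position a -> n - a + 1
  bnd <- ssd$boundary
  fixB <- !toA & is_np
  bnd[fixB & !ssd$blocked] <- n2[fixB & !ssd$blocked] - bnd[fixB & !ssd$blocked]
  bnd[fixB & ssd$blocked] <- n2[fixB & ssd$blocked] - bnd[fixB & ssd$blocked] + 1L
  ssd$boundary <- bnd
  # the parent new pole predates daughter B: it is B's old pole
  ssd$kind[ssd$kind == "polar_new"] <- "polar_old"

  # ---- fresh poles at the septum (minB- only) --------------------------
  newpoles <- NULL
  if (cfg$strain == "minB") {
    pole_ids <- as.vector(rbind(idA, idB))      # ascending daughter ids
    if (cfg$model_variant >= 2L) {
      # each septum pole is a new potential site: the full blocking
      # lottery runs over the daughter's inherited blocked pool plus the
      # new pole, exactly as at a segregation event
      cpl <- split(cpd, cpd$cell_id)
      ssl <- split(ssd, ssd$cell_id)
      comp_list <- vector("list", length(pole_ids))
      site_list <- vector("list", length(pole_ids))
      for (j in seq_along(pole_ids)) {
        id <- pole_ids[j]
        cc <- cpl[[as.character(id)]]
        cc <- cc[order(cc$pos), , drop = FALSE]
        ss <- ssl[[as.character(id)]]
        if (is.null(ss)) ss <- empty_sites()
        pole <- data.frame(cell_id = id, kind = "polar_new",
                           boundary = NA_integer_, blocked = FALSE,
                           t_w = NA_real_, s = 0, appeared_at = state$t)
        res <- cell_lottery(cc, ss, integer(0), pole, cfg, state$t)
        comp_list[[j]] <- res$comp
        site_list[[j]] <- res$sites
      }
      cpd <- do.call(rbind, comp_list)
      ssd <- do.call(rbind, site_list)
    } else {
      newpoles <- data.frame(
        cell_id = pole_ids, kind = "polar_new", boundary = NA_integer_,
        blocked = FALSE,
        t_w = assign_waiting_time(length(pole_ids), "polar",
                                  cfg$model_variant, cfg$strain, p),
        s = 0, appeared_at = state$t)
    }
  }

  # ---- bookkeeping -----------------------------------------------------
  ci <- match(div_cells, cells$cell_id)
  ev <- data.frame(
    t_min = state$t, event = "division", cell_id = div_cells,
    parent_id = cells$parent_id[ci], site_class = "nonpolar",
    site_appeared_t = site_app,
    birth_t = cells$born_at[ci], birth_length_nm = cells$L0[ci],
    cell_length_nm = cells$length[ci], n_compartments = n_per,
    daughter1_id = idA, daughter2_id = idB,
    daughter1_length_nm = LA, daughter2_length_nm = LB)
  daughters <- data.frame(
    cell_id = c(idA, idB), parent_id = rep(div_cells, 2L),
    L0 = c(LA, LB), born_at = state$t, length = c(LA, LB))

  cp2 <- rbind(cp[!sel, , drop = FALSE], cpd)
  cp2 <- cp2[order(cp2$cell_id, cp2$pos), , drop = FALSE]
  rownames(cp2) <- NULL
  st2 <- rbind(sites[!sel_s, , drop = FALSE], ssd, newpoles)
  st2 <- st2[order(st2$cell_id, st2$kind, st2$boundary), , drop = FALSE]
  rownames(st2) <- NULL
  cl2 <- rbind(cells[!(cells$cell_id %in% div_cells), , drop = FALSE], daughters)
  cl2 <- cl2[order(cl2$cell_id), , drop = FALSE]
  rownames(cl2) <- NULL
  state$comp <- cp2
  state$sites <- st2
  state$cells <- cl2
  log_events(state, ev)
}
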