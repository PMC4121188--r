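#' Blocking threshold for the segregation-defect lottery
#'
#' Whenever a new potential division site appears in a minB- cell (models
#' 2-4), fresh uniform marks are assigned to all currently blocked sites of
#' that cell and to the new site; sites whose mark exceeds the threshold
#' `p_th` are (re-)blocked. Setting
#' `p_th = max(0, 1 - n_block_target / n_randomized)` makes the expected
#' number of blocked sites after the lottery equal
#' `min(n_block_target, n_randomized)`, which maintains the observed
#' average of two blocked potential division sites per cell.
#'
#' @param n_blocked_now Number of currently blocked sites entering the
#'   lottery (informational; the threshold depends only on `n_randomized`).
#' @param n_randomized Total number of sites receiving fresh marks
#'   (blocked + new), at least 1.
#' @param n_block_target Desired mean number of blocked sites per cell.
#' @return The threshold probability `p_th` in `[0, 1]`.
#' @examples
#' block_threshold(1, 2, 2)  # 0: both marks exceed it, both blocked
#' block_threshold(2, 5, 2)  # 0.6: expect 5 * 0.4 = 2 blocked
#' @export
block_threshold <- function(n_blocked_now, n_randomized, n_block_target) {
  if (any(n_randomized < 1)) stop("n_randomized must be >= 1", call. = FALSE)
  if (any(n_block_target < 0)) stop("n_block_target must be >= 0", call. = FALSE)
  pmax(0, 1 - n_block_target / n_randomized)
}

#' Split a compartment in two with capped placement noise
#'
#' Division-site placement is noisy: the split point deviates from the
#' midpoint by `delta ~ Normal(0, delta_sd)`, redrawn until the first
#' daughter deviates at most 10% from half the parent length. Lengths are
#' conserved exactly: `L1 + L2 = L_parent`.
#'
#' @param L_parent Parent compartment length(s), nm (vectorized).
#' @param delta_sd Placement-noise standard deviation, nm.
#' @param max_dev Maximum allowed relative deviation of `L1` from
#'   `L_parent / 2` (default 0.1).
#' @param max_tries Rejection-sampling cap; exceeding it is a
#'   configuration error (`delta_sd` far larger than the cap allows).
#' @return A tibble with columns `L1` and `L2`, one row per parent.
#' @examples
#' withr::with_seed(1, split_lengths(5000, delta_sd = 100))
#' @export
split_lengths <- function(L_parent, delta_sd, max_dev = 0.1, max_tries = 1e4) {
  if (any(L_parent <= 0)) stop("L_parent must be > 0", call. = FALSE)
  n <- length(L_parent)
  if (delta_sd == 0) {
    return(tibble::tibble(L1 = L_parent / 2, L2 = L_parent / 2))
  }
  cap <- max_dev * L_parent / 2
  delta <- stats::rnorm(n, 0, delta_sd)
  bad <- which(abs(delta) > cap)
  tries <- 0L
  while (length(bad) > 0) {
    delta[bad] <- stats::rnorm(length(bad), 0, delta_sd)
    bad <- bad[abs(delta[bad]) > cap[bad]]
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("placement-noise rejection did not converge; delta_sd too large ",
           "for the 10% cap", call. = FALSE)
    }
  }
  L1 <- L_parent / 2 + delta
  tibble::tibble(L1 = L1, L2 = L_parent - L1)
}

# Fresh compartment rows after a split piece is created: a new round of
# replication starts, so each piece draws a new doubling time, resets its
# age, and gets a full-doubling replication timer.
new_piece <- function(cell_id, len, Td) {
  data.frame(cell_id = cell_id, pos = NA_integer_, L_start = len, Td = Td,
             tau = 0, T_seg = Td, length = len)
}

#' Segregate replication-complete compartments
#'
#' Processes every compartment whose replication timer has reached zero.
#' In model 1 (and for WT, where there is no segregation defect) each such
#' compartment splits into two via [split_lengths()], and the new boundary
#' becomes an active non-polar division site with a freshly assigned
#' waiting time. In models 2-4 for minB- cells, each appearance of a new
#' prospective boundary triggers the blocking lottery of
#' [block_threshold()] over all currently blocked sites of the cell plus
#' the new boundary: boundaries whose mark exceeds the threshold are
#' blocked (the chromosomes do not segregate there and the compartment
#' stays merged, restarting a replication round), previously blocked
#' boundaries whose fresh mark falls below the threshold segregate now,
#' and blocked polar sites that fall below the threshold become active
#' with a newly assigned waiting time.
#'
#' @param state A `sim_state`.
#' @return The updated state (also logs segregation events when configured).
#' @export
segregate_step <- function(state) {
  done <- which(state$comp$T_seg <= 0)
  if (length(done) == 0) return(state)
  cfg <- state$config
  blocking <- cfg$strain == "minB" && cfg$model_variant >= 2L
  if (!blocking) {
    segregate_fast(state, done)
  } else {
    segregate_blocked(state, done)
  }
}

# -- no-blocking path: every completed compartment splits in two ------------
segregate_fast <- function(state, done) {
  cfg <- state$config
  p <- cfg$params
  cp <- state$comp
  n_done <- length(done)
  flag <- logical(nrow(cp)); flag[done] <- TRUE

  halves <- split_lengths(cp$length[done], param(p, "delta_sd"))
  Td_kids <- matrix(assign_doubling_time(2L * n_done, p, cfg$shared_Td),
                    ncol = 2, byrow = TRUE)
  t_w_new <- assign_waiting_time(n_done, "nonpolar", cfg$model_variant,
                                 cfg$strain, p)

  # per-cell cumulative number of splits at or before each position
  cum_done <- stats::ave(as.numeric(flag), cp$cell_id, FUN = cumsum)

  idx <- rep.int(seq_len(nrow(cp)), 1L + flag)         # done rows duplicated
  new <- cp[idx, , drop = FALSE]
  child2 <- duplicated(idx)                            # second copy = right child
  child1 <- flag[idx] & !child2                        # first copy = left child
  new$length[child1] <- halves$L1
  new$length[child2] <- halves$L2
  new$L_start[child1] <- halves$L1
  new$L_start[child2] <- halves$L2
  new$Td[child1] <- Td_kids[, 1]
  new$Td[child2] <- Td_kids[, 2]
  new$tau[flag[idx]] <- 0
  new$T_seg[child1] <- Td_kids[, 1]
  new$T_seg[child2] <- Td_kids[, 2]
  new$pos <- stats::ave(rep(1, nrow(new)), new$cell_id, FUN = cumsum)
  rownames(new) <- NULL

  # shift existing non-polar boundaries: boundary j gains one compartment
  # for every split at position <= j in the same cell
  sites <- state$sites
  if (nrow(sites) > 0) {
    np <- which(sites$kind == "nonpolar" & !sites$blocked)
    if (length(np) > 0) {
      key_comp <- cp$cell_id * 1e7 + cp$pos
      key_site <- sites$cell_id[np] * 1e7 + sites$boundary[np]
      shift <- cum_done[match(key_site, key_comp)]
      sites$boundary[np] <- sites$boundary[np] + as.integer(shift)
    }
  }
  # new boundary between the two children of a split at old position q:
  # index q + (cumulative splits through q) - 1
  b_new <- cp$pos[done] + as.integer(cum_done[done]) - 1L
  add <- data.frame(cell_id = cp$cell_id[done], kind = "nonpolar",
                    boundary = b_new, blocked = FALSE, t_w = t_w_new,
                    s = 0, appeared_at = state$t)
  state$comp <- new
  state$sites <- rbind(sites, add)
  if (cfg$log_segregation) {
    state <- log_events(state, data.frame(
      t_min = state$t, event = "segregation", cell_id = cp$cell_id[done],
      parent_id = NA_integer_, site_class = "nonpolar",
      site_appeared_t = state$t, birth_t = NA_real_, birth_length_nm = NA_real_,
      cell_length_nm = NA_real_, n_compartments = NA_integer_,
      daughter1_id = NA_integer_, daughter2_id = NA_integer_,
      daughter1_length_nm = NA_real_, daughter2_length_nm = NA_real_))
  }
  state
}

# -- minB- models 2-4: blocking lottery per cell ----------------------------
#
# One lottery event covers every new potential site appearing in a cell in
# this step (new prospective boundaries from completed replication rounds,
# or a newly formed pole): fresh uniform marks go to all currently blocked
# sites plus the new ones, the threshold is recomputed from the pool size,
# and sites above the threshold are blocked.
cell_lottery <- function(cc, ss, new_bnd, new_pole, cfg, t) {
  p <- cfg$params
  target <- param(p, "n_block_target")
  delta_sd <- param(p, "delta_sd")
  n_new <- length(new_bnd) + NROW(new_pole)
  blk <- which(ss$blocked)
  n_rand <- length(blk) + n_new
  if (n_rand == 0) return(list(comp = cc, sites = ss))
  p_th <- block_threshold(length(blk), n_rand, target)
  marks <- stats::runif(n_rand)
  blk_marks <- marks[seq_along(blk)]
  bnd_marks <- marks[length(blk) + seq_along(new_bnd)]
  pole_marks <- if (NROW(new_pole) > 0) marks[n_rand] else numeric(0)

  unblock <- blk[blk_marks <= p_th]
  # blocked polar sites that unblock become active with a fresh timer
  ub_pol <- unblock[ss$kind[unblock] != "nonpolar"]
  if (length(ub_pol) > 0) {
    ss$blocked[ub_pol] <- FALSE
    ss$t_w[ub_pol] <- assign_waiting_time(length(ub_pol), "polar",
                                          cfg$model_variant, cfg$strain, p)
    ss$s[ub_pol] <- 0
  }
  ub_np <- unblock[ss$kind[unblock] == "nonpolar"]

  # splits per compartment position: one per unblocked boundary living in
  # it, plus one per unblocked new prospective boundary
  n_splits <- integer(nrow(cc))
  add_blocked_at <- integer(0)
  for (j in seq_along(new_bnd)) {
    q <- new_bnd[j]
    if (bnd_marks[j] > p_th) {
      add_blocked_at <- c(add_blocked_at, q)
    } else {
      n_splits[q] <- n_splits[q] + 1L
    }
  }
  for (i in ub_np) n_splits[ss$boundary[i]] <- n_splits[ss$boundary[i]] + 1L
  if (length(ub_np) > 0) ss <- ss[-ub_np, , drop = FALSE]
  stay_np <- which(ss$blocked & ss$kind == "nonpolar")
  stay_pos <- ss$boundary[stay_np]

  done_flag <- logical(nrow(cc)); done_flag[new_bnd] <- TRUE
  if (any(done_flag) || any(n_splits > 0)) {
    pieces <- list(); piece_src <- integer(0)
    boundaries_new <- integer(0)
    pc <- 0L
    for (q in seq_len(nrow(cc))) {
      row <- cc[q, , drop = FALSE]
      u <- n_splits[q]
      if (done_flag[q] || u > 0) {
        if (u == 0) {
          # stays merged: restart replication with a fresh doubling time
          Td <- assign_doubling_time(1L, p, cfg$shared_Td)
          row$Td <- Td; row$tau <- 0; row$L_start <- row$length; row$T_seg <- Td
          pc <- pc + 1L
          pieces[[pc]] <- row; piece_src <- c(piece_src, q)
        } else {
          lens <- row$length
          for (k in seq_len(u)) {
            # split the largest current piece at its midpoint
            tgt <- which.max(lens)
            h <- split_lengths(lens[tgt], delta_sd)
            lens <- append(lens[-tgt], c(h$L1, h$L2), after = tgt - 1L)
          }
          Tds <- assign_doubling_time(length(lens), p, cfg$shared_Td)
          for (k in seq_along(lens)) {
            pc <- pc + 1L
            pieces[[pc]] <- new_piece(cc$cell_id[1], lens[k], Tds[k])
            piece_src <- c(piece_src, q)
          }
          boundaries_new <- c(boundaries_new, pc - seq_len(u))
        }
      } else {
        pc <- pc + 1L
        pieces[[pc]] <- row; piece_src <- c(piece_src, q)
      }
    }
    comp_new <- do.call(rbind, pieces)
    comp_new$pos <- seq_len(nrow(comp_new))

    # remap boundaries: old boundary j -> position of the last piece of old
    # compartment j
    last_piece_of <- cumsum(tabulate(piece_src, nrow(cc)))
    act_np <- which(ss$kind == "nonpolar" & !ss$blocked)
    if (length(act_np) > 0) {
      ss$boundary[act_np] <- last_piece_of[ss$boundary[act_np]]
    }
    # surviving blocked records follow a random piece of their compartment
    if (length(stay_np) > 0) {
      first_piece_of <- c(1L, utils::head(last_piece_of, -1) + 1L)
      new_att <- integer(length(stay_np))
      for (ii in seq_along(stay_np)) {
        q <- stay_pos[ii]
        npieces <- last_piece_of[q] - first_piece_of[q] + 1L
        new_att[ii] <- first_piece_of[q] +
          floor(stats::runif(1) * npieces)
      }
      ss$boundary[stay_np] <- new_att
    }
    if (length(add_blocked_at) > 0) {
      first_piece_of <- c(1L, utils::head(last_piece_of, -1) + 1L)
      ss <- rbind(ss, data.frame(
        cell_id = cc$cell_id[1], kind = "nonpolar",
        boundary = first_piece_of[add_blocked_at], blocked = TRUE,
        t_w = NA_real_, s = 0, appeared_at = t))
    }
    if (length(boundaries_new) > 0) {
      ss <- rbind(ss, data.frame(
        cell_id = cc$cell_id[1], kind = "nonpolar",
        boundary = as.integer(boundaries_new), blocked = FALSE,
        t_w = assign_waiting_time(length(boundaries_new), "nonpolar",
                                  cfg$model_variant, cfg$strain, cfg$params),
        s = 0, appeared_at = t))
    }
    cc <- comp_new
  }
  if (NROW(new_pole) > 0) {
    if (pole_marks > p_th) {
      new_pole$blocked <- TRUE
    } else {
      new_pole$t_w <- assign_waiting_time(1L, "polar", cfg$model_variant,
                                          cfg$strain, cfg$params)
    }
    ss <- rbind(ss, new_pole)
  }
  list(comp = cc, sites = ss)
}

segregate_blocked <- function(state, done) {
  cfg <- state$config
  cp <- state$comp
  sites <- state$sites
  affected_cells <- sort(unique(cp$cell_id[done]))
  keep_comp <- !(cp$cell_id %in% affected_cells)
  keep_site <- !(sites$cell_id %in% affected_cells)
  new_comp <- list(cp[keep_comp, , drop = FALSE])
  new_site <- list(sites[keep_site, , drop = FALSE])
  seg_log <- integer(0)

  cpl <- split(cp[!keep_comp, , drop = FALSE], cp$cell_id[!keep_comp])
  ssl <- split(sites[!keep_site, , drop = FALSE], sites$cell_id[!keep_site])
  for (i in seq_along(affected_cells)) {
    cid <- affected_cells[i]
    cc <- cpl[[as.character(cid)]]
    ss <- ssl[[as.character(cid)]]
    if (is.null(ss)) ss <- empty_sites()
    new_bnd <- which(cc$T_seg <= 0)
    res <- cell_lottery(cc, ss, new_bnd, NULL, cfg, state$t)
    new_comp[[i + 1L]] <- res$comp
    new_site[[i + 1L]] <- res$sites
    seg_log <- c(seg_log, rep.int(cid, length(new_bnd)))
  }
  cp2 <- do.call(rbind, new_comp)
  cp2 <- cp2[order(cp2$cell_id, cp2$pos), , drop = FALSE]
  rownames(cp2) <- NULL
  st2 <- do.call(rbind, new_site)
  st2 <- st2[order(st2$cell_id, st2$kind, st2$boundary), , drop = FALSE]
  rownames(st2) <- NULL
  state$comp <- cp2
  state$sites <- st2
  if (cfg$log_segregation && length(seg_log) > 0) {
    state <- log_events(state, data.frame(
      t_min = state$t, event = "segregation", cell_id = seg_log,
      parent_id = NA_integer_, site_class = "nonpolar",
      site_appeared_t = state$t, birth_t = NA_real_, birth_length_nm = NA_real_,
      cell_length_nm = NA_real_, n_compartments = NA_integer_,
      daughter1_id = NA_integer_, daughter2_id = NA_integer_,
      daughter1_length_nm = NA_real_, daughter2_length_nm = NA_real_))
  }
  state
}

log_events <- function(state, df) {
  state$events[[length(state$events) + 1L]] <- df
  state
}
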