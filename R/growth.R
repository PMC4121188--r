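#' Exponential length increment over one time step
#'
#' Single cells (and compartments) grow exponentially, doubling their birth
#' length `L0` after one doubling time `Td`:
#' `L(tau) = L0 * 2^(tau / Td)`. The increment over a step of width `dt`
#' starting at age `tau` is therefore
#' `dL = L0 * (2^((tau + dt)/Td) - 2^(tau/Td))`, which telescopes exactly:
#' accumulating increments from age 0 to `Td` adds exactly `L0`.
#'
#' All arguments are vectorized and recycled.
#'
#' @param L0 Birth (creation) length, nm.
#' @param Td Doubling time, minutes.
#' @param tau Age since creation, minutes.
#' @param dt Step width, minutes (0 allowed, giving 0).
#' @return Length increment, nm.
#' @examples
#' length_increment(1000, 75, 0, 75) # one full doubling adds L0
#' @export
length_increment <- function(L0, Td, tau, dt) {
  if (any(L0 <= 0)) stop("L0 must be > 0", call. = FALSE)
  if (any(Td <= 0)) stop("Td must be > 0", call. = FALSE)
  if (any(dt < 0)) stop("dt must be >= 0", call. = FALSE)
  if (any(tau < 0)) stop("tau must be >= 0", call. = FALSE)
  L0 * (2^((tau + dt) / Td) - 2^(tau / Td))
}

#' Replication timer for a newly created chromosome
#'
#' Each new chromosome is assigned the time its compartment needs to grow
#' from its starting length `L_start` to its segregation length `L_end`
#' under exponential growth: `T_seg = Td * log2(L_end / L_start)`. With the
#' convention `L_end = 2 * L_start` this is one full doubling time; for
#' randomly aged cells at initialization it is the remaining fraction.
#'
#' @param L_start Compartment length at chromosome creation, nm.
#' @param L_end Compartment length at which the chromosome is ready to
#'   segregate, nm (`>= L_start`).
#' @param Td Doubling time, minutes.
#' @return Time until the chromosome is ready to segregate, minutes.
#' @examples
#' replication_time(1000, 2000, 75) # doubling takes one doubling time
#' @export
replication_time <- function(L_start, L_end, Td) {
  if (any(L_start <= 0)) stop("L_start must be > 0", call. = FALSE)
  if (any(Td <= 0)) stop("Td must be > 0", call. = FALSE)
  if (any(L_end < L_start)) stop("L_end must be >= L_start", call. = FALSE)
  Td * log2(L_end / L_start)
}

#' Draw per-compartment doubling times
#'
#' Doubling times are normal with the measured culture parameters
#' (default 75 +/- 15 min), truncated to strictly positive values by
#' resampling (the truncation probability at the defaults is ~3e-7, so the
#' sample moments are unaffected to well below Monte-Carlo error).
#'
#' @param n Number of draws.
#' @param params A [div_params()] object.
#' @param shared If `TRUE`, return `Td_mean` for every draw (the modified
#'   model variant in which all compartments share one doubling time).
#' @return Numeric vector of doubling times, minutes.
#' @export
assign_doubling_time <- function(n, params = div_params(), shared = FALSE) {
  m <- param(params, "Td_mean")
  if (shared) return(rep(m, n))
  rnorm_pos(n, m, param(params, "Td_sd"))
}

# positive-truncated normal by resampling
rnorm_pos <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  tries <- 0L
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
    tries <- tries + 1L
    if (tries > 10000L) stop("positive truncation failed to converge", call. = FALSE)
  }
  x
}

#' Advance growth and replication timers by one step
#'
#' Every compartment's length follows its own exponential law
#' `L_start * 2^(tau / Td)`; ages advance by `dt` and replication timers
#' `T_seg` are reduced by `dt` (floored at zero). Compartments whose timer
#' reaches zero are replication-complete and will be handled by the
#' segregation stage. Cached per-cell lengths are refreshed.
#'
#' @param state A simulation state (see [init_population()]).
#' @param dt Step width, minutes.
#' @return The updated state.
#' @export
grow_and_tick <- function(state, dt) {
  if (dt < 0) stop("dt must be >= 0", call. = FALSE)
  if (dt == 0) return(state)
  cp <- state$comp
  cp$tau <- cp$tau + dt
  cp$length <- cp$L_start * 2^(cp$tau / cp$Td)
  cp$T_seg <- pmax(cp$T_seg - dt, 0)
  state$comp <- cp
  state$cells$length <- cell_lengths(cp, state$cells$cell_id)
  state
}

# sum of compartment lengths per cell, in the order of cell_ids
cell_lengths <- function(comp, cell_ids) {
  s <- rowsum(comp$length, comp$cell_id, reorder = FALSE)
  s[match(as.character(cell_ids), rownames(s)), 1]
}
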