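# Shared, lazily computed simulation runs so expensive populations are
# simulated once per test session.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

run_m1_wt <- function(seed = 1, n_init = 200) {
  cached(paste0("m1wt", seed, "_", n_init),
         run_simulation(sim_config(1, "WT", t_max = 300, n_init = n_init,
                                   seed = seed)))
}

run_m3_minb <- function(seed = 1, n_init = 100) {
  cached(paste0("m3minb", seed, "_", n_init),
         run_simulation(sim_config(3, "minB", t_max = 400, n_init = n_init,
                                   seed = seed)))
}

final_snap <- function(run) {
  dplyr::filter(run$snapshots, t_min == max(t_min))
}

# a tiny hand-built state: one cell, two compartments, one non-polar site
toy_state <- function(L1 = 1000, L2 = 1500, Td = 75, strain = "WT",
                      model = 1, t_w = 10) {
  cfg <- sim_config(model, strain, t_max = 10, n_init = 1, seed = 1)
  cells <- data.frame(cell_id = 1L, parent_id = NA_integer_,
                      L0 = L1 + L2, born_at = 0, length = L1 + L2)
  comp <- data.frame(cell_id = 1L, pos = 1:2, L_start = c(L1, L2),
                     Td = Td, tau = 0, T_seg = Td, length = c(L1, L2))
  sites <- data.frame(cell_id = 1L, kind = "nonpolar", boundary = 1L,
                      blocked = FALSE, t_w = t_w, s = 0, appeared_at = 0)
  sim_state(cells, comp, sites, t = 0, config = cfg)
}
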