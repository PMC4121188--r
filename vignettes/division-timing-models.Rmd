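---
title: "Models of division timing in E. coli with and without the Min system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of division timing in E. coli with and without the Min system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mindivsim)
```

## The biological picture

The Min proteins of *E. coli* oscillate pole-to-pole and suppress
assembly of the FtsZ ring near the poles, so wild-type cells divide at
mid-cell with fairly regular timing. Cells lacking the *minB* operon
divide at their poles as well (producing chromosome-free minicells),
grow filamentous, segregate their chromosomes inefficiently, and show
division *waiting times* — the interval between appearance of a division
site and the division event there — that are much longer and broader than
wild type. `mindivsim` implements four nested stochastic models of this
phenomenology as one configurable population simulator, plus the
statistics used to compare them with single-cell tracking data.

## Core model and assumptions

1. **Exponential single-cell growth.** A compartment created at length
   `L_start` has length `L_start * 2^(tau/Td)` at age `tau`; `Td` is
   drawn per compartment from `N(75, 15^2)` min upon initiation of a new
   replication round. Growth is deterministic given `Td`; all
   stochasticity in size comes from `Td`, placement noise and division
   timing. A culture of such cells grows bulk-exponentially with a
   fitted doubling time close to 75 min (slightly below, because
   fast-growing compartments are over-represented in total length — the
   Malthusian parameter of a Bellman–Harris process with normal lifetime
   is biased below the mean lifetime by the lifetime variance).

2. **Compartments.** A multi-chromosome cell is partitioned into
   compartments, one chromosome *cluster* each; cell length is the sum of
   compartment lengths, and each compartment grows independently.

3. **Replication timer.** Each new chromosome gets
   `T_seg = Td * log2(L_end/L_start)` with `L_end = 2*L_start`
   (replication finishes exactly when the compartment has doubled, so
   growth and replication stay in register). At initialization cells are
   seeded mid-cycle, so `T_seg` is the remaining fraction.

4. **Segregation and placement noise.** An expired timer splits the
   compartment at its midpoint plus `delta ~ N(0, delta_sd)`, redrawn
   until the daughter is within 10% of half the parent. The new boundary
   is a potential division site.

5. **Waiting times and progression.** Active sites carry an assigned
   waiting time `t_w` and a progression variable `s` advancing by `f*dt`
   per step; division fires at `s >= t_w`. Models 1–3 use `f = 1`
   (pure countdown); model 4 uses machinery competition (below).

6. **Blocking (minB- segregation defect, models 2–4).** When a new
   potential site appears in a cell, fresh uniform marks are assigned to
   all currently blocked sites plus the new one, and marks above
   `p_th = max(0, 1 - target/n_randomized)` are blocked. The linear
   expectation rule makes the expected post-lottery blocked count
   `min(target, n_randomized)`; with the default target 2 the long-run
   time average measured by `blocked_sites_summary()` settles at ~1.95.
   A blocked boundary keeps its flanking chromosomes as one unsplit
   compartment (one visible cluster) that keeps growing and replicating;
   it becomes eligible again at the cell's next lottery.

7. **Division execution.** Non-polar division splits the cell at the
   site's boundary; carried-over sites keep `t_w` and `s`; the septum
   becomes each daughter's new pole. Polar division emits a minicell:
   the count increments, the cell is otherwise unchanged, and the pole
   re-arms with a fresh `t_w` while keeping its *formation* time — the
   measured polar waiting time is formation-to-division, exactly as the
   microscopy measurement defines it.

## The four variants

* **Model 1** assigns measured waiting-time normals per site class
  (polar vs non-polar) and has no segregation defect. It reproduces bulk
  growth but — as the original analysis found — makes too many minicells
  and too few filamentous cells.
* **Model 2** adds blocking. It fixes the length distribution but still
  fails the polar waiting-time distribution: blocked poles make polar
  waits *longer than the distribution it was given*.
* **Model 3** draws *all* waiting times from the non-polar distribution.
  Polar and non-polar sites are a priori equivalent; the longer polar
  waits emerge from the dynamics. This is asserted in the test suite as
  a directional property (emergent polar mean > assigned non-polar mean).
* **Model 4** derives waiting times mechanistically: all sites draw from
  the *wild-type* distribution `N(17.7, 11.9^2)` min, but progression is
  scaled by competition for division machinery,
  `f = ftsz_factor * c * L / (n * Lc)` (minB-) or `f = c * (L/2) / (n * Lc)`
  (WT, machinery confined to half the cell by the Min oscillations), with
  `n` the number of active sites (poles count only in minB-). Doubling
  FtsZ (`ftsz_factor = 2`, blocking target lowered to 1) moves the minB-
  length distribution toward wild type, which the tests assert as a
  Kolmogorov–Smirnov distance inequality.

## Parameters, units, defaults

All times are minutes, all lengths nanometres.

| parameter | default | origin |
|---|---|---|
| `Td_mean`, `Td_sd` | 75, 15 | measured doubling-time normal |
| `w_wt_mean`, `w_wt_sd` | 17.7, 11.9 | measured WT waiting-time normal |
| `w_nonpolar_*` | 35, 25 | stand-in (see below) |
| `w_polar_*` | 65, 45 | stand-in (see below) |
| `L0_mean`, `L0_sd` | 2500, 250 | stand-in newborn length |
| `Lc` | 2500 | stand-in chromosome size |
| `delta_sd` | 100 | stand-in placement noise |
| `n_block_target` | 2 | cluster-offset measurement |
| `c_rate` | 2 | calibration: WT reference geometry has f = 1 |
| `dt` | 1 | resolves the 17.7-min waiting scale with < 6% discretization |
| `n_init` | 1000 | the standard population size for steady-state runs |

The minB- per-class waiting normals and the length scales are only
available in supplementary material we do not ship; they are
configuration inputs with defaults chosen once to be biologically
plausible (minB- waits longer and broader than WT, polar longer than
non-polar; a ~2.5 µm newborn cell for a slow-growth medium) and are
never tuned against test outcomes. Every quantity the acceptance
criteria check depends only on the measured values above.

## Numerical and design choices

* **Waiting-time draws are not truncated.** Resampling `N(17.7, 11.9^2)`
  to positive values would shift the sample mean to 19.4 and shrink the
  SD to 10.4 (closed-form truncated-normal moments), contradicting the
  measured moments the model is built on. Instead a non-positive
  assigned `t_w` (probability ~6.9% for WT) completes at the site's
  first progression step — division "immediately upon appearance",
  which is also how marginal events look in the experiment. Doubling
  times and lengths *are* resample-truncated; at their defaults the
  truncation probability (< 3e-7) is irrelevant.
* **Polar sites join the blocking lottery.** The defect analysis of
  model 2 requires polar division sites to be blockable; a newly formed
  septum pole enters the same lottery as a new chromosome boundary. A
  blocked pole carries no waiting time until a later lottery releases
  it; its measured waiting time still runs from formation.
* **Merged-cluster bookkeeping.** Multiply-blocked compartments are
  handled as clusters that segregate as two halves per completed
  replication round; several simultaneous unblocks split a compartment
  by successive binary midpoint splits (largest piece first). This keeps
  exact length conservation and the per-cell blocked count — the
  quantities the observables use — while avoiding explicit intra-cluster
  coordinates, which the models deliberately do not track.
* **Update order and batching.** Steps apply grow → segregate → progress
  → divide, in that fixed order; all lottery events of a cell within one
  step form a single lottery; at most one non-polar division per cell
  executes per step (error bounded by `dt`). Cells are processed in id
  order, making runs bit-reproducible for a given seed and
  configuration (asserted byte-for-byte in the tests).
* **Completion uses `s >= t_w` at step boundaries** with no sub-step
  interpolation: timing errors are at most `dt` (default 1 min) against
  the 17.7-min waiting scale.
* **Initialization.** Populations start with chromosome number uniform
  on {1, 2, 3} per cell, newborn lengths from the `L0` normal, uniformly
  random cell-cycle age. Transient population composition depends on
  these choices; steady-state distributions do not (tested by comparing
  100- vs 1000-cell runs via a KS distance).
* **Carried-over sites are not re-drawn** at division; nothing in the
  biology suggests a septum resets unrelated sites' maturation.

## The synthetic tracking generator

`generate_tracking()` emulates microscopy-derived lineage tables without
running the simulator: founder cells (spread over the first 30 min) grow
exponentially, optionally bud off minicells at each pole (probability
`p_polar` per pole), then divide non-polar after one doubling plus a
class-specific waiting draw; daughters recurse for `n_generations`.
Observed cluster counts are `round(N_exp - target + noise)`, and events
dividing after the observation window (default 213 min, the experimental
limit) are right-censored — dropped and counted — so estimator bias from
finite observation is reproducible. What a green round-trip test
establishes: the observables recover the generating parameters within
Monte-Carlo error *under this idealized structure*. What it does not:
segmentation/tracking errors, non-exponential growth, cell crowding,
or correlated waiting times, none of which the generator emulates.

## Known limitations

* No explicit replication forks or overlapping rounds (slow-growth
  medium assumption); no sub-cell chromosome coordinates; no molecular
  Min or FtsZ dynamics — blocking and competition are effective
  descriptions.
* Minicells are counted, not sized or tracked.
* The multiway split rule and the pole lottery at division are modelling
  choices on points the effective description leaves open; both conserve
  the quantities the statistics depend on.
* Model-4 minB- populations produce minicells at a high rate because
  re-armed poles compete with rate `f > 1` in long cells; only
  length-distribution and waiting-time observables are used for
  comparisons, not absolute minicell rates.
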