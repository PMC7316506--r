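---
title: "Costly DNA uptake and slightly beneficial genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costly DNA uptake and slightly beneficial genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtgenes)
```

# The scientific problem

Bacteria gain and lose genes quickly. A gene with a small growth benefit
`b` that is lost at rate `l` cannot be held by selection alone once
`b < l`: the lineage loses it faster than selection can enrich it.
Transformation — taking up DNA from the environment — can return lost genes
to non-carrier cells, but running the uptake machinery is itself costly,
and the same route lets selfish genetic elements (SGEs) in. This package
implements a stack of three models of that trade-off, from closed-form
theory to a stochastic spatial simulation, together with the measurement
layer and protocol drivers needed to reproduce the whole analysis.

# The well-mixed chemostat model

Carriers `C` and non-carriers `N` compete in a chemostat (`C + N = 1` at
steady state). Carriers grow at `1 + b - c h`, non-carriers at `1 - c h`,
carriers lose the gene at rate `l`, and mass-action uptake converts
non-carriers back at rate `h C N`. The cost `c h` is paid continuously by
everyone, carrier or not, reflecting the price of expressing and running
uptake machinery whether or not anything useful is acquired.

Everything about this model is closed-form:

* carrier frequency `C* = 1 - l / (b + h)` when `h > l - b`, else 0
  (`carrier_frequency()`);
* steady-state growth `phi*(h) = 1 - c h` below the persistence threshold
  and `1 - c h + b - b l / (b + h)` above it (`phi_star()`); the two
  branches meet continuously at `h = l - b`;
* the uptake rate maximising the persisting branch,
  `h_opt = sqrt(b l / c) - b`, clamped at zero (`optimal_uptake()`).

```{r ode}
p <- gene_params(b = 0.025, l = 0.02, c = 0.2)
carrier_frequency(p, h = 0)
optimal_uptake(p)
phi_star(p, h = optimal_uptake(p))
```

Note on `h_opt`: for genes that are lost without uptake (`b <= l`) the
no-uptake population sits at growth rate 1, which can exceed the peak of
the persisting branch. `optimal_uptake()` deliberately returns the peak of
the persisting branch (the rate a transferring population would settle
on), not the global argmax; the classifier compares the two branches
explicitly.

## Gene classes

Two questions partition the benefit axis for fixed `l` and `c < 1`:
does the gene persist without uptake (`b > l`)? and can some uptake rate
raise steady-state growth above its no-uptake value? Working out where
`phi*(h_opt) = 1` gives the closed-form boundary `b = 4 c l / (1 + c)^2`,
and the five classes follow:

| class | range | persists alone | uptake helps |
|---|---|---|---|
| indispensable | `b >= l/c` | yes | never |
| enrichable | `l < b < l/c` | yes | yes |
| rescuable | `4cl/(1+c)^2 < b <= l` | no | yes |
| unrescuable | `0 < b <= 4cl/(1+c)^2` | no | no |
| SGE | `b <= 0` | no | never |

Boundary values are assigned to the weaker-gene side, except `b = l/c`
where `h_opt` is exactly zero and the gene is indispensable. The test
suite checks this table against an independent oracle (persistence by
numerical integration, benefit by grid maximisation) on 200 random
parameter draws.

# Invasion analysis

To ask whether uptake is an evolutionarily stable and/or attainable
strategy, a four-type model tracks a transferring and a non-transferring
strain, each with carriers and non-carriers. The crucial coupling is the
donor pool: a transferring cell can pick up the gene from *any* carrier,
its own strain or the competitor's.

`invasion_fitness(params, h_res, h_inv)` linearises the rare invader's
2-by-2 subsystem around the resident equilibrium, holding the chemostat
dilution at the resident value (the invader is measure-zero; this is
standard adaptive-dynamics practice). Its sign decides invasion from
rare; `founder_basin_scan()` integrates the full nonlinear system for
finite founders.

Two results organise the biology:

* **ESS**: a non-transferring mutant cannot invade a population
  transferring at `h_opt`, for every rescuable and enrichable gene.
* **Evolvability**: the transferring mutant invades a non-transferring
  resident only for enrichable genes. For rescuable genes the resident
  holds no carriers, so the mutant pays the cost with no donors to learn
  from — invasion fails from rare and succeeds only above a founder
  threshold (an Allee effect). The evolvable range is in fact a strict
  sub-interval of the enrichable class: just above `b = l` the resident's
  carrier frequency `1 - l/b` is still nearly zero, and even the
  optimal-uptake mutant lacks donors. The package tests assert
  containment and contiguity of the evolvable set rather than equality
  with the enrichable interval.

The nonlinear success criterion used in basin scans is deliberately
seed-free and unambiguous: the transferring strain's share must exceed
0.5 at `t = 1e5` and not be declining over the last decade of time.

# The spatial individual-based model

Every site of an `n x n` torus holds exactly one cell with a gene flag
(plus barcode), an SGE flag (plus barcode) and its own uptake rate
`h_ij`. Per-cell growth is `phi = max(0, 1 + b - beta - c h)`. One time
step applies, in fixed order: reproduction, gene loss, SGE loss, uptake,
influx, mutation of `h`, mixing. The order is fixed for reproducibility;
order effects are second-order in the per-step probabilities.

Rate-like processes (reproduction, loss, uptake) happen with probability
rate times `dt = 0.1` per step, so that the lattice reproduces the
chemostat rates. Influx and mutation are per-step probabilities used as
given — they have no counterpart in the chemostat model.

Key design choices, and why:

* **Competition excludes self.** The competitor that may reproduce into a
  focal site is drawn uniformly from the other `s^2 - 1 = 8` cells of the
  Moore block, and replaces the focal cell with probability
  `phi * dt`. Including the focal cell in its own candidate pool damps
  selection by exactly `(s^2-1)/s^2`, and the well-mixed lattice then
  equilibrates at `1 - l/(8b/9 + h)` instead of the mass-action
  `1 - l/(b + h)`; with self excluded the correspondence is exact, which
  the suite verifies against the closed form within binomial error.
* **Well-mixed mode samples partners globally.** Instead of physically
  permuting all positions every step, reproduction competitors and uptake
  donors are drawn uniformly from the whole grid. For single-draw
  interactions this is the same process in distribution, and much
  cheaper. The full-permutation operation is still exposed (`well_mix()`)
  and tested for multiset conservation and positional uniformity.
* **Synchronous sweeps.** Reproduction and uptake decisions are taken
  against the pre-sweep state and applied atomically, so raster order
  cannot leak into the dynamics.
* **Uptake is recipient-controlled.** Each cell runs at most one uptake
  trial per step (probability `h_ij * dt`), sampling one donor from its
  `t x t` neighbourhood (excluding itself); gene and SGE transfer
  independently from whatever that donor carries. SGEs are lost at the
  same rate `l` as genes, which is what makes the persistence condition
  `h > l - b` apply to them too.
* **Mutation truncates at zero.** A mutating cell redraws
  `h ~ Uniform(h - m, h + m)` clamped below at 0; no reflection, the
  simplest non-negative scheme.
* **Margolus mixing.** `d` applications per step of the block-rotation
  algorithm: 2-by-2 blocks at alternating offsets, each rotated a quarter
  turn clockwise or counter-clockwise with probability 1/2. It is a pure
  permutation, so the cell multiset is conserved exactly.
* **Boundaries are toroidal**, the standard choice for this model family.

## Ambiguous printed parameters and how they were resolved

The source descriptions of three stochastic parameters are internally
contradictory, and each was resolved to the reading under which the
corresponding headline experiment behaves as described; all three
decisions were made once and are fixed package-wide.

* **Mutation probability `u`**: printed in two places that disagree by two
  orders of magnitude. Taken as `5e-5` per cell per step, unscaled. If it
  is additionally `dt`-scaled, uptake never evolves de novo at desk scale
  (no mutational supply); if taken at the larger printed value, mutation
  pressure alone pushes over a third of cells past the HGT+ threshold
  before any gene exists, and uptake "evolves" even in mass action —
  contradicting the model's own invasion analysis.
* **Gene influx `f`**: taken as a `dt`-scaled rate (`5e-6`, so `5e-7` per
  cell per step). At ten times that supply the standing pool of
  influx-born carriers bridges the Allee threshold even in well-mixed
  populations, erasing the spatial/well-mixed contrast that is the
  central result.
* **SGE influx**: two inconsistent values are printed; taken as an
  effective `1e-5` per cell per step. At a tenth of that, strong SGEs are
  purged at desk scale rather than coexisting, and the weak-SGE uptake
  response undershoots.
* **Uptake range `t`**: unstated for the main experiments, but strong
  SGEs are reported to die out when transfer is strictly
  nearest-neighbour while the main strong-SGE experiment shows
  coexistence — so the range must exceed the 3x3 block. The protocol
  drivers use `t = 5`, the smallest such; `ibm_config()` keeps `t = 3`
  as the generic default.

## Observables

* `phi_pop`: mean of per-cell growth rates — the lattice analogue of the
  chemostat growth rate.
* `sigma_c`: for each carrier, its growth-rate excess over the mean of
  its eight Moore neighbours, averaged over carriers. It is `b` for a
  lone carrier among equal-uptake non-carriers and falls to 0 as carriers
  saturate — the effective local benefit of the gene, and the quantity
  that explains why clumped populations hold genes so poorly.
* `phi_lod`: the line-of-descent growth rate. Each reproduction event
  records the mother's growth rate and a parent pointer; `phi_lod`
  averages, over all extant cells, the recorded rates along each cell's
  own ancestry up to 250 generations back. The lineage store is pruned
  to the reachable window as it grows; pruning is exact (verified
  against an unpruned reference).
* Barcodes: every influxed gene or SGE gets a unique id inherited through
  reproduction and transfer, so one can ask whether persistence reflects
  one long-lived lineage or continuous rediscovery.

# Desk-scale protocols and what they do and do not show

The protocol drivers run at `n = 100` with the influx window at steps
20,000–100,000 plus a 50,000-step closed phase (de novo evolution), and
20,000 equilibration + 50,000 influx steps (SGE challenge). These sizes
keep a full protocol under a minute of compute while preserving the
qualitative regimes; they are quarter-linear-scale versions of the
original experiments.

Three finite-size effects matter when interpreting results at this scale,
and all three are deliberate limitations rather than bugs:

* **Spatial nucleation is stochastic.** The de novo emergence of a
  gene-sharing community is a rare local nucleation event; at `n = 100`
  it occurs in roughly half of the seeds within the influx window
  (measured across batches). The per-run nucleation probability scales
  with grid area times window length, so larger grids establish almost
  surely — at this scale, expect seed-to-seed variation.
* **The well-mixed control can nucleate by fluctuation.** In mass action
  the Allee threshold is deterministic and uptake for a rescuable gene
  should never evolve; at `10^4` cells, demographic fluctuations around
  the influx-sustained carrier pool (about 2% standing carriers) cross
  it in roughly a fifth to a quarter of seeds anyway. This is a property
  of small well-mixed populations, not of the model's mass-action
  limit — the acceptance checks assert the deterministic contrast and
  are expected to miss in such seed batches.
* **Rare coexistence states are fragile.** Strong SGEs persist at a few
  percent frequency; once their influx stops, a few hundred clustered
  infected cells go extinct readily at `n = 100`, whereas large grids
  hold refugia. Tests therefore assert the low-versus-high frequency
  contrast between strong and weak SGEs during the influx phase rather
  than closed-phase coexistence.

Similarly, the evolved uptake rate in established gene-sharing
communities sits near — typically slightly above — the chemostat optimum
`h_opt = sqrt(b l / c) - b` (about 0.047 for `b = 0.03`, `c = 0.1`,
`l = 0.02`): the selection gradient is flat near the peak, so
mutation–drift pressure at desk-scale population sizes inflates the mean
somewhat.

# Numerical choices

* ODE integration uses `deSolve::lsoda` with relative tolerance `1e-8`;
  a steady state is declared when the largest derivative magnitude falls
  below `1e-10`. Solver states are clamped at zero before evaluating the
  right-hand side (the solver may step infinitesimally negative).
* Invasion fitness is the dominant eigenvalue of the 2-by-2 invader
  Jacobian, computed exactly.
* The IBM uses a dedicated xoshiro256++ generator seeded from the run
  seed, so runs are bit-reproducible across platforms and independent of
  R's global RNG state. Sparse Bernoulli sweeps (loss, influx, mutation)
  use geometric skipping, which is exactly equivalent to per-site trials.
* Statistical tests compare Monte Carlo means against exact enumerated
  expectations within four standard errors.

```{r classes, fig.width = 6, fig.height = 3, eval = FALSE}
# carrier-frequency surface and class boundaries, as CSV-ready data
surface <- scan_surface(b_grid = seq(-0.02, 0.12, by = 0.002),
                        h_grid = seq(0, 0.2, by = 0.005),
                        l = 0.02, c = 0.2)
head(surface)
```

# Known limitations

* One focal gene and one SGE kind at a time; no multi-gene genomes, no
  differential gene mobility.
* Donor-controlled transfer and success-only cost variants are not
  implemented (the uptake model here is recipient-controlled
  transformation with continuous cost).
* The environment is constant: benefits never fluctuate, so nothing here
  speaks to genes that are only intermittently useful.
* Well-mixed mode is exact for interactions but does not simulate
  physical cell movement; spatial observables (snapshots, barcode maps)
  are only meaningful in the spatial mode.
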