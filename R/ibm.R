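#' Threshold above which an individual counts as a transferring (HGT+) cell
#' @export
HGT_PLUS_THRESHOLD <- 0.02

#' Configuration of the spatial individual-based model
#'
#' Collects every parameter of the lattice model. The processes that mirror
#' the chemostat model's rates — reproduction, gene/SGE loss and uptake —
#' occur each step with probability rate times the scaling constant `dt`
#' (default 0.1), which keeps them faithful to the continuous-time rates.
#' Gene and SGE influx are rates on the same footing and are `dt`-scaled
#' too. The mutation probability `u` has no rate counterpart and is a plain
#' per-cell per-step probability, used as given.
#'
#' @param n Grid side; the population is the full `n x n` torus and every
#'   site is always occupied. Must be even (Margolus mixing works on 2x2
#'   blocks).
#' @param b Growth-rate benefit carried by the (influxed) gene.
#' @param l Gene-loss rate; selfish elements are lost at the same rate.
#' @param c Cost coefficient of uptake: a cell with uptake rate `h` pays
#'   `c * h` growth rate.
#' @param beta Fitness penalty of the selfish genetic element.
#' @param h_init Initial uptake rate given to every cell by [ibm_grid()].
#' @param d Number of Margolus-diffusion applications per step (`0` = rigid
#'   biofilm-like population).
#' @param well_mixed If `TRUE`, reproduction competitors and uptake donors
#'   are sampled uniformly from the whole grid, the mass-action limit;
#'   equivalent in distribution to randomly re-assigning every cell's
#'   position each step.
#' @param s Competition range: the competitor that may reproduce into a
#'   focal site is drawn uniformly from the other `s^2 - 1` cells of the
#'   `s x s` block centred on it (default 3: the eight Moore neighbours).
#' @param t Uptake range: donors are sampled uniformly from the `t x t`
#'   block around the recipient, excluding the recipient itself.
#' @param u Mutation probability of the individual uptake rate, per cell per
#'   step (not `dt`-scaled).
#' @param m Mutation step: a mutating cell redraws `h` uniformly in
#'   `[h - m, h + m]`, truncated below at 0.
#' @param f Gene influx (discovery) rate, active during
#'   `[f_start, f_stop)`.
#' @param f_start,f_stop Step window of gene influx.
#' @param sge_influx SGE influx rate, active during `[i_start, i_stop)`.
#' @param i_start,i_stop Step window of SGE influx.
#' @param dt Probability scaling constant applied to the rate-like processes
#'   (default 0.1).
#' @param hgt_plus Reporting threshold on `h` above which a cell is counted
#'   as HGT+ (default [HGT_PLUS_THRESHOLD]).
#' @param seed Default RNG seed for [ibm_run()].
#' @return An object of class `ibm_config`.
#' @export
ibm_config <- function(n = 100, b = 0.03, l = 0.02, c = 0.2, beta = 0,
                       h_init = 0, d = 0, well_mixed = FALSE, s = 3, t = 3,
                       u = 0, m = 0.05, f = 0, f_start = 0, f_stop = 0,
                       sge_influx = 0, i_start = 0, i_stop = 0, dt = 0.1,
                       hgt_plus = HGT_PLUS_THRESHOLD, seed = 1L) {
  stopifnot(n >= 4, n %% 2 == 0, s >= 1, s %% 2 == 1, t >= 3, t %% 2 == 1,
            d >= 0, l >= 0, c >= 0, u >= 0, m >= 0, f >= 0, sge_influx >= 0,
            beta >= 0, dt > 0, h_init >= 0)
  if (f > 0 && f_stop <= f_start)
    stop("gene influx window must satisfy f_start < f_stop", call. = FALSE)
  if (sge_influx > 0 && i_stop <= i_start)
    stop("SGE influx window must satisfy i_start < i_stop", call. = FALSE)
  if ((1 + max(b, 0)) * dt > 1)
    stop("reproduction probability (1 + b) * dt exceeds 1", call. = FALSE)
  for (rate in c(l, f, sge_influx)) if (rate * dt > 1)
    stop("a rate times dt exceeds 1; decrease dt", call. = FALSE)
  if (u > 1)
    stop("u is a per-step probability and must be <= 1", call. = FALSE)
  structure(list(n = as.integer(n), b = as.numeric(b), l = as.numeric(l),
                 c = as.numeric(c), beta = as.numeric(beta),
                 h_init = as.numeric(h_init), d = as.integer(d),
                 well_mixed = isTRUE(well_mixed),
                 s = as.integer(s), t = as.integer(t), u = as.numeric(u),
                 m = as.numeric(m), f = as.numeric(f),
                 f_start = as.integer(f_start),
                 f_stop = as.integer(f_stop),
                 sge_influx = as.numeric(sge_influx),
                 i_start = as.integer(i_start), i_stop = as.integer(i_stop),
                 dt = as.numeric(dt), hgt_plus = as.numeric(hgt_plus),
                 seed = as.integer(seed)),
            class = "ibm_config")
}

#' @export
print.ibm_config <- function(x, ...) {
  cat(sprintf("ibm_config: %d x %d torus, b = %g, l = %g, c = %g, dt = %g\n",
              x$n, x$n, x$b, x$l, x$c, x$dt))
  cat(sprintf("  mixing: %s | uptake: h_init = %g, u = %g, m = %g\n",
              if (x$well_mixed) "well-mixed" else sprintf("Margolus d = %d", x$d),
              x$h_init, x$u, x$m))
  if (x$f > 0)
    cat(sprintf("  gene influx f = %g during [%d, %d)\n", x$f, x$f_start, x$f_stop))
  if (x$sge_influx > 0)
    cat(sprintf("  SGE influx %g (beta = %g) during [%d, %d)\n",
                x$sge_influx, x$beta, x$i_start, x$i_stop))
  invisible(x)
}

#' Read and write lattice configurations as JSON
#'
#' The JSON keys mirror the [ibm_config()] argument names exactly, so a
#' config file is also a complete record of a run's parameters. Unknown
#' keys are rejected; `overrides` (e.g. from command-line flags) replace
#' file values before validation.
#'
#' @param path File path.
#' @param overrides Named list of fields replacing the file's values.
#' @return `read_ibm_config()` returns an [ibm_config()];
#'   `write_ibm_config()` invisibly returns `path`.
#' @export
read_ibm_config <- function(path, overrides = list()) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals[names(overrides)] <- overrides
  known <- names(formals(ibm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(ibm_config, vals)
}

#' @param config An [ibm_config()] to serialise.
#' @rdname read_ibm_config
#' @export
write_ibm_config <- function(config, path) {
  stopifnot(inherits(config, "ibm_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Build an initial lattice of cells
#'
#' @param config An [ibm_config()].
#' @param carrier Initial carriers: `FALSE` (none), `TRUE` (all), or a
#'   fraction in `(0, 1)` placed uniformly at random (uses `config$seed`).
#' @param infected Same convention for SGE infection.
#' @param h Initial uptake rate (default `config$h_init`).
#' @return A grid: a list of `n x n` matrices `gene`, `gene_barcode`,
#'   `sge`, `sge_barcode`, `h`, with attribute `registry` holding the next
#'   free barcode ids. Initial carriers (infecteds) share founding barcode 1.
#' @export
ibm_grid <- function(config, carrier = FALSE, infected = FALSE,
                     h = config$h_init) {
  n <- config$n
  place <- function(frac) {
    m <- matrix(0L, n, n)
    if (isTRUE(frac)) m[] <- 1L
    else if (is.numeric(frac) && frac > 0) {
      k <- round(frac * n * n)
      m[sample.int(n * n, k)] <- 1L
    }
    m
  }
  if (is.numeric(carrier) || is.numeric(infected)) set.seed(config$seed)
  gene <- place(carrier)
  sge <- place(infected)
  grid <- list(gene = gene,
               gene_barcode = gene * 1L,
               sge = sge,
               sge_barcode = sge * 1L,
               h = matrix(as.numeric(h), n, n))
  attr(grid, "registry") <- list(gene_next = if (any(gene > 0)) 2L else 1L,
                                 sge_next = if (any(sge > 0)) 2L else 1L)
  class(grid) <- "ibm_grid"
  grid
}

cfg_for_cpp <- function(config) {
  config[c("n", "s", "t", "d", "well_mixed", "l", "c", "u", "m", "f", "b",
           "sge_influx", "beta", "dt", "hgt_plus",
           "f_start", "f_stop", "i_start", "i_stop")]
}

registry_of <- function(grid, registry = NULL) {
  if (!is.null(registry)) return(registry)
  reg <- attr(grid, "registry")
  if (is.null(reg)) reg <- list(gene_next = max(grid$gene_barcode) + 1L,
                                sge_next = max(grid$sge_barcode) + 1L)
  reg
}

#' Run the individual-based model
#'
#' Advances the lattice `steps` time steps. Each step applies, in fixed
#' order: reproduction, gene loss, SGE loss, uptake, influx, mutation and
#' mixing. The run is fully reproducible from `seed`.
#'
#' @param config An [ibm_config()].
#' @param steps Number of time steps.
#' @param init Initial grid (default: [ibm_grid()] of all non-carriers).
#' @param report_every Observable reporting cadence in steps.
#' @param snapshot_steps Integer vector of absolute step numbers at which to
#'   keep a copy of the whole grid.
#' @param track_lineage If `TRUE`, record the ancestry of every birth event
#'   so that the line-of-descent growth rate `phi_lod` (mean ancestral
#'   growth rate over a 250-generation window) can be reported.
#' @param seed RNG seed (default `config$seed`).
#' @param step_offset Absolute step number of the initial state, for
#'   continued (checkpointed) runs.
#' @param registry Barcode registry carried over from a previous segment.
#' @param phase Margolus phase carried over from a previous segment.
#' @param prune_limit Lineage-store size above which ancestry older than the
#'   250-generation window is discarded.
#' @param return_lineage If `TRUE` (and tracking), attach the raw lineage
#'   table to the result.
#' @return An object of class `ibm_run`: list with `ts` (data frame of
#'   observables), `grid` (final state), `registry`, `snapshots`, `config`,
#'   `seed`, `phase`, and optionally `lineage`.
#' @export
ibm_run <- function(config, steps, init = NULL, report_every = 100,
                    snapshot_steps = integer(), track_lineage = FALSE,
                    seed = config$seed, step_offset = 0, registry = NULL,
                    phase = 0, prune_limit = 4e6, return_lineage = FALSE) {
  stopifnot(inherits(config, "ibm_config"), steps >= 1)
  if (is.null(init)) init <- ibm_grid(config)
  reg <- registry_of(init, registry)
  res <- cpp_ibm_run(unclass(init), cfg_for_cpp(config), as.integer(steps),
                     as.integer(step_offset), as.integer(report_every),
                     as.integer(snapshot_steps), isTRUE(track_lineage),
                     as.numeric(seed), reg$gene_next, reg$sge_next,
                     as.integer(phase), prune_limit, isTRUE(return_lineage))
  ts <- as.data.frame(res$ts)
  names(ts) <- as.character(res$ts_names)
  grid <- res$grid
  attr(grid, "registry") <- list(gene_next = res$gene_next,
                                 sge_next = res$sge_next)
  class(grid) <- "ibm_grid"
  snaps <- res$snapshots
  names(snaps) <- as.character(res$snapshot_steps)
  out <- list(ts = ts, grid = grid,
              registry = list(gene_next = res$gene_next,
                              sge_next = res$sge_next,
                              gene_born = res$gene_born,
                              sge_born = res$sge_born),
              snapshots = snaps, config = config, seed = seed,
              steps = steps, step_offset = step_offset, phase = res$phase)
  if (!is.null(res$lineage)) out$lineage <- res$lineage
  class(out) <- "ibm_run"
  out
}

#' @export
print.ibm_run <- function(x, ...) {
  last <- x$ts[nrow(x$ts), ]
  cat(sprintf("ibm_run: %d steps on %d x %d grid (seed %s)\n",
              x$steps, x$config$n, x$config$n, format(x$seed)))
  cat(sprintf("  final: carriers %.3f, SGE %.3f, mean h %.4f, phi_pop %.4f\n",
              last$carrier_freq, last$sge_freq, last$mean_h, last$phi_pop))
  invisible(x)
}

#' Apply one sweep of the update rule to a grid
#'
#' Low-level access to the individual update processes, mainly for
#' verifying their statistical behaviour in isolation.
#'
#' @inheritParams ibm_run
#' @param grid An `ibm_grid`.
#' @param sweep One of `"reproduction"`, `"gene_loss"`, `"sge_loss"`,
#'   `"hgt"`, `"influx"`, `"mutation"`, `"margolus"` (applies `config$d`
#'   rotations), `"well_mix"`, or `"step"` (the full composite).
#' @param step_idx Absolute step index (used by influx windows).
#' @return The updated grid (with updated registry attribute).
#' @export
ibm_sweep <- function(grid, config, sweep, seed = config$seed, step_idx = 0,
                      phase = 0) {
  reg <- registry_of(grid)
  res <- cpp_ibm_sweep(unclass(grid), cfg_for_cpp(config), sweep,
                       as.numeric(seed), as.integer(step_idx),
                       as.integer(phase), reg$gene_next, reg$sge_next)
  g <- res$grid
  attr(g, "registry") <- list(gene_next = res$gene_next,
                              sge_next = res$sge_next)
  attr(g, "phase") <- res$phase
  class(g) <- "ibm_grid"
  g
}

#' Margolus diffusion mixing
#'
#' Partitions the torus into 2x2 blocks (offset alternating between
#' applications) and rotates each block a quarter turn clockwise or
#' counter-clockwise with probability 1/2. The multiset of cells is exactly
#' preserved.
#'
#' @inheritParams ibm_sweep
#' @param d Number of applications.
#' @return The mixed grid.
#' @export
margolus_mix <- function(grid, d, seed = 1L, phase = 0) {
  n <- nrow(grid$gene)
  if (n %% 2 != 0) stop("Margolus mixing requires an even grid side", call. = FALSE)
  if (d == 0) return(grid)
  cfg <- ibm_config(n = n, d = as.integer(d))
  ibm_sweep(grid, cfg, "margolus", seed = seed, phase = phase)
}

#' Random full permutation of all cell positions
#' @inheritParams margolus_mix
#' @return The permuted grid.
#' @export
well_mix <- function(grid, seed = 1L) {
  cfg <- ibm_config(n = nrow(grid$gene), well_mixed = TRUE)
  ibm_sweep(grid, cfg, "well_mix", seed = seed)
}

#' Per-cell growth rate
#'
#' `phi = max(0, 1 + b * gene - beta * sge - c * h)`: baseline growth 1
#' plus the gene benefit, minus the SGE penalty and the uptake cost.
#'
#' @param grid An `ibm_grid`.
#' @param config The matching [ibm_config()] (supplies `b`, `beta`, `c`).
#' @return An `n x n` numeric matrix of growth rates.
#' @export
growth_rate <- function(grid, config) {
  phi <- 1 + config$b * grid$gene - config$beta * grid$sge -
    config$c * grid$h
  phi[phi < 0] <- 0
  phi
}
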