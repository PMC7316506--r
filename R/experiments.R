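#' De novo evolution of DNA uptake under sporadic gene discovery
#'
#' The lattice starts as all non-carriers with `h = 0`. After `f_start`
#' steps, a slightly beneficial gene starts fluxing in at a very low rate
#' `f` (each influx event gets a fresh barcode); influx stops at `f_stop`
#' and the ecosystem then runs closed for `closed_steps`. Uptake rates
#' evolve by mutation throughout. The protocol reports whether a
#' self-sustaining gene-sharing community established: population-mean
#' uptake above the HGT+ threshold and carriers still present after the
#' influx has stopped.
#'
#' @param b Benefit of the influxed gene.
#' @param n Grid side.
#' @param well_mixed Permute all positions every step instead of spatial
#'   growth.
#' @param d Margolus applications per step when not well-mixed.
#' @param l,c Loss rate and uptake cost.
#' @param u,m Per-step mutation probability and step size of the uptake rate.
#' @param f Gene influx (discovery) rate.
#' @param f_start,f_stop Influx window (steps).
#' @param closed_steps Closed-ecosystem steps appended after `f_stop`.
#' @param summary_window Trailing window (steps) over which final summaries
#'   are averaged.
#' @param seed RNG seed.
#' @param t Uptake neighbourhood side.
#' @param report_every Reporting cadence.
#' @param ... Passed on to [ibm_run()] (e.g. `snapshot_steps`,
#'   `track_lineage`).
#' @return A list with elements `run` (the [ibm_run()] result),
#'   `established` (logical), `carrier_freq_final`, `mean_h_final` (means
#'   over the trailing window) and `config`.
#' @export
protocol_denovo_uptake <- function(b = 0.03, n = 100, well_mixed = FALSE,
                                   d = 0, l = 0.02, c = 0.1, u = 5e-5,
                                   m = 0.05, f = 5e-6, f_start = 20000,
                                   f_stop = 100000, closed_steps = 50000,
                                   summary_window = 10000, seed = 1, t = 5,
                                   report_every = 100, ...) {
  cfg <- ibm_config(n = n, b = b, l = l, c = c, h_init = 0, d = d,
                    well_mixed = well_mixed, t = t, u = u, m = m, f = f,
                    f_start = f_start, f_stop = f_stop, seed = seed)
  steps <- f_stop + closed_steps
  run <- ibm_run(cfg, steps, report_every = report_every, ...)
  ts <- run$ts
  tail_ts <- ts[ts$step > steps - summary_window, ]
  mean_h_final <- mean(tail_ts$mean_h)
  carrier_final <- mean(tail_ts$carrier_freq)
  established <- mean_h_final > cfg$hgt_plus &&
    ts$carrier_freq[nrow(ts)] > 0
  list(run = run, established = established,
       carrier_freq_final = carrier_final, mean_h_final = mean_h_final,
       config = cfg)
}

#' Challenge an evolved gene-sharing population with selfish elements
#'
#' First equilibrates an all-carrier population that already transfers
#' (`h_init`, uptake rate evolving), then opens a window of SGE influx with
#' fitness penalty `beta`, and optionally lets the ecosystem run closed
#' afterwards. Reports the evolved uptake rate during the late influx phase
#' and whether cells, gene and SGEs coexist at the end.
#'
#' @param beta SGE fitness penalty.
#' @param b Benefit of the resident gene.
#' @param n Grid side.
#' @param d Margolus applications per step.
#' @param well_mixed Permute positions every step.
#' @param l,c Loss rate and uptake cost.
#' @param u,m Per-step mutation probability and step size of the uptake rate.
#' @param sge_influx SGE influx rate during the window.
#' @param h_init Initial (pre-evolved) uptake rate.
#' @param equil_steps Equilibration steps before SGE influx.
#' @param influx_steps Length of the SGE influx window.
#' @param closed_steps Closed-ecosystem steps after the window.
#' @param summary_window Trailing part of the influx window (steps) over
#'   which the evolved uptake rate is averaged.
#' @param seed RNG seed.
#' @param t Uptake neighbourhood side.
#' @param report_every Reporting cadence.
#' @param ... Passed on to [ibm_run()].
#' @return A list with `run`, `mean_h_influx_tail`, `sge_freq_influx_tail`,
#'   `coexistence` (carriers, gene and SGEs all present at the end) and
#'   `config`.
#' @export
protocol_sge_challenge <- function(beta = 0.01, b = 0.03, n = 100, d = 0,
                                   well_mixed = FALSE, l = 0.02, c = 0.1,
                                   u = 5e-5, m = 0.05, sge_influx = 1e-4,
                                   h_init = 0.05, equil_steps = 20000,
                                   influx_steps = 50000, closed_steps = 20000,
                                   summary_window = 20000, seed = 1, t = 5,
                                   report_every = 100, ...) {
  cfg <- ibm_config(n = n, b = b, l = l, c = c, beta = beta, h_init = h_init,
                    d = d, well_mixed = well_mixed, t = t, u = u, m = m,
                    sge_influx = sge_influx, i_start = equil_steps,
                    i_stop = equil_steps + influx_steps, seed = seed)
  steps <- equil_steps + influx_steps + closed_steps
  init <- ibm_grid(cfg, carrier = TRUE, h = h_init)
  run <- ibm_run(cfg, steps, init = init, report_every = report_every, ...)
  ts <- run$ts
  influx_end <- equil_steps + influx_steps
  tail_ts <- ts[ts$step > influx_end - summary_window & ts$step <= influx_end, ]
  last <- ts[nrow(ts), ]
  list(run = run,
       mean_h_influx_tail = mean(tail_ts$mean_h),
       sge_freq_influx_tail = mean(tail_ts$sge_freq),
       coexistence = last$carrier_freq > 0 && last$sge_freq > 0,
       config = cfg)
}

#' Export a run to plain-text artifacts
#'
#' Writes the observable time series as CSV and a self-describing metadata
#' JSON (all configuration fields, the seed and the package version) into a
#' directory, enough to re-run the simulation exactly.
#'
#' @param run An [ibm_run()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_run <- function(run, dir) {
  stopifnot(inherits(run, "ibm_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts_path <- file.path(dir, "timeseries.csv")
  write.csv(run$ts, ts_path, row.names = FALSE)
  meta <- c(unclass(run$config),
            list(steps = run$steps, run_seed = run$seed,
                 step_offset = run$step_offset,
                 package_version = as.character(utils::packageVersion("hgtgenes"))))
  meta_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(ts_path, meta_path))
}
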