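#' Population mean growth rate
#'
#' Arithmetic mean of the per-cell growth rate over the whole lattice; the
#' lattice counterpart of the chemostat growth rate `phi`.
#'
#' @inheritParams growth_rate
#' @return A single number.
#' @export
phi_pop <- function(grid, config) {
  mean(growth_rate(grid, config))
}

# toroidal shift of a matrix by (di, dj)
shift_torus <- function(m, di, dj) {
  n <- nrow(m); p <- ncol(m)
  m[(seq_len(n) - 1 - di) %% n + 1, (seq_len(p) - 1 - dj) %% p + 1]
}

#' Local competitive advantage of carrier cells
#'
#' For every carrier, the excess of its growth rate over the mean growth
#' rate of its eight Moore neighbours (toroidal wrap); `sigma_c` is the mean
#' of these excesses over all carriers. It is 0 when all competitors are
#' carriers too and approaches the gene benefit `b` when a carrier sits
#' among non-carriers with equal uptake rates — the effective local benefit
#' of carrying the gene.
#'
#' @inheritParams growth_rate
#' @return A single number, or `NA` if the grid holds no carriers.
#' @export
sigma_c <- function(grid, config) {
  if (!any(grid$gene > 0)) return(NA_real_)
  phi <- growth_rate(grid, config)
  nb <- matrix(0, nrow(phi), ncol(phi))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- nb + shift_torus(phi, di, dj)
  }
  mean((phi - nb / 8)[grid$gene > 0])
}

#' Line-of-descent growth rate from a recorded lineage
#'
#' Averages, over all extant cells with recorded ancestry, the mean growth
#' rate of the cell's ancestors along its own line of descent, up to
#' `window` generations back (a generation boundary is a reproduction
#' event). Cells that have not yet reproduced into existence (no recorded
#' birth) are skipped; with no recorded births at all the value is `NA`.
#'
#' @param lineage The `lineage` element of an [ibm_run()] result (requires
#'   `track_lineage = TRUE, return_lineage = TRUE`): a list with `parent`,
#'   `phi`, `generation` (one entry per birth event, 0-based parent ids,
#'   -1 = none) and `site_node` (per-site id of the latest birth event).
#' @param window Number of ancestral generations to average over.
#' @return A single number.
#' @export
phi_lod <- function(lineage, window = 250) {
  par <- lineage$parent; phi <- lineage$phi
  vals <- vapply(lineage$site_node, function(v) {
    if (v < 0) return(NA_real_)
    s <- 0; k <- 0
    while (v >= 0 && k < window) {
      s <- s + phi[v + 1L]; k <- k + 1L
      v <- par[v + 1L]
    }
    s / k
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Barcode abundance tables
#'
#' Counts how many cells carry each gene barcode and each SGE barcode.
#' Column sums equal the number of carriers and infected cells.
#'
#' @param grid An `ibm_grid`.
#' @return A list of two data frames, `genes` and `sges`, with columns
#'   `barcode` and `count` (empty when no element of that kind is present).
#' @export
barcode_abundances <- function(grid) {
  tab <- function(flag, bar) {
    ids <- bar[flag > 0]
    if (length(ids) == 0)
      return(data.frame(barcode = integer(), count = integer()))
    t <- table(ids)
    data.frame(barcode = as.integer(names(t)), count = as.integer(t))
  }
  list(genes = tab(grid$gene, grid$gene_barcode),
       sges = tab(grid$sge, grid$sge_barcode))
}

#' Empirical gene classification from lattice simulations
#'
#' Determines a gene's class from simulation alone, the lattice analogue of
#' [classify_gene()]: (i) persistence without uptake is decided by whether
#' replicate runs started from an all-carrier population keep the gene
#' (majority rule); (ii) uptake is called beneficial when some fixed uptake
#' rate in `h_values` yields a mean population growth rate exceeding the
#' no-uptake baseline by more than `z` replicate standard errors. Uptake
#' rates do not evolve (`u = 0`).
#'
#' @param b Gene benefit.
#' @param config An [ibm_config()] providing everything except `b`, `u` and
#'   `h_init` (typically sets `n`, mixing, `l`, `c`).
#' @param h_values Positive uptake rates to sweep.
#' @param steps Steps per run.
#' @param burn_frac Fraction of the run discarded before averaging
#'   `phi_pop`.
#' @param replicates Replicate seeds per condition.
#' @param z Standard-error multiple for calling a growth improvement.
#' @param seed Base seed.
#' @return A list with `class` (character), `persists`, `hgt_helps`,
#'   `detail` (per-condition means), and `inconclusive` (`TRUE` when the
#'   growth comparison is within `z` standard errors both ways).
#' @export
empirical_classify <- function(b, config, h_values = c(0.02, 0.05, 0.1),
                               steps = 4000, burn_frac = 0.5,
                               replicates = 3, z = 2, seed = 1) {
  stopifnot(all(h_values > 0))
  run_at <- function(h, k) {
    cfg <- ibm_config(n = config$n, b = b, l = config$l, c = config$c,
                      h_init = h, d = config$d,
                      well_mixed = config$well_mixed, s = config$s,
                      t = config$t, u = 0, dt = config$dt,
                      seed = seed + 1000L * k)
    g <- ibm_grid(cfg, carrier = TRUE, h = h)
    ibm_run(cfg, steps, init = g, report_every = max(1, steps %/% 200))$ts
  }
  summarise <- function(h) {
    runs <- lapply(seq_len(replicates), function(k) run_at(h, k))
    tail_of <- function(ts) ts[ts$step > burn_frac * steps, ]
    phis <- vapply(runs, function(ts) mean(tail_of(ts)$phi_pop), numeric(1))
    surv <- vapply(runs, function(ts)
      ts$carrier_freq[nrow(ts)] > 0, logical(1))
    list(phi = mean(phis), se = sd(phis) / sqrt(length(phis)), surv = surv)
  }
  base <- summarise(0)
  persists <- mean(base$surv) > 0.5
  sweeps <- lapply(h_values, summarise)
  diffs <- vapply(sweeps, function(s) s$phi - base$phi, numeric(1))
  ses <- vapply(sweeps, function(s) sqrt(s$se^2 + base$se^2), numeric(1))
  helps <- any(diffs > z * ses)
  inconclusive <- !helps && any(abs(diffs) <= z * ses & diffs > 0)
  cls <- if (persists && !helps) "indispensable"
  else if (persists && helps) "enrichable"
  else if (!persists && helps) "rescuable"
  else if (b > 0) "unrescuable" else "sge"
  list(class = cls, persists = persists, hgt_helps = helps,
       detail = data.frame(h = c(0, h_values),
                           phi_pop = c(base$phi, vapply(sweeps, `[[`,
                                                        numeric(1), "phi")),
                           se = c(base$se, vapply(sweeps, `[[`, numeric(1),
                                                  "se"))),
       inconclusive = inconclusive)
}

#' Is DNA uptake evolutionarily maintained?
#'
#' Starts replicate populations of carriers that already transfer
#' (`h_init = 0.05`) with the uptake rate free to evolve, and reports
#' whether the population-mean uptake rate is still above the HGT+ threshold
#' at the end of the run in a majority of replicates.
#'
#' @param b Gene benefit.
#' @param config An [ibm_config()] supplying lattice, rates and mutation
#'   parameters (with `u = 0` the uptake rate cannot change, so the test is
#'   degenerate and trivially reports maintenance).
#' @param steps Steps per run.
#' @param replicates Number of replicate seeds.
#' @param h_init Initial uptake rate (default 0.05).
#' @param seed Base seed.
#' @return A list with `maintained` (logical) and `mean_h_end` per replicate.
#' @export
maintenance_test <- function(b, config, steps = 50000, replicates = 3,
                             h_init = 0.05, seed = 1) {
  ends <- vapply(seq_len(replicates), function(k) {
    cfg <- ibm_config(n = config$n, b = b, l = config$l, c = config$c,
                      h_init = h_init, d = config$d,
                      well_mixed = config$well_mixed, s = config$s,
                      t = config$t, u = config$u, m = config$m,
                      dt = config$dt, seed = seed + 1000L * k)
    g <- ibm_grid(cfg, carrier = TRUE, h = h_init)
    ts <- ibm_run(cfg, steps, init = g,
                  report_every = max(1, steps %/% 200))$ts
    ts$mean_h[nrow(ts)]
  }, numeric(1))
  list(maintained = mean(ends > config$hgt_plus) > 0.5, mean_h_end = ends)
}
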