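test_that("per-cell growth rate follows benefit, penalty and uptake cost", {
  cfg <- ibm_config(n = 4, b = 0.03, beta = 0.04, c = 0.1)
  g <- ibm_grid(cfg)
  expect_equal(unname(growth_rate(g, cfg)[1, 1]), 1.0)
  g$gene[1, 1] <- 1L; g$h[1, 1] <- 0.05
  expect_equal(unname(growth_rate(g, cfg)[1, 1]), 1.025)
  g$sge[1, 1] <- 1L
  expect_equal(unname(growth_rate(g, cfg)[1, 1]), 0.985)
  # growth rates are clamped at zero
  g$h[1, 1] <- 1000
  expect_equal(unname(growth_rate(g, cfg)[1, 1]), 0)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(ibm_config(n = 7), "n")
  expect_error(ibm_config(f = 1e-6, f_start = 10, f_stop = 10), "window")
  expect_error(ibm_config(b = 12), "exceeds 1")
  expect_error(ibm_config(u = 1.5), "probability")
})

test_that("reproduction copies whole cells at rate phi * dt", {
  cfg <- ibm_config(n = 40, b = 0, l = 0, c = 0)
  g <- tagged_grid(cfg)
  # every cell identical except its barcode: replacement probability is
  # exactly dt, and a replacement always changes the barcode
  changed <- vapply(1:30, function(s) {
    g2 <- ibm_sweep(g, cfg, "reproduction", seed = s)
    mean(g2$gene_barcode != g$gene_barcode)
  }, numeric(1))
  se <- sqrt(0.1 * 0.9 / (40^2 * 30))
  expect_lt(abs(mean(changed) - cfg$dt), 4 * se)
  # offspring are exact copies: barcodes always come from the block around
  # the site, and all other fields are copied along
  g$h[] <- 0.03
  g3 <- ibm_sweep(g, cfg, "reproduction", seed = 1)
  expect_true(all(g3$h == 0.03))
  expect_true(all(g3$gene == 1L))
})

test_that("reproduction favours fitter cells exactly as enumerated", {
  cfg <- ibm_config(n = 20, b = 0.5, l = 0, c = 0, seed = 9)
  set.seed(9)
  g <- ibm_grid(cfg, carrier = 0.5)
  exp_tr <- expected_transitions(g, cfg)
  gains <- losses <- numeric(200)
  for (s in 1:200) {
    g2 <- ibm_sweep(g, cfg, "reproduction", seed = s)
    gains[s] <- sum(g2$gene > g$gene)
    losses[s] <- sum(g2$gene < g$gene)
  }
  # Monte Carlo means against the exact one-sweep expectations
  expect_lt(abs(mean(gains) - exp_tr$gain), 4 * sd(gains) / sqrt(200))
  expect_lt(abs(mean(losses) - exp_tr$loss), 4 * sd(losses) / sqrt(200))
  # the carrier advantage shows: gains outnumber losses by roughly (1 + b)
  expect_gt(mean(gains), mean(losses))
})

test_that("gene loss is binomial with probability l * dt and spares non-carriers", {
  cfg <- ibm_config(n = 100, b = 0.03, l = 0.02)
  g <- ibm_grid(cfg, carrier = TRUE)
  losses <- vapply(1:40, function(s) {
    g2 <- ibm_sweep(g, cfg, "gene_loss", seed = s)
    sum(g$gene) - sum(g2$gene)
  }, numeric(1))
  expected <- 100^2 * cfg$l * cfg$dt                     # = 20
  expect_lt(abs(mean(losses) - expected), 4 * sd(losses) / sqrt(40))
  # lost genes drop their barcode too
  g2 <- ibm_sweep(g, cfg, "gene_loss", seed = 1)
  expect_true(all((g2$gene == 0) == (g2$gene_barcode == 0)))
  # l = 0 leaves the grid untouched; non-carriers are never affected
  cfg0 <- ibm_config(n = 20, l = 0)
  g0 <- ibm_grid(cfg0, carrier = TRUE)
  expect_identical(ibm_sweep(g0, cfg0, "gene_loss", seed = 1)$gene, g0$gene)
})

test_that("uptake is recipient-controlled and mass-action in the mixed limit", {
  # no donors carry anything: nothing changes
  cfg <- ibm_config(n = 20, h_init = 0.5)
  g <- ibm_grid(cfg, h = 0.5)
  g2 <- ibm_sweep(g, cfg, "hgt", seed = 1)
  expect_identical(g2$gene, g$gene)
  # a recipient with h = 0 is never transformed
  cfg2 <- ibm_config(n = 20, h_init = 0)
  gd <- ibm_grid(cfg2, carrier = 0.5, h = 0)
  g3 <- ibm_sweep(gd, cfg2, "hgt", seed = 1)
  expect_identical(g3$gene, gd$gene)
  # well-mixed limit: per-step transformation frequency of non-carriers is
  # h * dt * carrier fraction, the mass-action uptake term
  cfg3 <- ibm_config(n = 100, well_mixed = TRUE, h_init = 0.1, seed = 3)
  set.seed(3)
  gw <- ibm_grid(cfg3, carrier = 0.3, h = 0.1)
  n_non <- sum(gw$gene == 0)
  p_expect <- 0.1 * cfg3$dt * mean(gw$gene)
  trans <- vapply(1:40, function(s) {
    gw2 <- ibm_sweep(gw, cfg3, "hgt", seed = s)
    sum(gw2$gene > gw$gene) / n_non
  }, numeric(1))
  expect_lt(abs(mean(trans) - p_expect), 4 * sd(trans) / sqrt(40))
  # the recipient inherits the donor's barcodes; gene and SGE transfer
  # together from the same donor (h = 10 makes the uptake trial certain)
  cfg4 <- ibm_config(n = 10, h_init = 0, t = 3, beta = 0.01)
  g4 <- ibm_grid(cfg4, carrier = TRUE, infected = TRUE, h = 10)
  g4$gene[1, 1] <- 0L; g4$gene_barcode[1, 1] <- 0L
  g4$sge[1, 1] <- 0L; g4$sge_barcode[1, 1] <- 0L
  got <- ibm_sweep(g4, cfg4, "hgt", seed = 7)
  expect_equal(got$gene[1, 1], 1L)
  expect_equal(got$gene_barcode[1, 1], 1L)
  expect_equal(got$sge[1, 1], 1L)
  expect_equal(got$sge_barcode[1, 1], 1L)
})

test_that("influx honours its window, counts and barcode registry", {
  cfg <- ibm_config(n = 100, f = 0.05, f_start = 100, f_stop = 200,
                    sge_influx = 0, b = 0.03)
  g <- ibm_grid(cfg)
  # outside the window nothing happens
  g_out <- ibm_sweep(g, cfg, "influx", seed = 1, step_idx = 50)
  expect_equal(sum(g_out$gene), 0)
  g_out2 <- ibm_sweep(g, cfg, "influx", seed = 1, step_idx = 200)
  expect_equal(sum(g_out2$gene), 0)
  # inside: binomial count with per-step probability f * dt, each
  # discovery getting a fresh unique barcode
  counts <- vapply(1:30, function(s) {
    g2 <- ibm_sweep(g, cfg, "influx", seed = s, step_idx = 150)
    sum(g2$gene)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 100^2 * 0.05 * cfg$dt),
            4 * sd(counts) / sqrt(30))
  g2 <- ibm_sweep(g, cfg, "influx", seed = 1, step_idx = 150)
  ids <- g2$gene_barcode[g2$gene > 0]
  expect_equal(length(unique(ids)), length(ids))
  expect_equal(attr(g2, "registry")$gene_next, max(ids) + 1L)
})

test_that("uptake-rate mutation is uniform with truncation at zero", {
  cfg <- ibm_config(n = 100, u = 1, m = 0.05, h_init = 0)
  g <- ibm_grid(cfg)
  g2 <- ibm_sweep(g, cfg, "mutation", seed = 2)
  expect_true(all(g2$h >= 0))
  expect_true(all(g2$h <= 0.05))
  # mean of max(0, U(-m, m)) is m/4
  sd_mean <- sqrt(0.05^2 * 5 / 48) / 100
  expect_lt(abs(mean(g2$h) - 0.05 / 4), 4 * sd_mean)
  # u = 0 changes nothing
  cfg0 <- ibm_config(n = 20, u = 0)
  g0 <- ibm_grid(cfg0, h = 0.3)
  expect_identical(ibm_sweep(g0, cfg0, "mutation", seed = 1)$h, g0$h)
})

test_that("Margolus mixing permutes cells and destroys spatial structure", {
  cfg <- ibm_config(n = 20, d = 0)
  g <- tagged_grid(cfg)
  set.seed(7); g$h[] <- runif(400)
  expect_identical(margolus_mix(g, d = 0)$h, g$h)
  mixed <- margolus_mix(g, d = 13, seed = 4)
  expect_false(identical(mixed$gene_barcode, g$gene_barcode))
  expect_equal(cell_multiset(mixed), cell_multiset(g),
               ignore_attr = TRUE)
  expect_error(margolus_mix(list(gene = matrix(0L, 5, 5)), d = 1), "even")
  # heavy mixing of a clustered pattern removes lag-1 autocorrelation:
  # the both-carrier frequency of neighbouring sites approaches p^2
  cfg2 <- ibm_config(n = 40, d = 0)
  g2 <- ibm_grid(cfg2)
  g2$gene[1:20, ] <- 1L; g2$gene_barcode[1:20, ] <- 1L
  pair_freq <- vapply(1:30, function(s) {
    m <- margolus_mix(g2, d = 2000, seed = s)
    mean(m$gene * m$gene[c(2:40, 1), ])
  }, numeric(1))
  expect_lt(abs(mean(pair_freq) - 0.25), 4 * sd(pair_freq) / sqrt(30) + 0.002)
})

test_that("full permutation preserves the multiset and is position-uniform", {
  cfg <- ibm_config(n = 4)
  g <- tagged_grid(cfg)
  mixed <- well_mix(g, seed = 1)
  expect_equal(cell_multiset(mixed), cell_multiset(g), ignore_attr = TRUE)
  # the tracked cell lands uniformly across the 16 positions
  where <- vapply(1:2000, function(s)
    which(well_mix(g, seed = s)$gene_barcode == 1L), integer(1))
  expect_gt(stats::chisq.test(tabulate(where, 16))$p.value, 1e-4)
})

test_that("a full step composes the sweeps and matches the mixed-limit theory", {
  # empty dynamics: a fixed point
  cfg0 <- ibm_config(n = 10, b = 0, l = 0, c = 0, u = 0, d = 0)
  g0 <- tagged_grid(cfg0)
  g0$h[] <- 0
  stepped <- ibm_sweep(g0, cfg0, "step", seed = 3)
  # reproduction still copies cells around, but with all rates zero the
  # multiset is conserved and nothing else may change
  expect_equal(sum(stepped$gene), sum(g0$gene))
  # strong mixing restores the mass-action steady state C* = 1 - l/b = 1/3
  cfg <- ibm_config(n = 100, b = 0.03, l = 0.02, c = 0.2, d = 10, seed = 5)
  r <- ibm_run(cfg, 6000, init = ibm_grid(cfg, carrier = TRUE))
  tail_cf <- mean(r$ts$carrier_freq[r$ts$step > 3000])
  expect_lt(abs(tail_cf - 1 / 3), 0.06)
  # without mixing the same gene cannot be maintained: clumped carriers
  # compete mostly with each other, and the gene is lost
  cfg_s <- ibm_config(n = 100, b = 0.03, l = 0.02, c = 0.2, d = 0, seed = 5)
  r_s <- ibm_run(cfg_s, 20000, init = ibm_grid(cfg_s, carrier = TRUE))
  expect_equal(r_s$ts$carrier_freq[nrow(r_s$ts)], 0)
})

test_that("runs are reproducible, restartable and absorbing without carriers", {
  cfg <- ibm_config(n = 40, b = 0.025, l = 0.02, c = 0.2, h_init = 0.02,
                    u = 1e-4, m = 0.05, seed = 11)
  g <- ibm_grid(cfg, carrier = 0.5, h = 0.02)
  r1 <- ibm_run(cfg, 400, init = g, report_every = 50)
  r2 <- ibm_run(cfg, 400, init = g, report_every = 50)
  expect_identical(r1$ts, r2$ts)
  expect_identical(r1$grid, r2$grid)
  # checkpoint/restore: a segmented run is fully reproducible
  a1 <- ibm_run(cfg, 200, init = g, report_every = 50)
  a2 <- ibm_run(cfg, 200, init = a1$grid, report_every = 50, seed = 99,
                step_offset = 200, phase = a1$phase)
  b1 <- ibm_run(cfg, 200, init = g, report_every = 50)
  b2 <- ibm_run(cfg, 200, init = b1$grid, report_every = 50, seed = 99,
                step_offset = 200, phase = b1$phase)
  expect_identical(a2$ts, b2$ts)
  expect_identical(a2$grid, b2$grid)
  # two seeds agree qualitatively for a deep-interior gene (persistence)
  r3 <- ibm_run(cfg, 4000, init = g, seed = 12)
  r4 <- ibm_run(cfg, 4000, init = g, seed = 13)
  expect_gt(r3$ts$carrier_freq[nrow(r3$ts)], 0.2)
  expect_gt(r4$ts$carrier_freq[nrow(r4$ts)], 0.2)
  # with no influx and no carriers the non-carrier state is absorbing and
  # phi_pop = 1 - c * mean(h)
  cfg_a <- ibm_config(n = 20, b = 0.03, l = 0.02, c = 0.2, h_init = 0.05)
  ra <- ibm_run(cfg_a, 300, report_every = 300)
  expect_equal(sum(ra$grid$gene), 0)
  last <- ra$ts[nrow(ra$ts), ]
  expect_equal(last$phi_pop, 1 - 0.2 * last$mean_h, tolerance = 1e-12)
})

test_that("halving dt and doubling steps leaves the equilibrium unchanged", {
  p <- gene_params(0.025, 0.02, 0.2)
  target <- carrier_frequency(p, 0.02)
  freqs <- vapply(c(0.1, 0.05), function(dt) {
    scale <- round(0.1 / dt)
    cfg <- ibm_config(n = 100, b = 0.025, l = 0.02, c = 0.2, h_init = 0.02,
                      well_mixed = TRUE, dt = dt, seed = 21)
    g <- ibm_grid(cfg, carrier = target, h = 0.02)
    r <- ibm_run(cfg, 16000 * scale, init = g, report_every = 100)
    ts <- r$ts
    mean(ts$carrier_freq[ts$step > 4000 * scale])
  }, numeric(1))
  expect_lt(abs(freqs[1] - freqs[2]), 0.03)
})

test_that("snapshots capture the grid at requested steps", {
  cfg <- ibm_config(n = 20, b = 0.03, l = 0.02, seed = 2)
  g <- ibm_grid(cfg, carrier = TRUE)
  r <- ibm_run(cfg, 100, init = g, snapshot_steps = c(50, 100))
  expect_equal(names(r$snapshots), c("50", "100"))
  expect_identical(r$snapshots[[2]]$gene, r$grid$gene)
})
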