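# Independent oracles used across the suite.

# Numerical maximiser of the steady-state growth rate over h, independent of
# optimal_uptake()'s closed form.
numeric_h_opt <- function(params, lower = 0, upper = 0.5, tol = 1e-10) {
  stats::optimize(function(h) phi_star(params, h), c(lower, upper),
                  maximum = TRUE, tol = tol)$maximum
}

# Empirical persistence: integrate the two-type system at h = 0 from an
# interior state and ask whether carriers remain.
persists_empirically <- function(params, t_max = 2e4) {
  tr <- integrate_two_type(c(0.5, 0.5), params, h = 0, t_max = t_max)
  tr$C[nrow(tr)] > 1e-4
}

# Empirical benefit of uptake: does any h on a fine grid beat h = 0?
hgt_helps_empirically <- function(params, h_max = 0.5, n_grid = 2001) {
  hs <- seq(0, h_max, length.out = n_grid)
  phis <- phi_star(params, hs)
  max(phis[-1]) > phis[1] + 1e-12
}

# Random gene parameters kept clear of the class boundaries so that the
# closed-form and empirical classifications cannot disagree by numerics.
random_params_off_boundary <- function(margin = 0.05) {
  repeat {
    l <- runif(1, 0.005, 0.05)
    cc <- runif(1, 0.05, 0.9)
    bnd <- class_boundaries(l, cc)
    b <- runif(1, -l, 1.5 * l / cc)
    gaps <- abs(b - c(0, bnd)) / l
    if (min(gaps) > margin) return(gene_params(b, l, cc))
  }
}

# A small all-distinct grid: every cell gets a unique gene barcode so that
# any movement or replacement is visible.
tagged_grid <- function(cfg, h = 0) {
  g <- ibm_grid(cfg, carrier = TRUE, h = h)
  g$gene_barcode <- matrix(seq_len(cfg$n^2), cfg$n, cfg$n)
  attr(g, "registry") <- list(gene_next = cfg$n^2 + 1L, sge_next = 1L)
  g
}

# Sort all per-cell fields jointly, for multiset comparisons.
cell_multiset <- function(grid) {
  df <- data.frame(gene = as.vector(grid$gene),
                   gbar = as.vector(grid$gene_barcode),
                   sge = as.vector(grid$sge),
                   sbar = as.vector(grid$sge_barcode),
                   h = as.vector(grid$h))
  df <- df[order(df$gene, df$gbar, df$sge, df$sbar, df$h), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Exact per-sweep expectation of state transitions in one reproduction
# sweep, enumerated from the fixed pre-sweep grid (the decision rule reads
# only the pre-sweep state, so the expectation is a plain sum over sites).
expected_transitions <- function(grid, cfg) {
  n <- cfg$n
  phi <- growth_rate(grid, cfg)
  exp_gain <- 0; exp_loss <- 0
  rad <- cfg$s %/% 2
  for (i in seq_len(n)) for (j in seq_len(n)) {
    nb_i <- ((i - 1 + (-rad:rad)) %% n) + 1
    nb_j <- ((j - 1 + (-rad:rad)) %% n) + 1
    p_rep <- 0; p_carrier_rep <- 0
    for (a in nb_i) for (bb in nb_j) {
      if (a == i && bb == j) next
      p <- phi[a, bb] * cfg$dt / (cfg$s^2 - 1)
      p_rep <- p_rep + p
      if (grid$gene[a, bb] > 0) p_carrier_rep <- p_carrier_rep + p
    }
    if (grid$gene[i, j] > 0) exp_loss <- exp_loss + (p_rep - p_carrier_rep)
    else exp_gain <- exp_gain + p_carrier_rep
  }
  list(gain = exp_gain, loss = exp_loss)
}
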