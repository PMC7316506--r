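#' Parameters of a transferable gene
#'
#' Bundles the three parameters that characterise a gene in the well-mixed
#' chemostat model: its growth-rate effect `b` (negative for a selfish
#' genetic element), the rate `l` at which carriers lose it, and the
#' dimensionless cost coefficient `c` paid per unit uptake rate.
#'
#' @param b Growth-rate benefit of carrying the gene (per unit time). May be
#'   negative, in which case the element is selfish.
#' @param l Gene-loss rate (per unit time), must be positive.
#' @param c Cost coefficient of DNA uptake (dimensionless), must be positive.
#'   Gene classification additionally assumes `c < 1`, which guarantees the
#'   ordering of the class boundaries `4cl/(1+c)^2 < l < l/c`.
#' @return An object of class `gene_params`.
#' @examples
#' gene_params(b = 0.025, l = 0.02, c = 0.2)
#' @export
gene_params <- function(b, l, c) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
  if (!is.numeric(l) || length(l) != 1L || l <= 0)
    stop("gene-loss rate `l` must be a single positive number", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || c <= 0)
    stop("uptake cost `c` must be a single positive number", call. = FALSE)
  structure(list(b = b, l = l, c = c), class = "gene_params")
}

#' @export
print.gene_params <- function(x, ...) {
  cat(sprintf("gene: b = %g, l = %g, c = %g\n", x$b, x$l, x$c))
  if (x$l > 0 && x$c > 0 && x$c < 1)
    cat(sprintf("class: %s\n", classify_gene(x)))
  invisible(x)
}

as_gene_params <- function(params) {
  if (inherits(params, "gene_params")) return(params)
  if (is.list(params) && all(c("b", "l", "c") %in% names(params)))
    return(gene_params(params$b, params$l, params$c))
  stop("`params` must be a gene_params object", call. = FALSE)
}

check_uptake <- function(h) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0))
    stop("uptake rate `h` must be finite and non-negative", call. = FALSE)
  h
}

#' Right-hand side of the two-type carrier/non-carrier model
#'
#' Time derivatives of the carrier density `C` and non-carrier density `N`
#' in a chemostat where carriers grow at rate `1 + b - c h`, non-carriers at
#' `1 - c h`, carriers lose the gene at rate `l`, and non-carriers are
#' transformed into carriers by mass-action uptake `h C N`. The mean growth
#' rate `phi` is washed out of both types, so any state with `C + N = 1`
#' stays on that simplex.
#'
#' @param state Numeric vector `c(C, N)` of non-negative densities.
#' @param params A [gene_params()] object.
#' @param h Uptake rate, a single non-negative number.
#' @return Numeric vector `c(dC, dN)`.
#' @export
rhs_two_type <- function(state, params, h) {
  params <- as_gene_params(params)
  check_uptake(h)
  C <- state[[1]]; N <- state[[2]]
  if (C < 0 || N < 0) stop("densities must be non-negative", call. = FALSE)
  gC <- 1 - params$c * h + params$b
  gN <- 1 - params$c * h
  phi <- gC * C + gN * N
  dC <- gC * C - params$l * C + h * C * N - phi * C
  dN <- gN * N + params$l * C - h * C * N - phi * N
  c(dC = dC, dN = dN)
}

#' Integrate the two-type model to (or towards) steady state
#'
#' Numerically solves the carrier/non-carrier system with an adaptive
#' non-stiff solver. Convergence is declared when the largest derivative
#' magnitude at the final time drops below `deriv_tol`; otherwise the
#' (partial) trajectory is returned with `converged = FALSE`.
#'
#' @inheritParams rhs_two_type
#' @param init Numeric vector `c(C, N)` of initial densities.
#' @param t_max Final integration time.
#' @param n_out Number of output time points.
#' @param rtol Relative tolerance passed to the solver.
#' @param deriv_tol Derivative threshold below which the end state counts as
#'   a steady state.
#' @return A data frame with columns `time`, `C`, `N` and attribute
#'   `converged`.
#' @export
integrate_two_type <- function(init, params, h, t_max = 1e4, n_out = 200,
                               rtol = 1e-8, deriv_tol = 1e-10) {
  params <- as_gene_params(params)
  check_uptake(h)
  stopifnot(t_max > 0)
  times <- seq(0, t_max, length.out = n_out)
  # the solver may step infinitesimally below zero; clamp before evaluating
  fn <- function(t, y, p) list(rhs_two_type(pmax(y, 0), params, h))
  sol <- deSolve::lsoda(c(C = init[[1]], N = init[[2]]), times, fn,
                        parms = NULL, rtol = rtol, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out) <- c("time", "C", "N")
  end <- pmax(unlist(out[nrow(out), c("C", "N")]), 0)
  attr(out, "converged") <- max(abs(rhs_two_type(end, params, h))) < deriv_tol
  out
}

#' Steady-state carrier frequency
#'
#' Closed-form equilibrium frequency of carrier cells: the gene persists
#' only when `h > l - b`, in which case `C* = 1 - l/(b + h)`; otherwise the
#' population equilibrates at all non-carriers.
#'
#' @inheritParams rhs_two_type
#' @return Carrier frequency in `[0, 1]` (vectorised over `h`).
#' @export
carrier_frequency <- function(params, h) {
  params <- as_gene_params(params)
  check_uptake(h)
  ifelse(h > params$l - params$b, 1 - params$l / (params$b + h), 0)
}

#' Steady-state population growth rate
#'
#' The equilibrium mean growth rate as a function of the uptake rate `h`:
#' `1 - c h` while the gene cannot persist (`h <= l - b`) and
#' `1 - c h + b - b l/(b + h)` once it does. The two branches meet
#' continuously at `h = l - b`. The identity
#' `phi* = 1 + b C* - c h` links it to [carrier_frequency()].
#'
#' @inheritParams rhs_two_type
#' @return The steady-state growth rate (vectorised over `h`).
#' @export
phi_star <- function(params, h) {
  params <- as_gene_params(params)
  check_uptake(h)
  ifelse(h > params$l - params$b,
         1 - params$c * h + params$b - params$b * params$l / (params$b + h),
         1 - params$c * h)
}

#' Growth-optimal uptake rate
#'
#' The uptake rate at which the persisting branch of the steady-state
#' growth rate peaks: `h_opt = sqrt(b l / c) - b`, clamped at zero. For
#' `b >= l/c` (indispensable genes) the peak sits at or below zero, so no
#' uptake is ever optimal, and for `b <= 0` (selfish elements) uptake only
#' costs. For genes that persist without uptake (`b > l`) this is the global
#' maximiser of [phi_star()]; for weaker genes the all-non-carrier branch
#' value `1` may still exceed the peak (the unrescuable case).
#'
#' @inheritParams rhs_two_type
#' @return Optimal uptake rate, `>= 0`.
#' @export
optimal_uptake <- function(params) {
  params <- as_gene_params(params)
  if (params$b <= 0) return(0)
  max(0, sqrt(params$b * params$l / params$c) - params$b)
}

#' Class boundaries on the benefit axis
#'
#' For fixed `l` and `c` (`0 < c < 1`) the benefit axis is partitioned at
#' `b = 0`, `b = 4cl/(1+c)^2`, `b = l` and `b = l/c`.
#'
#' @param l Gene-loss rate.
#' @param c Uptake cost coefficient, in `(0, 1)`.
#' @return Named numeric vector of the four boundaries in increasing order.
#' @export
class_boundaries <- function(l, c) {
  stopifnot(l > 0, c > 0, c < 1)
  bnd <- c(sge = 0,
           unrescuable = 4 * c * l / (1 + c)^2,
           rescuable = l,
           enrichable = l / c)
  stopifnot(all(diff(bnd) > 0))
  bnd
}

#' Classify a gene by persistence and by the value of uptake
#'
#' Genes fall into five classes according to (i) whether they persist in the
#' population without any uptake and (ii) whether some uptake rate raises
#' the steady-state growth rate above its no-uptake value:
#' \describe{
#'   \item{indispensable}{`b >= l/c`: persists, uptake never pays.}
#'   \item{enrichable}{`l < b < l/c`: persists, moderate uptake raises growth.}
#'   \item{rescuable}{`4cl/(1+c)^2 < b <= l`: lost without uptake, but uptake
#'     can raise growth above baseline.}
#'   \item{unrescuable}{`0 < b <= 4cl/(1+c)^2`: lost without uptake and not
#'     worth recovering.}
#'   \item{sge}{`b <= 0`: a selfish element, persists only through uptake.}
#' }
#' Boundary values are assigned to the weaker-gene side except `b = l/c`,
#' which is indispensable (there `h_opt = 0` exactly).
#'
#' @inheritParams rhs_two_type
#' @return A single character string, one of `"indispensable"`,
#'   `"enrichable"`, `"rescuable"`, `"unrescuable"`, `"sge"`.
#' @export
classify_gene <- function(params) {
  params <- as_gene_params(params)
  if (params$c >= 1)
    stop("classification requires c < 1 (boundary ordering breaks)", call. = FALSE)
  bnd <- class_boundaries(params$l, params$c)
  b <- params$b
  if (b >= bnd[["enrichable"]]) "indispensable"
  else if (b > bnd[["rescuable"]]) "enrichable"
  else if (b > bnd[["unrescuable"]]) "rescuable"
  else if (b > bnd[["sge"]]) "unrescuable"
  else "sge"
}

#' Scan the carrier-frequency and growth-rate surfaces
#'
#' Evaluates the closed-form steady state on the outer product of a benefit
#' grid and an uptake grid, in long format ready for CSV export.
#'
#' @param b_grid,h_grid Numeric vectors of benefits and uptake rates.
#' @param l,c Loss rate and uptake cost.
#' @return A data frame with columns `b`, `h`, `C_star`, `phi_star`,
#'   `class`, `dphi_dh_sign`.
#' @export
scan_surface <- function(b_grid, h_grid, l, c) {
  stopifnot(all(is.finite(b_grid)), all(is.finite(h_grid)))
  grid <- expand.grid(b = b_grid, h = h_grid, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    p <- gene_params(grid$b[k], l, c)
    h <- grid$h[k]
    data.frame(b = p$b, h = h,
               C_star = carrier_frequency(p, h),
               phi_star = phi_star(p, h),
               class = classify_gene(p),
               dphi_dh_sign = dphi_dh_sign(p, h))
  })
  do.call(rbind, res)
}

# Sign of the derivative of phi* with respect to h, branch-aware.
dphi_dh_sign <- function(params, h) {
  d <- if (h > params$l - params$b)
    -params$c + params$b * params$l / (params$b + h)^2
  else -params$c
  sign(d)
}

#' Bifurcation scan of the growth-rate response to uptake
#'
#' For each point of a `(b, h)` grid, reports the sign of the derivative of
#' the steady-state growth rate with respect to `h`, together with the two
#' organising curves: the persistence line `h = l - b` and the optimal
#' uptake curve `h_opt(b)`.
#'
#' @inheritParams scan_surface
#' @return A list with elements `grid` (data frame `b`, `h`,
#'   `dphi_dh_sign`), and `curves` (data frame `b`, `h_persist`, `h_opt`).
#' @export
bifurcation_scan <- function(b_grid, h_grid, l, c) {
  grid <- expand.grid(b = b_grid, h = h_grid, KEEP.OUT.ATTRS = FALSE)
  grid$dphi_dh_sign <- vapply(seq_len(nrow(grid)), function(k)
    dphi_dh_sign(gene_params(grid$b[k], l, c), grid$h[k]), numeric(1))
  curves <- data.frame(
    b = b_grid,
    h_persist = pmax(0, l - b_grid),
    h_opt = vapply(b_grid, function(b) optimal_uptake(gene_params(b, l, c)),
                   numeric(1)))
  list(grid = grid, curves = curves)
}
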