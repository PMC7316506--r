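#' Right-hand side of the two-species (four-type) competition model
#'
#' Dynamics of an uptake-negative species (densities `C_minus`, `N_minus`,
#' uptake rate `h_minus`, normally 0) competing in a chemostat with an
#' uptake-positive species (`C_plus`, `N_plus`, uptake rate `h_plus`). Both
#' species carry, lose and donate the same gene; crucially the donor pool
#' for uptake is the total carrier density `C_minus + C_plus`, so a
#' transferring invader can feed on resident carriers.
#'
#' @param state Numeric vector `c(C_minus, N_minus, C_plus, N_plus)`.
#' @param params A [gene_params()] object.
#' @param h_plus Uptake rate of the uptake-positive species.
#' @param h_minus Uptake rate of the other species (default 0).
#' @return Numeric vector of the four time derivatives.
#' @export
rhs_four_type <- function(state, params, h_plus, h_minus = 0) {
  params <- as_gene_params(params)
  check_uptake(h_plus); check_uptake(h_minus)
  if (any(state < 0)) stop("densities must be non-negative", call. = FALSE)
  Cm <- state[[1]]; Nm <- state[[2]]; Cp <- state[[3]]; Np <- state[[4]]
  b <- params$b; l <- params$l; cc <- params$c
  donors <- Cm + Cp
  gCm <- 1 + b - cc * h_minus; gNm <- 1 - cc * h_minus
  gCp <- 1 + b - cc * h_plus;  gNp <- 1 - cc * h_plus
  phi <- gCm * Cm + gNm * Nm + gCp * Cp + gNp * Np
  c(dC_minus = gCm * Cm - l * Cm + h_minus * Nm * donors - phi * Cm,
    dN_minus = gNm * Nm + l * Cm - h_minus * Nm * donors - phi * Nm,
    dC_plus  = gCp * Cp - l * Cp + h_plus * Np * donors - phi * Cp,
    dN_plus  = gNp * Np + l * Cp - h_plus * Np * donors - phi * Np)
}

#' Integrate the four-type model
#'
#' @inheritParams rhs_four_type
#' @param init Numeric vector `c(C_minus, N_minus, C_plus, N_plus)`.
#' @param t_max Final time.
#' @param n_out Number of output rows.
#' @param rtol Relative solver tolerance.
#' @return Data frame `time`, `C_minus`, `N_minus`, `C_plus`, `N_plus`.
#' @export
integrate_four_type <- function(init, params, h_plus, h_minus = 0,
                                t_max = 1e5, n_out = 400, rtol = 1e-8) {
  params <- as_gene_params(params)
  times <- exp(seq(log(1e-2), log(t_max), length.out = n_out - 1L))
  times <- c(0, times)
  fn <- function(t, y, p) list(rhs_four_type(pmax(y, 0), params, h_plus, h_minus))
  y0 <- c(C_minus = init[[1]], N_minus = init[[2]],
          C_plus = init[[3]], N_plus = init[[4]])
  sol <- deSolve::lsoda(y0, times, fn, parms = NULL, rtol = rtol, atol = 1e-14)
  out <- as.data.frame(sol)
  names(out) <- c("time", "C_minus", "N_minus", "C_plus", "N_plus")
  out
}

#' Resident equilibrium of a single species
#'
#' Places one species at its two-type steady state (from
#' [carrier_frequency()]) and the other at density zero, as the starting
#' point of an invasion experiment.
#'
#' @inheritParams rhs_four_type
#' @param h_res Uptake rate of the resident.
#' @param resident Which slot the resident occupies: `"minus"` (default) or
#'   `"plus"`.
#' @return Named numeric vector `c(C_minus, N_minus, C_plus, N_plus)` with
#'   attribute `phi`, the resident equilibrium growth rate.
#' @export
resident_equilibrium <- function(params, h_res, resident = c("minus", "plus")) {
  params <- as_gene_params(params)
  resident <- match.arg(resident)
  Cs <- carrier_frequency(params, h_res)
  st <- if (resident == "minus")
    c(C_minus = Cs, N_minus = 1 - Cs, C_plus = 0, N_plus = 0)
  else
    c(C_minus = 0, N_minus = 0, C_plus = Cs, N_plus = 1 - Cs)
  attr(st, "phi") <- phi_star(params, h_res)
  st
}

#' Invasion fitness of a rare uptake mutant
#'
#' Linearises the invader's carrier/non-carrier subsystem around the
#' resident equilibrium, holding the chemostat dilution `phi` at the
#' resident value (the invader is measure-zero). The invader Jacobian is
#' \preformatted{
#'   | 1 + b - c h_inv - l - phi*      h_inv C_res*            |
#'   | l                               1 - c h_inv - h_inv C_res* - phi* |
#' }
#' and the returned dominant eigenvalue is positive exactly when the mutant
#' grows from rare.
#'
#' @inheritParams rhs_four_type
#' @param h_res Resident uptake rate.
#' @param h_inv Invader uptake rate.
#' @return The dominant eigenvalue (per unit time).
#' @export
invasion_fitness <- function(params, h_res, h_inv) {
  params <- as_gene_params(params)
  check_uptake(h_res); check_uptake(h_inv)
  b <- params$b; l <- params$l; cc <- params$c
  Cres <- carrier_frequency(params, h_res)
  phi <- phi_star(params, h_res)
  J <- matrix(c(1 + b - cc * h_inv - l - phi, h_inv * Cres,
                l, 1 - cc * h_inv - h_inv * Cres - phi),
              nrow = 2, byrow = TRUE)
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' Is an uptake rate evolutionarily stable?
#'
#' `is_ess(params, h)` asks whether a non-transferring mutant can invade a
#' resident transferring at rate `h`; `is_evolvable(params, h)` asks whether
#' a mutant transferring at rate `h` can invade a non-transferring resident.
#'
#' @inheritParams rhs_four_type
#' @param h Uptake rate under test (must be positive for a meaningful test;
#'   `is_evolvable` returns `FALSE` for `h = 0`).
#' @return Logical scalar.
#' @export
is_ess <- function(params, h) {
  invasion_fitness(params, h_res = h, h_inv = 0) < 0
}

#' @rdname is_ess
#' @export
is_evolvable <- function(params, h) {
  if (h <= 0) return(FALSE)
  invasion_fitness(params, h_res = 0, h_inv = h) > 0
}

#' Founder-size basin scan for invasion of a transferring strain
#'
#' For each founder composition `(C_plus, N_plus)` the uptake-positive
#' strain is introduced into an uptake-negative resident occupying the
#' remaining density at its own equilibrium proportions, and the full
#' nonlinear system is integrated. Invasion counts as successful when the
#' uptake-positive share exceeds 0.5 at `t_max` and has not declined over
#' the last decade of time. For rescuable genes this reveals positive
#' frequency dependence (an Allee effect): only sufficiently large founder
#' populations with enough carriers invade.
#'
#' @inheritParams rhs_four_type
#' @param h_inv Uptake rate of the introduced strain.
#' @param C_plus_grid,N_plus_grid Founder densities to scan (each in
#'   `(0, 1]`, pairs with total `> 1` are skipped as `NA`).
#' @param t_max Integration horizon.
#' @return Data frame `C_plus_0`, `N_plus_0`, `success`.
#' @export
founder_basin_scan <- function(params, h_inv, C_plus_grid, N_plus_grid,
                               t_max = 1e5) {
  params <- as_gene_params(params)
  grid <- expand.grid(C_plus_0 = C_plus_grid, N_plus_0 = N_plus_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$success <- vapply(seq_len(nrow(grid)), function(k) {
    cp <- grid$C_plus_0[k]; np <- grid$N_plus_0[k]
    if (cp + np > 1) return(NA)
    invasion_succeeds(params, h_inv, cp, np, t_max)
  }, logical(1))
  grid
}

# Shared nonlinear invasion criterion: resident fills the density left by
# the founder at its own equilibrium composition.
invasion_succeeds <- function(params, h_inv, C_plus_0, N_plus_0, t_max = 1e5) {
  Cres <- carrier_frequency(params, 0)
  rest <- 1 - C_plus_0 - N_plus_0
  init <- c(rest * Cres, rest * (1 - Cres), C_plus_0, N_plus_0)
  tr <- integrate_four_type(init, params, h_plus = h_inv, t_max = t_max)
  share <- (tr$C_plus + tr$N_plus) /
    pmax(tr$C_minus + tr$N_minus + tr$C_plus + tr$N_plus, 1e-300)
  n <- nrow(tr)
  early <- which.min(abs(tr$time - t_max / 10))
  share[n] > 0.5 && share[n] >= share[early] - 1e-6
}

#' Trajectory of gene-carrying donor cells during an invasion
#'
#' Integrates the four-type model from a founder composition and returns
#' the total carrier (donor) density over time — the quantity whose decay
#' or growth decides the fate of a transferring invader.
#'
#' @inheritParams founder_basin_scan
#' @param founder Numeric vector `c(C_plus_0, N_plus_0)`.
#' @return Data frame `time`, `donors`, `share_plus`.
#' @export
donor_trajectory <- function(params, h_inv, founder, t_max = 1e5) {
  params <- as_gene_params(params)
  Cres <- carrier_frequency(params, 0)
  rest <- 1 - founder[[1]] - founder[[2]]
  stopifnot(rest >= 0)
  init <- c(rest * Cres, rest * (1 - Cres), founder[[1]], founder[[2]])
  tr <- integrate_four_type(init, params, h_plus = h_inv, t_max = t_max)
  data.frame(time = tr$time,
             donors = tr$C_minus + tr$C_plus,
             share_plus = (tr$C_plus + tr$N_plus) /
               pmax(tr$C_minus + tr$N_minus + tr$C_plus + tr$N_plus, 1e-300))
}
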