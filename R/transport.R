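#' Create an empty chemokine field state
#'
#' Per-voxel free and ECM-bound CXCL12 concentration fields (nM) plus the
#' simulation clock in seconds.
#'
#' @param grid a `cxcl_grid`.
#' @param free,bound optional initial 3D arrays (nM), defaults all zero.
#' @param time simulation clock (s).
#' @return a `cxcl_state` object.
#' @export
grid_state <- function(grid, free = NULL, bound = NULL, time = 0) {
  stopifnot(inherits(grid, "cxcl_grid"))
  z <- array(0, dim = grid$dims)
  if (is.null(free)) free <- z
  if (is.null(bound)) bound <- z
  stopifnot(identical(dim(free), grid$dims), identical(dim(bound), grid$dims))
  if (any(free < 0) || any(bound < 0)) {
    abort("concentrations must be non-negative",
          class = "cxcl12grad_state_error")
  }
  structure(list(free = free, bound = bound, time = time, dims = grid$dims),
            class = "cxcl_state")
}

#' @export
print.cxcl_state <- function(x, ...) {
  cat(sprintf("<cxcl_state> %s voxels, t = %.1f s, free %.4g nM, bound %.4g nM (grid totals)\n",
              paste(x$dims, collapse = "x"), x$time,
              sum(x$free), sum(x$bound)))
  invisible(x)
}

#' Total (free + bound) concentration in a voxel
#'
#' Gradients are always computed on the sum of the free and ECM-bound
#' pools.
#'
#' @param state a `cxcl_state`.
#' @param voxel 1-based linear voxel index (vectorized).
#' @return total concentration(s) in nM.
#' @export
total_concentration <- function(state, voxel) {
  n <- prod(state$dims)
  if (any(voxel < 1 | voxel > n)) {
    abort("voxel index out of range", class = "cxcl12grad_state_error")
  }
  state$free[voxel] + state$bound[voxel]
}

#' Isoform-specific extracellular parameters
#'
#' Default parameter sets for CXCL12-alpha, -beta and -gamma. The ordering
#' constraints are the established biology — ECM partition gamma > beta >
#' alpha, secretion rate and blood level alpha > beta > gamma — while the
#' magnitudes are literature-informed package defaults, overridable in the
#' run configuration.
#'
#' @param isoform `"alpha"`, `"beta"` or `"gamma"`.
#' @return list with `S` (molecules/cell/s), `K_p` (ECM partition
#'   coefficient, bound/free at equilibrium), `k_on_ecm` (1/s) and
#'   `blood_mean` (nM).
#' @export
isoform_params <- function(isoform = c("alpha", "beta", "gamma")) {
  isoform <- match.arg(isoform)
  switch(isoform,
    alpha = list(isoform = "alpha", S = 1.0,  K_p = 1,  k_on_ecm = 0.1,
                 blood_mean = 0.25),
    beta  = list(isoform = "beta",  S = 0.5,  K_p = 5,  k_on_ecm = 0.1,
                 blood_mean = 0.10),
    gamma = list(isoform = "gamma", S = 0.25, K_p = 25, k_on_ecm = 0.1,
                 blood_mean = 0.02)
  )
}

#' Secrete chemokine into occupied voxels
#'
#' Each secreting cell adds `S * dt` molecules to its own compartment,
#' converted to nM through the voxel volume and Avogadro's number (602
#' molecules per 1-pL voxel per nM).
#'
#' @param state a `cxcl_state`.
#' @param placements placements tibble of secreting cells.
#' @param S secretion rate, molecules/cell/s.
#' @param dt timestep (s).
#' @param grid the `cxcl_grid` (for the voxel volume).
#' @return updated `cxcl_state`.
#' @export
secrete <- function(state, placements, S, dt, grid) {
  if (S < 0) abort("secretion rate must be >= 0",
                   class = "cxcl12grad_config_error")
  if (nrow(placements) == 0 || S == 0) return(state)
  d_nM <- S * dt / molecules_per_nM(grid$voxel_volume_l)
  state$free[placements$voxel] <- state$free[placements$voxel] + d_nM
  state
}

#' Diffuse the free field (alternating direction explicit scheme)
#'
#' One or more timesteps of diffusion of the free pool with no-flux
#' boundaries; the ECM-bound pool is immobile. The scheme averages an
#' upward and a downward Saul'yev sweep per step; each sweep is written in
#' flux form so total mass is conserved to round-off. The scheme is
#' unconditionally stable; a warning is issued when `D*dt/dx^2 > 1`
#' (accuracy, not stability).
#'
#' @param state a `cxcl_state`.
#' @param grid a `cxcl_grid`.
#' @param D diffusivity (um^2/s).
#' @param dt timestep (s).
#' @param vessel optional `cxcl_vessel`: vessel voxels are excluded from the
#'   tissue domain (internal no-flux wall).
#' @param n_steps number of consecutive steps to take.
#' @return updated `cxcl_state`.
#' @export
diffuse <- function(state, grid, D, dt, vessel = NULL, n_steps = 1L) {
  lam <- D * dt / grid$voxel_size^2
  if (lam > 1) {
    warn(sprintf("D*dt/dx^2 = %.2f > 1: ADE remains stable but accuracy degrades", lam))
  }
  mask <- vessel_mask(grid, vessel)
  state$free <- cpp_ade_step(state$free, grid$dims, mask, lam,
                             as.integer(n_steps))
  state$time <- state$time + n_steps * dt
  state
}

vessel_mask <- function(grid, vessel = NULL) {
  mask <- logical(grid$n_voxels)
  if (!is.null(vessel)) mask[vessel$vessel_voxels] <- TRUE
  mask
}

#' First-order extracellular degradation
#'
#' Exact exponential decay of the free pool; ECM-bound chemokine is
#' protected from extracellular proteolysis and is untouched.
#'
#' @param state a `cxcl_state`.
#' @param k_deg degradation rate (1/s).
#' @param dt timestep (s).
#' @return updated `cxcl_state`.
#' @export
degrade <- function(state, k_deg, dt) {
  stopifnot(k_deg >= 0, dt >= 0)
  state$free <- state$free * exp(-k_deg * dt)
  state
}

#' Reversible ECM binding (linear, non-saturable)
#'
#' Per-voxel exchange `dB/dt = k_on * F - (k_on / K_p) * B`, integrated
#' exactly over `dt` (exponential relaxation toward the equilibrium
#' partition `B/F = K_p`); free + bound is conserved in every voxel.
#'
#' @param state a `cxcl_state`.
#' @param ecm list with `k_on_ecm` (1/s) and `K_p` (dimensionless
#'   equilibrium partition coefficient bound/free).
#' @param dt timestep (s).
#' @return updated `cxcl_state`.
#' @export
ecm_exchange <- function(state, ecm, dt) {
  k_on <- ecm$k_on_ecm
  K_p <- ecm$K_p
  stopifnot(k_on >= 0, dt >= 0)
  if (k_on == 0 || K_p <= 0) return(state)
  k_off <- k_on / K_p
  rate <- k_on + k_off
  tot <- state$free + state$bound
  beq <- tot * (k_on / rate)
  state$bound <- beq + (state$bound - beq) * exp(-rate * dt)
  state$free <- tot - state$bound
  state
}
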