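#' Circadian forcing parameters
#'
#' Cosine forcing of either the cellular secretion rate or the blood
#' CXCL12 concentration:
#' `X(t) = ((X_max - X_min)/2) cos(2 pi f (t - phi)) + (X_max + X_min)/2`.
#' With the default `"printed"` phase convention `phi = t_start - t_max`;
#' the `"natural"` convention uses `phi = t_max - t_start` so the maximum
#' falls at clock time `t_max` hours after a start at `t_start = 0`. The
#' default fold change max/min is 2 over a 24-h period, with the human
#' phase (blood maximum in the morning, 9 am).
#'
#' @param x_max,x_min maximum and minimum of the forced quantity (same
#'   units as the quantity; `x_max >= x_min >= 0`).
#' @param f frequency (1/h), default 1/24.
#' @param t_start clock time (h) the simulation begins.
#' @param t_max clock time (h) of the maximum.
#' @param convention `"printed"` or `"natural"` phase construction.
#' @return a `circadian_params` list.
#' @export
circadian_params <- function(x_max, x_min, f = 1 / 24, t_start = 9,
                             t_max = 9, convention = c("printed", "natural")) {
  convention <- match.arg(convention)
  if (!(x_max >= x_min && x_min >= 0)) {
    abort("need x_max >= x_min >= 0", class = "cxcl12grad_config_error")
  }
  structure(list(x_max = x_max, x_min = x_min, f = f, t_start = t_start,
                 t_max = t_max, convention = convention),
            class = "circadian_params")
}

#' Build circadian parameters from a mean and fold change
#'
#' `x_max` and `x_min` such that their arithmetic mean is `mean` and
#' `x_max / x_min = fold` (default 2-fold daily variation).
#'
#' @param mean mean of the forced quantity.
#' @param fold max/min ratio (>= 1).
#' @inheritParams circadian_params
#' @return a `circadian_params`.
#' @export
circadian_from_mean <- function(mean, fold = 2, f = 1 / 24, t_start = 9,
                                t_max = 9,
                                convention = c("printed", "natural")) {
  stopifnot(mean >= 0, fold >= 1)
  circadian_params(x_max = 2 * mean * fold / (fold + 1),
                   x_min = 2 * mean / (fold + 1),
                   f = f, t_start = t_start, t_max = t_max,
                   convention = match.arg(convention))
}

circadian_phase0 <- function(params) {
  if (params$convention == "printed") params$t_start - params$t_max
  else params$t_max - params$t_start
}

#' Evaluate the circadian forcing at clock time t
#'
#' @param t clock time in hours (vectorized).
#' @param params a `circadian_params`.
#' @return the forced quantity at `t`.
#' @export
#' @examples
#' p <- circadian_from_mean(0.25, fold = 2, t_start = 9, t_max = 9)
#' max(circadian_value(seq(0, 24, by = 0.01), p)) /
#'   min(circadian_value(seq(0, 24, by = 0.01), p)) # 2
circadian_value <- function(t, params) {
  stopifnot(inherits(params, "circadian_params"))
  A <- (params$x_max - params$x_min) / 2
  M <- (params$x_max + params$x_min) / 2
  A * cos(2 * pi * params$f * (t - circadian_phase0(params))) + M
}

#' Transvascular mass transfer across the vessel wall
#'
#' Moles-equivalent of CXCL12 transferred from blood to a tissue
#' compartment over one step, `n = p A (C_blood - C_endo) dt`; positive
#' into tissue when blood exceeds tissue. Units: with `p` in um/s, `A` in
#' um^2 and concentrations in nM the return value is nM * um^3 (divide by
#' the compartment volume in um^3 for the concentration increment).
#'
#' @param c_blood blood concentration (nM).
#' @param c_endo tissue concentration just outside the wall (nM).
#' @param p vascular permeability (um/s).
#' @param A exchange surface area (um^2).
#' @param dt timestep (s).
#' @return transferred amount (nM um^3), signed.
#' @export
vessel_exchange <- function(c_blood, c_endo, p, A, dt) {
  stopifnot(p >= 0, all(A >= 0), dt >= 0)
  p * A * (c_blood - c_endo) * dt
}

#' Apply the vessel mass-transfer boundary condition
#'
#' Every lining compartment sharing at least one face with the vessel
#' exchanges free chemokine with the blood via [vessel_exchange()], the
#' exchange area being the summed shared face area. The blood is an
#' infinite reservoir: tissue fluxes do not alter `C_blood`.
#'
#' @param state a `cxcl_state`.
#' @param vessel a `cxcl_vessel`.
#' @param grid a `cxcl_grid`.
#' @param c_blood blood concentration at this time (nM), spatially uniform.
#' @param p vascular permeability (um/s).
#' @param dt timestep (s).
#' @return updated `cxcl_state`.
#' @export
apply_vessel_bc <- function(state, vessel, grid, c_blood, p, dt) {
  ex <- vessel$exchange
  dC <- vessel_exchange(c_blood, state$free[ex$voxel], p, ex$area_um2, dt) /
    grid$voxel_volume_um3
  state$free[ex$voxel] <- state$free[ex$voxel] + dC
  state
}
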