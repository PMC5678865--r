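# Shared desk-scale configurations; kinetic defaults are never altered here,
# only problem size and schedule.
tiny_setup2 <- function(...) scaled_config("setup2", ...)
tiny_setup1 <- function(...) scaled_config("setup1", ...)

# independent lsoda reference for the trafficking subsystem (same model,
# different integrator)
trafficking_reference <- function(params, L, times, y0 = NULL) {
  rhs <- function(t, y, pp) {
    with(as.list(c(y, pp)), {
      bind <- k_on * L * Rs
      list(c(
        Rs = -bind + k_off * Cs - k_int0 * Rs + k_rec * Ri + q_syn,
        Cs = bind - (k_off + k_int) * Cs,
        Ri = k_int0 * Rs - k_rec * Ri + k_degL * Ci,
        Ci = k_int * Cs - k_degL * Ci,
        Ldeg = k_degL * Ci))
    })
  }
  if (is.null(y0)) {
    y0 <- c(Rs = params$R_total, Cs = 0,
            Ri = params$k_int0 * params$R_total / params$k_rec,
            Ci = 0, Ldeg = 0)
  }
  deSolve::ode(y0, times, rhs, c(unclass(params), L = L),
               method = "lsoda", rtol = 1e-10, atol = 1e-8)
}

# eigenfunction series for no-flux diffusion on [0, L], evaluated at voxel
# centers, from a unit impulse in voxel i0 (1-based)
series_profile_1d <- function(n_vox, dx, D, t, i0, n_terms = 300) {
  L <- n_vox * dx
  x <- (seq_len(n_vox) - 0.5) * dx
  x0 <- (i0 - 0.5) * dx
  s <- rep(1 / L, n_vox)
  for (n in seq_len(n_terms)) {
    s <- s + (2 / L) * cos(n * pi * x / L) * cos(n * pi * x0 / L) *
      exp(-D * (n * pi / L)^2 * t)
  }
  s
}
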