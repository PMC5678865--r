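#' CXCR7 trafficking parameters
#'
#' Rate constants of the receptor-mediated scavenging subsystem run by every
#' CXCR7+ cell: surface binding, complex internalization, constitutive
#' receptor cycling, and intracellular ligand degradation. Defaults are
#' literature-informed package values, not measured constants, and are
#' overridable per cell type in the run configuration. The implied ligand
#' affinity `K_D = k_off/k_on` (0.1 nM by default) is about two orders of
#' magnitude tighter than typical CXCR4 values, the premise for neglecting
#' CXCR4-mediated uptake.
#'
#' @param k_on association rate (1/(nM s)).
#' @param k_off dissociation rate (1/s).
#' @param k_int complex internalization rate (1/s).
#' @param k_int0 constitutive receptor internalization rate (1/s).
#' @param k_rec receptor recycling rate (1/s).
#' @param k_degL internal ligand degradation rate (1/s).
#' @param R_total resting surface receptor count per cell.
#' @param q_syn receptor synthesis rate (1/s); the default 0 keeps the
#'   receptor pool exactly conserved, and the resting state is chosen so the
#'   ligand-free steady state has `R_s = R_total`.
#' @return a `trafficking_params` list.
#' @export
trafficking_params <- function(k_on = 0.1, k_off = 0.01, k_int = 0.1,
                               k_int0 = 0.001, k_rec = 0.01, k_degL = 0.05,
                               R_total = 2e5, q_syn = 0) {
  p <- list(k_on = k_on, k_off = k_off, k_int = k_int, k_int0 = k_int0,
            k_rec = k_rec, k_degL = k_degL, R_total = R_total, q_syn = q_syn)
  if (any(unlist(p) < 0)) {
    abort("trafficking rates must be >= 0", class = "cxcl12grad_config_error")
  }
  structure(p, class = "trafficking_params")
}

#' Resting trafficking state for n cells
#'
#' Cells start at the ligand-free steady state: `R_s = R_total` on the
#' surface, `R_i = k_int0 R_total / k_rec` inside, no complexes, nothing yet
#' degraded.
#'
#' @param params a `trafficking_params`.
#' @param n number of cells.
#' @return numeric matrix, one row per cell, columns `R_s, C_s, R_i, C_i,
#'   L_degraded` (receptor/molecule counts).
#' @export
trafficking_state <- function(params, n = 1L) {
  Ri <- if (params$k_rec > 0) params$k_int0 * params$R_total / params$k_rec else 0
  m <- matrix(rep(c(params$R_total, 0, Ri, 0, 0), each = max(n, 1)),
              nrow = max(n, 1), ncol = 5)[seq_len(n), , drop = FALSE]
  colnames(m) <- c("R_s", "C_s", "R_i", "C_i", "L_degraded")
  m
}

#' Advance the per-cell trafficking ODEs one transport step
#'
#' The local ligand concentration (free + ECM-bound of the cell's voxel) is
#' held constant over `dt` while the linear trafficking system is advanced
#' by classical RK4 with substeps bounded by the fastest rate. The net
#' ligand removed from the voxel (binding minus release, in nM through the
#' voxel volume) is clipped at the available amount so a cell can never
#' drive its compartment negative.
#'
#' @param state trafficking state matrix (rows = cells), as from
#'   [trafficking_state()].
#' @param L_local local ligand concentration(s), nM (free + bound); length 1
#'   or `nrow(state)`.
#' @param params a `trafficking_params`.
#' @param dt timestep (s), at most the transport timestep.
#' @param volume_l voxel volume (L) for the count <-> nM bridge.
#' @return list with `state` (updated matrix) and `dL_nM` (per-cell ligand
#'   removed from the voxel, nM; clipped at `L_local`).
#' @export
step_trafficking <- function(state, L_local, params, dt, volume_l = 1e-12) {
  if (any(L_local < 0) || any(state < 0)) {
    abort("negative ligand or receptor state", class = "cxcl12grad_state_error")
  }
  L <- rep_len(L_local, nrow(state))
  res <- cpp_trafficking_step(state, L, unclass(params), dt)
  colnames(res$state) <- colnames(state)
  dL <- res$uptake_counts / molecules_per_nM(volume_l)
  clip <- dL > L
  if (any(clip)) {
    warn(sprintf("uptake clipped to available ligand for %d cell(s)",
                 sum(clip)))
    dL[clip] <- L[clip]
  }
  list(state = res$state, dL_nM = dL)
}

#' Split ligand removal between the free and ECM-bound pools
#'
#' CXCR7+ cells bind free and ECM-bound chemokine with the same parameters,
#' so removal is pro rata to the two pools.
#'
#' @param dL amount removed (nM, >= 0 expected).
#' @param free,bound current pool concentrations (nM).
#' @return list with `d_free` and `d_bound` (amounts to subtract).
#' @export
uptake_partition <- function(dL, free, bound) {
  tot <- free + bound
  avail <- pmin(dL, tot)
  if (any(dL > tot + 1e-12)) {
    warn("requested uptake exceeds available ligand; clipped")
  }
  frac <- ifelse(tot > 0, free / tot, 0)
  list(d_free = avail * frac, d_bound = avail * (1 - frac))
}
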