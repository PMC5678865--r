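# Internal simulation driver shared by the two experiment setups: builds
# geometry + placements from a config and advances the fused C++ loop in
# chunks, accumulating records and mass-balance totals.

derive_seed <- function(master, offset) {
  as.integer((as.double(master) * 100003 + offset) %% 2147483647)
}

new_simulation <- function(config, seed, setup = c("setup2", "setup1")) {
  setup <- match.arg(setup)
  grid <- build_grid(config$grid$side_length, config$grid$voxel_size)
  iso <- active_isoform(config)

  vessel <- NULL
  placements <- list()
  if (setup == "setup2") {
    if (isTRUE(config$vessel$enabled)) {
      vessel <- place_vessel(grid, config$vessel$cross_section_area,
                             config$vessel$axis)
    }
    occupied <- integer()
    if (!is.null(vessel) && config$cells$n_endothelial > 0) {
      endo <- seed_endothelial(grid, vessel, config$cells$n_endothelial,
                               seed = derive_seed(seed, 1))
      placements$endothelial <- endo
      occupied <- endo$voxel
    }
    sec <- seed_cells_random(grid, config$cells$n_secreting, "secreting",
                             seed = derive_seed(seed, 2), vessel = vessel,
                             occupied = occupied)
    occupied <- c(occupied, sec$voxel)
    sca <- seed_cells_random(grid, config$cells$n_scavenging, "cxcr7_tissue",
                             seed = derive_seed(seed, 3), vessel = vessel,
                             occupied = occupied)
    placements$secreting <- sec
    placements$scavenging <- sca
  } else {
    half_sep <- config$clusters$separation / 2
    mid <- grid$side_length / 2
    c_src <- c(mid - half_sep, mid, mid)
    c_snk <- c(mid + half_sep, mid, mid)
    sec <- seed_cluster(grid, c_src, config$clusters$n_secreting,
                        "secreting", seed = derive_seed(seed, 2),
                        extent = config$clusters$extent)
    sca <- seed_cluster(grid, c_snk, config$clusters$n_scavenging,
                        "cxcr7_tissue", seed = derive_seed(seed, 3),
                        extent = config$clusters$extent)
    placements$secreting <- sec
    placements$scavenging <- sca
  }

  scav_all <- dplyr::bind_rows(placements[c("scavenging", "endothelial")])
  tpar <- do.call(trafficking_params, config$trafficking)
  scav_state <- trafficking_state(tpar, nrow(scav_all))

  # record sets
  sets <- list()
  if (setup == "setup2" && !is.null(vessel)) {
    sh <- vessel_shells(grid, vessel)
    names(sh) <- paste0("shell_", names(sh))
    sets <- sh
  } else if (setup == "setup1") {
    sets <- setup1_faces(grid, config)
  }

  exch <- if (!is.null(vessel)) vessel$exchange else
    tibble(voxel = integer(), area_um2 = numeric())

  list(
    config = config, setup = setup, seed = seed,
    grid = grid, vessel = vessel, placements = placements, iso = iso,
    tpar = tpar, scav_vox = scav_all$voxel, scav_state = scav_state,
    exch = exch, record_sets = sets,
    free = array(0, grid$dims), bound = array(0, grid$dims),
    time_s = 0,
    cums = c(secreted = 0, degraded = 0, scavenged = 0, exchanged = 0),
    clip_events = 0,
    records = NULL
  )
}

# Inner faces of the two Setup-1 cluster cubes (the planes facing each
# other), used as the endpoints of the inter-cluster gradient.
setup1_faces <- function(grid, config) {
  w <- as.integer(round(config$clusters$extent / grid$voxel_size))
  half_sep <- config$clusters$separation / 2
  mid <- grid$side_length / 2
  lo_src <- round((mid - half_sep) / grid$voxel_size - w / 2) + 1L
  lo_snk <- round((mid + half_sep) / grid$voxel_size - w / 2) + 1L
  lo_yz <- round(mid / grid$voxel_size - w / 2) + 1L
  yz <- lo_yz:(lo_yz + w - 1L)
  gg <- expand.grid(j = yz, k = yz)
  list(
    face_source = voxel_index(grid, rep(lo_src + w - 1L, nrow(gg)), gg$j, gg$k),
    face_sink = voxel_index(grid, rep(lo_snk, nrow(gg)), gg$j, gg$k)
  )
}

# Advance the simulation `n_steps` transport steps.
# S_mode / Cb_mode: 0 = frozen at t_start value, 1 = circadian, 2 = constant
# mean; Cb_mode ignored when there is no vessel.
advance_sim <- function(sim, n_steps, S_mode, Cb_mode,
                        record_every = NULL, t0_s = NULL) {
  cfg <- sim$config
  grid <- sim$grid
  iso <- sim$iso
  circ <- cfg$circadian
  dt <- cfg$transport$dt
  if (is.null(record_every)) {
    record_every <- max(1L, as.integer(round(cfg$schedule$record_every_s / dt)))
  }
  if (!is.null(t0_s)) sim$time_s <- t0_s
  lam <- cfg$transport$D * dt / grid$voxel_size^2
  fold_to_range <- function(mean, fold) {
    c(max = 2 * mean * fold / (fold + 1), min = 2 * mean / (fold + 1))
  }
  Sr <- fold_to_range(iso$S, circ$fold_secretion)
  Cr <- fold_to_range(iso$blood_mean, circ$fold_blood)
  phase0 <- if (identical(circ$convention, "printed")) {
    circ$t_start - circ$t_max
  } else {
    circ$t_max - circ$t_start
  }
  vmask <- vessel_mask(grid, sim$vessel)
  secr_vox <- sim$placements$secreting$voxel

  res <- cpp_run_sim(
    sim$free, sim$bound, grid$dims, vmask, lam, dt,
    cfg$transport$k_deg, iso$k_on_ecm, iso$K_p,
    as.integer(secr_vox - 1L),
    Sr[["max"]], Sr[["min"]], as.integer(S_mode),
    as.integer(sim$scav_vox - 1L), sim$scav_state, unclass(sim$tpar),
    molecules_per_nM(grid$voxel_volume_l),
    as.integer(sim$exch$voxel - 1L), sim$exch$area_um2, cfg$exchange$p,
    grid$voxel_volume_um3,
    Cr[["max"]], Cr[["min"]], as.integer(Cb_mode),
    circ$f, phase0, circ$t_start,
    sim$time_s, as.integer(n_steps), as.integer(record_every),
    lapply(unname(sim$record_sets), function(v) as.integer(v - 1L))
  )
  sim$free <- res$free
  sim$bound <- res$bound
  sim$scav_state <- res$scav_state
  sim$time_s <- res$time_s
  sim$cums <- sim$cums + c(secreted = res$cum_secreted,
                           degraded = res$cum_degraded,
                           scavenged = res$cum_scavenged,
                           exchanged = res$cum_exchanged)
  sim$clip_events <- sim$clip_events + res$clip_events
  rec <- res$records
  if (nrow(rec) > 0) {
    colnames(rec) <- c("time_h", "c_blood", "S",
                       names(sim$record_sets), "mass_free", "mass_bound",
                       "clip_events")
    rec <- as_tibble(as.data.frame(rec))
    sim$records <- dplyr::bind_rows(sim$records, rec)
  }
  sim
}

# Audit: initial + secreted + exchanged - degraded - scavenged = current
# grid total, in nM-voxel units (exact up to round-off).
mass_balance <- function(sim, initial_total = 0) {
  current <- sum(sim$free) + sum(sim$bound)
  expected <- initial_total + sim$cums[["secreted"]] +
    sim$cums[["exchanged"]] - sim$cums[["degraded"]] -
    sim$cums[["scavenged"]]
  tibble(current = current, expected = expected,
         abs_error = abs(current - expected),
         rel_error = abs(current - expected) / max(abs(expected), 1e-300))
}

sim_state <- function(sim) {
  grid_state(sim$grid, sim$free, sim$bound, sim$time_s)
}
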