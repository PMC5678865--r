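#' Cluster experiment: isoform-specific cell-derived gradients
#'
#' A cluster of CXCL12-secreting cells and a cluster of CXCR7+ cells
#' (default 100 cells each, confined to 60-um cubes 100 um apart) secrete
#' and scavenge in a vessel-free, non-circadian grid. The run advances
#' until the inter-cluster gradient is steady (excursion below
#' `schedule$setup1$steady_threshold` nM/um over a trailing
#' `steady_window_min` window) or `max_time_h` elapses.
#'
#' @param config a [sim_config()]; the `clusters`, `transport`, active
#'   isoform and `schedule$setup1` blocks drive the run.
#' @param seed placement seed (default `config$seed`).
#' @return a `setup1_result` with `$gradient` (tibble `time_h`, `value`
#'   nM/um between the facing cluster faces), `$total` (tibble `time_h`,
#'   `total_nM_voxels`), `$time_to_steady_h` (NA when not converged),
#'   `$converged`, `$final_gradient`, `$placements`, `$config`.
#' @export
run_setup1 <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  sim <- new_simulation(config, seed, "setup1")
  sch <- config$schedule$setup1
  dt <- config$transport$dt
  chunk_steps <- max(1L, as.integer(round(sch$steady_window_min * 60 / dt)))
  max_steps <- as.integer(round(sch$max_time_h * 3600 / dt))
  steady_at <- NA_real_
  done <- 0L
  while (done < max_steps) {
    n <- min(chunk_steps, max_steps - done)
    sim <- advance_sim(sim, n, S_mode = 2, Cb_mode = 2)
    done <- done + n
    hist <- setup1_gradient(sim)
    steady_at <- detect_steady_state(hist, sch$steady_threshold,
                                     sch$steady_window_min)
    if (!is.na(steady_at)) break
  }
  hist <- setup1_gradient(sim)
  structure(
    list(
      gradient = hist,
      total = tibble(time_h = sim$records$time_h,
                     total_nM_voxels = sim$records$mass_free +
                       sim$records$mass_bound),
      time_to_steady_h = steady_at,
      converged = !is.na(steady_at),
      final_gradient = hist$value[nrow(hist)],
      mass_balance = mass_balance(sim),
      placements = dplyr::bind_rows(sim$placements),
      isoform = config$isoform,
      config = config
    ),
    class = "setup1_result"
  )
}

setup1_gradient <- function(sim) {
  r <- sim$records
  sep <- sim$config$clusters$separation
  tibble(time_h = r$time_h,
         value = (r$face_source - r$face_sink) / sep)
}

#' Vascularized tumor section under circadian forcing
#'
#' Stage 1 initializes the field with secretion, transport, scavenging and
#' transvascular delivery held at their clock-start values until the
#' blood-tissue gradient is steady (relative excursion below
#' `schedule$setup2$stage1_rel_tol` over a 5-min window). Stage 2 then runs
#' `stage2_hours` of simulated time with the circadian cosine forcing both
#' the secretion rate and the blood concentration in phase.
#'
#' Gradient conventions: positive = CXCL12 higher in tissue than blood
#' (gradient points into the tissue). `blood_tissue` compares the mean
#' tissue concentration at `metrics$blood_radius_um` against the blood;
#' `endothelial_tissue` compares the tissue shell at `metrics$far_shell_um`
#' against the shell at `metrics$near_shell_um` (the compartments abutting
#' the vessel wall).
#'
#' @param config a [sim_config()].
#' @param seed placement seed (default `config$seed`).
#' @return a `setup2_result` with `$gradients` (tibble `time_h`, `metric`,
#'   `value_nM_per_um`, `sign`, stage-2 only), `$profiles` (radial mean
#'   total concentration at the time of the maximum endothelial-tissue
#'   gradient and at the end of stage 2), `$stage1_hours`,
#'   `$stage1_converged`, `$records` (raw shell means), `$placements`,
#'   `$config`.
#' @export
run_setup2 <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  sim <- new_simulation(config, seed, "setup2")
  if (is.null(sim$vessel)) {
    abort("setup 2 requires vessel$enabled = TRUE",
          class = "cxcl12grad_config_error")
  }
  sch <- config$schedule$setup2
  dt <- config$transport$dt
  shell_d <- as.numeric(sub("^shell_", "", names(sim$record_sets)))
  near_um <- clamp_shell(config$metrics$near_shell_um, shell_d)
  far_um <- clamp_shell(config$metrics$far_shell_um, shell_d)
  radius_um <- clamp_shell(config$metrics$blood_radius_um, shell_d)

  # stage 1: frozen forcing, run to quasi-steady blood-tissue gradient
  chunk_steps <- max(1L, as.integer(round(sch$stage1_window_min * 60 / dt)))
  max_steps <- as.integer(round(sch$stage1_max_h * 3600 / dt))
  steady_at <- NA_real_
  done <- 0L
  while (done < max_steps) {
    n <- min(chunk_steps, max_steps - done)
    sim <- advance_sim(sim, n, S_mode = 0, Cb_mode = 0)
    done <- done + n
    g <- setup2_gradients(sim, near_um, far_um, radius_um)
    bt <- g[g$metric == "blood_tissue", c("time_h", "value")]
    names(bt) <- c("time_h", "value")
    steady_at <- detect_steady_state(bt, sch$stage1_rel_tol,
                                     sch$stage1_window_min, relative = TRUE)
    if (!is.na(steady_at)) break
  }
  stage1_hours <- sim$time_s / 3600
  sim$records <- NULL # stage-2 records only

  # stage 2: circadian forcing of secretion and blood, clock starts t_start
  n2 <- as.integer(round(sch$stage2_hours * 3600 / dt))
  sim <- advance_sim(sim, n2, S_mode = 1, Cb_mode = 1,
                     t0_s = config$circadian$t_start * 3600)
  grads <- setup2_gradients(sim, near_um, far_um, radius_um)
  grads$sign <- sign(grads$value_nM_per_um)

  # radial profiles at the strongest endothelial-tissue gradient and at end
  et <- grads[grads$metric == "endothelial_tissue", ]
  t_max_g <- et$time_h[which.max(abs(et$value_nM_per_um))]
  prof <- dplyr::bind_rows(
    profile_at(sim, t_max_g, shell_d, "max_endothelial_gradient"),
    profile_at(sim, max(sim$records$time_h), shell_d, "end_of_run")
  )

  structure(
    list(
      gradients = grads,
      profiles = prof,
      stage1_hours = stage1_hours,
      stage1_converged = !is.na(steady_at),
      records = sim$records,
      mass_balance = mass_balance(sim),
      placements = dplyr::bind_rows(sim$placements),
      isoform = config$isoform,
      shells_um = shell_d,
      config = config
    ),
    class = "setup2_result"
  )
}

clamp_shell <- function(req, avail) {
  if (req %in% avail) return(req)
  out <- avail[which.min(abs(avail - req))]
  warn(sprintf("shell at %g um unavailable on this grid; using %g um",
               req, out))
  out
}

setup2_gradients <- function(sim, near_um, far_um, radius_um) {
  r <- sim$records
  near <- r[[paste0("shell_", near_um)]]
  far <- r[[paste0("shell_", far_um)]]
  at_r <- r[[paste0("shell_", radius_um)]]
  dplyr::bind_rows(
    tibble(time_h = r$time_h, metric = "blood_tissue",
           value_nM_per_um = (at_r - r$c_blood) / radius_um,
           value = (at_r - r$c_blood) / radius_um),
    tibble(time_h = r$time_h, metric = "endothelial_tissue",
           value_nM_per_um = (far - near) / (far_um - near_um),
           value = (far - near) / (far_um - near_um))
  )
}

profile_at <- function(sim, t_h, shell_d, label) {
  row <- sim$records[which.min(abs(sim$records$time_h - t_h)), ]
  tibble(distance_um = shell_d,
         total_nM = as.numeric(row[paste0("shell_", shell_d)]),
         time_h = row$time_h, at = label)
}

#' Replicate-averaged cell-composition sweep
#'
#' Runs the vascularized experiment over a grid of secreting x scavenging
#' cell counts, `replicates` independent placements per cell, and reports
#' the signed maximum-magnitude blood-tissue gradient over the circadian
#' stage, averaged across replicates. Replicate seeds fan out from the
#' master seed by a counter scheme, so results are reproducible and
#' replicate k does not depend on the others having run.
#'
#' @param config a [sim_config()].
#' @param n_secreting,n_scavenging count axes (defaults
#'   `c(25, 50, ..., 200)`).
#' @param replicates placements per composition (default 5).
#' @param seed master seed.
#' @return a `sweep_result`: `$summary` (tibble `n_secreting`,
#'   `n_scavenging`, `value` = replicate-mean signed max gradient,
#'   `abs_mean`, `exact_zero`), `$replicates` (per-replicate values),
#'   `$config`.
#' @export
sweep_composition <- function(config = sim_config(),
                              n_secreting = seq(25, 200, by = 25),
                              n_scavenging = seq(25, 200, by = 25),
                              replicates = 5, seed = config$seed) {
  stopifnot(length(n_secreting) >= 1, length(n_scavenging) >= 1,
            replicates >= 1)
  cells <- tidyr::expand_grid(n_secreting = n_secreting,
                              n_scavenging = n_scavenging)
  reps <- tidyr::expand_grid(cells, replicate = seq_len(replicates))
  run_one <- function(ns, nc, rep_i, idx) {
    cfg <- modify_deep(config, list(cells = list(n_secreting = ns,
                                                 n_scavenging = nc)))
    cfg <- validate_config(cfg)
    res <- run_setup2(cfg, seed = derive_seed(seed, 1000 * idx + rep_i))
    bt <- res$gradients[res$gradients$metric == "blood_tissue", ]
    bt$value_nM_per_um[which.max(abs(bt$value_nM_per_um))]
  }
  idx <- match(paste(reps$n_secreting, reps$n_scavenging),
               paste(cells$n_secreting, cells$n_scavenging))
  reps$value <- purrr::pmap_dbl(
    list(reps$n_secreting, reps$n_scavenging, reps$replicate, idx), run_one)
  summary <- reps |>
    dplyr::group_by(.data$n_secreting, .data$n_scavenging) |>
    dplyr::summarise(abs_mean = mean(abs(.data$value)),
                     exact_zero = all(.data$value == 0),
                     value = mean(.data$value),
                     .groups = "drop") |>
    dplyr::select("n_secreting", "n_scavenging", "value", "abs_mean",
                  "exact_zero")
  structure(list(summary = summary, replicates = reps, config = config,
                 isoform = config$isoform, seed = seed),
            class = "sweep_result")
}
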