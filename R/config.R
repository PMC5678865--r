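#' Default simulation configuration
#'
#' Nested configuration for the two experiment drivers. All kinetic and
#' transport magnitudes are literature-informed package defaults
#' (config-overridable); the structural values (10-um voxels, 200-um cube,
#' 400-um^2 vessel, 0.1-s transport step, 2-fold circadian variation,
#' baseline 200 cells of each type, clusters of 100 cells 100 um apart)
#' are the canonical study conditions.
#'
#' @param ... named overrides, nested lists merged over the defaults, e.g.
#'   `sim_config(grid = list(side_length = 100), transport = list(dt = 0.5))`.
#' @return a validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(isoform = "gamma")
#' cfg$isoforms$gamma$K_p
sim_config <- function(...) {
  defaults <- list(
    grid = list(side_length = 200, voxel_size = 10),
    vessel = list(enabled = TRUE, cross_section_area = 400, axis = "z"),
    isoform = "alpha",
    isoforms = list(
      alpha = isoform_params("alpha")[-1],
      beta = isoform_params("beta")[-1],
      gamma = isoform_params("gamma")[-1]
    ),
    transport = list(D = 150, k_deg = 1e-4, dt = 0.1),
    trafficking = unclass(trafficking_params()),
    cells = list(n_secreting = 200, n_scavenging = 200, n_endothelial = 200),
    clusters = list(extent = 60, separation = 100,
                    n_secreting = 100, n_scavenging = 100),
    circadian = list(fold_secretion = 2, fold_blood = 2, f = 1 / 24,
                     t_start = 9, t_max = 9, convention = "printed"),
    exchange = list(p = 0.1),
    schedule = list(
      record_every_s = 10,
      setup1 = list(steady_threshold = 0.1, steady_window_min = 5,
                    max_time_h = 6),
      setup2 = list(stage1_rel_tol = 0.01, stage1_window_min = 5,
                    stage1_max_h = 6, stage2_hours = 24)
    ),
    metrics = list(near_shell_um = 10, far_shell_um = 90,
                   blood_radius_um = 90),
    seed = 1L
  )
  cfg <- modify_deep(defaults, list(...))
  validate_config(cfg)
}

modify_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- modify_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  fail <- function(field, msg) {
    abort(sprintf("config field `%s`: %s", field, msg),
          class = "cxcl12grad_config_error")
  }
  nonneg <- function(field) {
    v <- cfg
    for (p in strsplit(field, "$", fixed = TRUE)[[1]]) v <- v[[p]]
    if (is.null(v) || !is.numeric(v) || any(v < 0)) {
      fail(field, "must be a non-negative number")
    }
  }
  for (f in c("transport$D", "transport$k_deg", "transport$dt",
              "exchange$p", "circadian$f",
              "cells$n_secreting", "cells$n_scavenging",
              "cells$n_endothelial",
              "clusters$n_secreting", "clusters$n_scavenging")) nonneg(f)
  for (iso in c("alpha", "beta", "gamma")) {
    for (f in c("S", "K_p", "k_on_ecm", "blood_mean")) {
      nonneg(paste0("isoforms$", iso, "$", f))
    }
  }
  for (f in names(cfg$trafficking)) nonneg(paste0("trafficking$", f))
  if (cfg$transport$dt <= 0) fail("transport$dt", "must be > 0")
  if (!cfg$isoform %in% c("alpha", "beta", "gamma")) {
    fail("isoform", "must be one of alpha, beta, gamma")
  }
  if (cfg$circadian$fold_secretion < 1 || cfg$circadian$fold_blood < 1) {
    fail("circadian$fold_*", "fold change must be >= 1")
  }
  structure(cfg, class = "sim_config")
}

#' Load / save a run configuration (YAML)
#'
#' Missing fields are filled from [sim_config()] defaults; an empty file
#' yields the full default configuration. Schema violations are reported
#' with their field path. Save/load round-trips exactly.
#'
#' @param path YAML file path.
#' @param quiet suppress the note about literature-informed defaults.
#' @return a validated `sim_config`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "cxcl12grad_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- do.call(sim_config, raw)
  if (!quiet) {
    message("cxcl12grad: kinetic magnitudes not set in the file use ",
            "literature-informed non-paper defaults")
  }
  cfg
}

#' @rdname load_config
#' @param config a `sim_config` to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

# parameters of the active isoform
active_isoform <- function(config) {
  c(list(isoform = config$isoform), config$isoforms[[config$isoform]])
}
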