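#' Build the cubic simulation lattice
#'
#' The tissue is discretized into cubic voxels of side `voxel_size`; each
#' voxel holds at most one cell. The default is a 200-um cube of 10-um
#' voxels (20^3 = 8000 compartments, total volume 8e-3 mm^3).
#'
#' @param side_length cube side length in um; must be a positive integer
#'   multiple of `voxel_size`.
#' @param voxel_size voxel side length in um (default 10, one cell diameter).
#' @return a `cxcl_grid` object with fields `side_length`, `voxel_size`,
#'   `dims` (voxels per axis), `n_voxels`, `voxel_volume_l` and
#'   `volume_mm3`.
#' @export
#' @examples
#' g <- build_grid(200, 10)
#' g$dims       # 20 20 20
#' g$volume_mm3 # 0.008
build_grid <- function(side_length = 200, voxel_size = 10) {
  if (!is.numeric(side_length) || !is.numeric(voxel_size) ||
      side_length <= 0 || voxel_size <= 0) {
    abort("side_length and voxel_size must be positive numbers",
          class = "cxcl12grad_config_error")
  }
  n <- side_length / voxel_size
  if (abs(n - round(n)) > 1e-9) {
    abort("side_length must be an integer multiple of voxel_size",
          class = "cxcl12grad_config_error")
  }
  n <- as.integer(round(n))
  structure(
    list(
      side_length = side_length,
      voxel_size = voxel_size,
      dims = c(n, n, n),
      n_voxels = n * n * n,
      voxel_volume_l = (voxel_size * 1e-6 * 1e2)^3 / 1e3, # um^3 -> L
      voxel_volume_um3 = voxel_size^3,
      volume_mm3 = (side_length / 1e3)^3
    ),
    class = "cxcl_grid"
  )
}

#' @export
print.cxcl_grid <- function(x, ...) {
  cat(sprintf("<cxcl_grid> %g-um cube, %d^3 voxels of %g um (%g mm^3)\n",
              x$side_length, x$dims[1], x$voxel_size, x$volume_mm3))
  invisible(x)
}

#' Convert between voxel coordinates and linear indices
#'
#' Voxels are addressed either by 1-based integer coordinates `(i, j, k)`
#' or by the 1-based linear index into the field arrays (`i` fastest).
#'
#' @param grid a `cxcl_grid`.
#' @param i,j,k integer coordinates (vectorized).
#' @param voxel linear indices (vectorized).
#' @return `voxel_index` returns linear indices; `voxel_coords` a tibble
#'   with `voxel`, `i`, `j`, `k`.
#' @export
voxel_index <- function(grid, i, j, k) {
  d <- grid$dims
  stopifnot(all(i >= 1 & i <= d[1]), all(j >= 1 & j <= d[2]),
            all(k >= 1 & k <= d[3]))
  as.integer(i + d[1] * (j - 1) + d[1] * d[2] * (k - 1))
}

#' @rdname voxel_index
#' @export
voxel_coords <- function(grid, voxel) {
  d <- grid$dims
  v0 <- as.integer(voxel) - 1L
  tibble(
    voxel = as.integer(voxel),
    i = v0 %% d[1] + 1L,
    j = (v0 %/% d[1]) %% d[2] + 1L,
    k = v0 %/% (d[1] * d[2]) + 1L
  )
}

#' Embed the central blood vessel
#'
#' The vessel is a rectangular prism spanning the full grid along `axis`,
#' realized as a centered k-by-k block of voxels in the cross-section
#' (400 um^2 with 10-um voxels gives k = 2). The lining is the one-voxel
#' shell around the cross-section on every layer, including diagonal
#' (corner) neighbours: 4k + 4 voxels per layer, i.e. 240 voxels for the
#' default geometry. When the block does not center exactly it is floored
#' toward the origin.
#'
#' @param grid a `cxcl_grid`.
#' @param cross_section_area vessel cross-sectional area in um^2; must be a
#'   perfect k x k voxel block.
#' @param axis one of `"x"`, `"y"`, `"z"` (vessel long axis).
#' @return a `cxcl_vessel` with `vessel_voxels`, `lining_voxels` (1-based
#'   linear indices), `k`, `axis`, and `exchange` (tibble of lining voxels
#'   sharing at least one face with the vessel, with total shared face area
#'   in um^2).
#' @export
place_vessel <- function(grid, cross_section_area = 400, axis = "z") {
  stopifnot(inherits(grid, "cxcl_grid"))
  axis <- match.arg(axis, c("x", "y", "z"))
  k <- sqrt(cross_section_area) / grid$voxel_size
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    abort("cross_section_area must correspond to an integer k x k voxel block",
          class = "cxcl12grad_config_error")
  }
  k <- as.integer(round(k))
  d <- grid$dims
  ax <- match(axis, c("x", "y", "z"))
  cross <- setdiff(1:3, ax)
  if (k + 2L > min(d[cross])) {
    abort("vessel (plus lining) does not fit in the grid",
          class = "cxcl12grad_config_error")
  }
  # centered block, floored toward the origin
  lo <- floor((d[cross] - k) / 2) + 1L
  r1 <- lo[1]:(lo[1] + k - 1L) # cross axis 1
  r2 <- lo[2]:(lo[2] + k - 1L) # cross axis 2
  s1 <- max(1L, lo[1] - 1L):min(d[cross[1]], lo[1] + k)
  s2 <- max(1L, lo[2] - 1L):min(d[cross[2]], lo[2] + k)

  along <- seq_len(d[ax])
  expand_idx <- function(a, b) {
    gg <- expand.grid(c1 = a, c2 = b, al = along)
    co <- list()
    co[[cross[1]]] <- gg$c1
    co[[cross[2]]] <- gg$c2
    co[[ax]] <- gg$al
    voxel_index(grid, co[[1]], co[[2]], co[[3]])
  }
  vessel_voxels <- sort(expand_idx(r1, r2))
  shell_all <- expand_idx(s1, s2)
  lining_voxels <- sort(setdiff(shell_all, vessel_voxels))

  # shared faces: lining voxels offset by exactly one step along one cross
  # axis from a vessel voxel share one 10x10 face per such neighbour
  co <- voxel_coords(grid, lining_voxels)
  cc <- cbind(co$i, co$j, co$k)
  n_faces <- integer(nrow(cc))
  for (ca in cross) {
    other <- setdiff(cross, ca)
    rng_ca <- if (ca == cross[1]) r1 else r2
    rng_other <- if (other == cross[1]) r1 else r2
    adj <- (cc[, ca] == min(rng_ca) - 1L | cc[, ca] == max(rng_ca) + 1L) &
      (cc[, other] >= min(rng_other) & cc[, other] <= max(rng_other))
    n_faces <- n_faces + as.integer(adj)
  }
  exchange <- tibble(voxel = lining_voxels, n_faces = n_faces,
                     area_um2 = n_faces * grid$voxel_size^2)
  exchange <- exchange[exchange$n_faces > 0L, ]

  structure(
    list(
      k = k, axis = axis, cross_section_area = cross_section_area,
      vessel_voxels = vessel_voxels, lining_voxels = lining_voxels,
      exchange = exchange
    ),
    class = "cxcl_vessel"
  )
}

#' @export
print.cxcl_vessel <- function(x, ...) {
  cat(sprintf(
    "<cxcl_vessel> %dx%d block along %s: %d vessel voxels, %d lining voxels\n",
    x$k, x$k, x$axis, length(x$vessel_voxels), length(x$lining_voxels)))
  invisible(x)
}

new_placements <- function(grid, voxels, cell_type) {
  co <- voxel_coords(grid, voxels)
  tibble(cell_type = rep(cell_type, length(voxels)),
         voxel = as.integer(voxels), i = co$i, j = co$j, k = co$k)
}

#' Seed cells uniformly at random over admissible voxels
#'
#' Samples `n` distinct empty tissue voxels (never inside the vessel, never
#' on an occupied voxel) uniformly without replacement. Reproducible for a
#' fixed seed.
#'
#' @param grid a `cxcl_grid`.
#' @param n number of cells.
#' @param cell_type `"secreting"`, `"cxcr7_tissue"` or `"cxcr7_endothelial"`.
#' @param seed integer RNG seed.
#' @param vessel optional `cxcl_vessel`; its voxels are excluded.
#' @param occupied integer vector of already-occupied voxel indices.
#' @return a placements tibble (`cell_type`, `voxel`, `i`, `j`, `k`).
#' @export
seed_cells_random <- function(grid, n, cell_type = c("secreting",
                              "cxcr7_tissue", "cxcr7_endothelial"),
                              seed = 1L, vessel = NULL,
                              occupied = integer()) {
  stopifnot(inherits(grid, "cxcl_grid"), n >= 0)
  cell_type <- match.arg(cell_type)
  excl <- unique(c(occupied, if (!is.null(vessel)) vessel$vessel_voxels))
  admissible <- setdiff(seq_len(grid$n_voxels), excl)
  if (n > length(admissible)) {
    abort(sprintf("cannot place %d cells on %d admissible voxels",
                  n, length(admissible)),
          class = "cxcl12grad_capacity_error")
  }
  if (n == 0) return(new_placements(grid, integer(), cell_type))
  vox <- withr::with_seed(seed, sample(admissible, n))
  new_placements(grid, sort(vox), cell_type)
}

#' Seed a confined cell cluster
#'
#' Places `n_cells` cells at random voxels inside a cubic region of side
#' `extent` centered at `center_um` (defaults to six cell diameters,
#' 60 um, i.e. a 6^3 = 216 voxel capacity).
#'
#' @param grid a `cxcl_grid`.
#' @param center_um numeric length-3, cluster center in um.
#' @param n_cells number of cells (must fit in the cube).
#' @param cell_type as in [seed_cells_random()].
#' @param seed integer RNG seed.
#' @param extent cluster cube side in um.
#' @param occupied voxels to avoid.
#' @return a placements tibble.
#' @export
seed_cluster <- function(grid, center_um, n_cells,
                         cell_type = c("secreting", "cxcr7_tissue"),
                         seed = 1L, extent = 60, occupied = integer()) {
  stopifnot(inherits(grid, "cxcl_grid"), length(center_um) == 3, n_cells >= 0)
  cell_type <- match.arg(cell_type)
  w <- extent / grid$voxel_size
  if (abs(w - round(w)) > 1e-9) {
    abort("extent must be an integer multiple of voxel_size",
          class = "cxcl12grad_config_error")
  }
  w <- as.integer(round(w))
  lo <- round(center_um / grid$voxel_size - w / 2) + 1L
  hi <- lo + w - 1L
  if (any(lo < 1L) || any(hi > grid$dims)) {
    abort("cluster cube extends outside the grid",
          class = "cxcl12grad_config_error")
  }
  gg <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  vox <- setdiff(voxel_index(grid, gg$i, gg$j, gg$k), occupied)
  if (n_cells > length(vox)) {
    abort(sprintf("cluster holds at most %d cells, requested %d",
                  length(vox), n_cells),
          class = "cxcl12grad_capacity_error")
  }
  if (n_cells == 0) return(new_placements(grid, integer(), cell_type))
  sel <- withr::with_seed(seed, sample(vox, n_cells))
  new_placements(grid, sort(sel), cell_type)
}

#' Seed endothelial CXCR7+ cells on the vessel lining
#'
#' Endothelial scavenger cells occupy lining-shell voxels only. When `n` is
#' below the lining capacity the occupied voxels are sampled uniformly at
#' random; coverage is reported as n / |lining|.
#'
#' @param grid a `cxcl_grid`.
#' @param vessel a `cxcl_vessel`.
#' @param n number of endothelial cells (<= lining voxels).
#' @param seed integer RNG seed.
#' @return placements tibble with attribute `coverage` (fraction).
#' @export
seed_endothelial <- function(grid, vessel, n, seed = 1L) {
  stopifnot(inherits(vessel, "cxcl_vessel"), n >= 0)
  lin <- vessel$lining_voxels
  if (n > length(lin)) {
    abort(sprintf("lining holds at most %d endothelial cells", length(lin)),
          class = "cxcl12grad_capacity_error")
  }
  vox <- if (n == length(lin)) lin else
    withr::with_seed(seed, sample(lin, n))
  out <- new_placements(grid, sort(vox), "cxcr7_endothelial")
  attr(out, "coverage") <- n / length(lin)
  out
}

#' Write / read cell placements
#'
#' One row per cell: `cell_type, voxel, i, j, k` as plain CSV; round-trips
#' exactly.
#'
#' @param placements a placements tibble.
#' @param path file path.
#' @return `read_placements` returns the placements tibble.
#' @export
write_placements <- function(placements, path) {
  readr::write_csv(placements, path)
  invisible(path)
}

#' @rdname write_placements
#' @export
read_placements <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    cell_type = readr::col_character(), voxel = readr::col_integer(),
    i = readr::col_integer(), j = readr::col_integer(),
    k = readr::col_integer()))
}
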