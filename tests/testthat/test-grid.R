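test_that("grid construction gives correct dimensions, volume and errors", {
  g <- build_grid(200, 10)
  expect_identical(g$dims, c(20L, 20L, 20L))
  expect_identical(g$n_voxels, 8000L)
  expect_equal(g$volume_mm3, 8e-3)
  expect_equal(g$voxel_volume_l, 1e-12)

  g1 <- build_grid(10, 10)
  expect_identical(g1$dims, c(1L, 1L, 1L))

  expect_error(build_grid(195, 10), class = "cxcl12grad_config_error")
  expect_error(build_grid(-200, 10), class = "cxcl12grad_config_error")
  expect_error(build_grid(200, 0), class = "cxcl12grad_config_error")
})

test_that("voxel index and coordinates are inverse maps", {
  g <- build_grid(100, 10)
  v <- voxel_index(g, c(1L, 10L, 3L), c(1L, 10L, 7L), c(1L, 10L, 2L))
  co <- voxel_coords(g, v)
  expect_identical(co$i, c(1L, 10L, 3L))
  expect_identical(co$j, c(1L, 10L, 7L))
  expect_identical(co$k, c(1L, 10L, 2L))
  expect_error(voxel_index(g, 11, 1, 1))
})

test_that("vessel embedding matches the 2x2 block and 12-voxel shell", {
  g <- build_grid(200, 10)
  v <- place_vessel(g, 400, "z")
  expect_length(v$vessel_voxels, 80)     # 2x2x20
  expect_length(v$lining_voxels, 240)    # 12 per layer x 20
  expect_length(intersect(v$vessel_voxels, v$lining_voxels), 0)
  # 200 endothelial cells on 240 lining voxels = 83% coverage
  expect_equal(200 / length(v$lining_voxels), 0.8333, tolerance = 1e-3)
  # face-sharing lining voxels: 8 per layer, one 100-um^2 face each
  expect_equal(nrow(v$exchange), 160)
  expect_true(all(v$exchange$area_um2 == 100))
  # vessel spans the full axis
  co <- voxel_coords(g, v$vessel_voxels)
  expect_setequal(unique(co$k), 1:20)
  expect_error(place_vessel(g, 350), class = "cxcl12grad_config_error")
})

test_that("vessel and lining counts are invariant under the axis choice", {
  g <- build_grid(200, 10)
  counts <- vapply(c("x", "y", "z"), function(a) {
    v <- place_vessel(g, 400, a)
    c(length(v$vessel_voxels), length(v$lining_voxels), nrow(v$exchange))
  }, numeric(3))
  expect_true(all(counts[1, ] == 80))
  expect_true(all(counts[2, ] == 240))
  expect_true(all(counts[3, ] == 160))
})

test_that("random seeding is reproducible, exclusive and capacity-checked", {
  g <- build_grid(100, 10)
  v <- place_vessel(g, 400, "z")
  p1 <- seed_cells_random(g, 50, "secreting", seed = 7, vessel = v)
  p2 <- seed_cells_random(g, 50, "secreting", seed = 7, vessel = v)
  expect_identical(p1, p2)
  expect_length(intersect(p1$voxel, v$vessel_voxels), 0)

  p3 <- seed_cells_random(g, 50, "cxcr7_tissue", seed = 8, vessel = v,
                          occupied = p1$voxel)
  expect_length(intersect(p3$voxel, p1$voxel), 0)
  # no double occupancy: unique voxels equal total cells placed
  expect_length(unique(c(p1$voxel, p3$voxel)), 100)

  expect_identical(nrow(seed_cells_random(g, 0, "secreting")), 0L)
  n_adm <- g$n_voxels - length(v$vessel_voxels)
  expect_error(seed_cells_random(g, n_adm + 1, "secreting", vessel = v),
               class = "cxcl12grad_capacity_error")
})

test_that("cluster seeding fills, confines and caps at cube capacity", {
  g <- build_grid(200, 10)
  full <- seed_cluster(g, c(50, 100, 100), 216, "secreting", seed = 1)
  expect_identical(nrow(full), 216L)
  expect_length(unique(full$voxel), 216)
  expect_error(seed_cluster(g, c(50, 100, 100), 217, "secreting"),
               class = "cxcl12grad_capacity_error")

  p <- seed_cluster(g, c(150, 100, 100), 100, "cxcr7_tissue", seed = 3)
  expect_identical(nrow(p), 100L)
  # all inside the 60-um bounding cube centered at (150,100,100)
  expect_true(all(p$i >= 13 & p$i <= 18))
  expect_true(all(p$j >= 8 & p$j <= 13))
  expect_true(all(p$k >= 8 & p$k <= 13))

  # default source/sink cluster centroids sit 100 um apart
  src <- seed_cluster(g, c(50, 100, 100), 216, "secreting", seed = 1)
  snk <- seed_cluster(g, c(150, 100, 100), 216, "cxcr7_tissue", seed = 1)
  centroid <- function(p) colMeans((cbind(p$i, p$j, p$k) - 0.5) * 10)
  expect_equal(sqrt(sum((centroid(src) - centroid(snk))^2)), 100)
})

test_that("endothelial cells sit on the lining and report coverage", {
  g <- build_grid(200, 10)
  v <- place_vessel(g)
  e <- seed_endothelial(g, v, 200, seed = 2)
  expect_true(all(e$voxel %in% v$lining_voxels))
  expect_equal(attr(e, "coverage"), 200 / 240)
  expect_error(seed_endothelial(g, v, 241),
               class = "cxcl12grad_capacity_error")
})

test_that("placements round-trip through CSV", {
  g <- build_grid(100, 10)
  p <- seed_cells_random(g, 20, "secreting", seed = 1)
  path <- tempfile(fileext = ".csv")
  write_placements(p, path)
  expect_equal(as.data.frame(read_placements(path)), as.data.frame(p))
})
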