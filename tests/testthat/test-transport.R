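test_that("secretion converts molecules to nM through the voxel volume", {
  g <- build_grid(50, 10)
  st <- grid_state(g)
  p <- tibble::tibble(cell_type = "secreting",
                      voxel = voxel_index(g, 3L, 3L, 3L),
                      i = 3L, j = 3L, k = 3L)
  # 602 molecules into a 1-pL voxel is 1.0 nM
  st2 <- secrete(st, p, S = 602, dt = 1, grid = g)
  expect_equal(st2$free[p$voxel], 1.0, tolerance = 1e-3)
  expect_equal(sum(st2$free) - st2$free[p$voxel], 0)

  expect_identical(secrete(st, p[0, ], 10, 0.1, g), st)
  expect_identical(secrete(st, p, 0, 0.1, g), st)
  expect_error(secrete(st, p, -1, 0.1, g), class = "cxcl12grad_config_error")
})

test_that("diffusion conserves mass, fixes uniform fields and respects extrema", {
  g <- build_grid(100, 10)
  st <- grid_state(g)
  st$free[] <- 0.7
  st2 <- diffuse(st, g, D = 150, dt = 0.1)
  expect_equal(st2$free, st$free, tolerance = 1e-12)

  st$free[] <- 0
  st$free[voxel_index(g, 5L, 5L, 5L)] <- 10
  m0 <- sum(st$free)
  st3 <- diffuse(st, g, D = 150, dt = 0.1, n_steps = 1000)
  expect_lt(abs(sum(st3$free) - m0) / m0, 1e-9)
  expect_true(all(st3$free >= -1e-12))
  expect_lt(max(st3$free), 10)
})

test_that("point impulse matches the no-flux eigenfunction series", {
  g <- build_grid(200, 10)
  st <- grid_state(g)
  st$free[voxel_index(g, 10L, 10L, 10L)] <- 1
  st <- diffuse(st, g, D = 150, dt = 0.1, n_steps = 100) # t = 10 s
  gx <- series_profile_1d(20, 10, 150, 10, 10)
  ana <- outer(outer(gx, gx), gx)
  ana <- ana / sum(ana)
  num <- st$free / sum(st$free)
  l2 <- sqrt(sum((num - ana)^2) / sum(ana^2))
  expect_lt(l2, 0.01)
})

test_that("degradation halves free in one half-life and spares bound", {
  g <- build_grid(50, 10)
  st <- grid_state(g)
  st$free[] <- 2
  st$bound[] <- 3
  k <- 1e-3
  st2 <- degrade(st, k, log(2) / k)
  expect_equal(st2$free, st$free / 2)
  expect_identical(st2$bound, st$bound)
  expect_identical(degrade(st, 0, 100)$free, st$free)
})

test_that("ECM exchange conserves voxel totals and relaxes to B/F = K_p", {
  g <- build_grid(50, 10)
  st <- grid_state(g)
  st$free[] <- 0.4
  st$bound[] <- 0.1
  ecm <- list(k_on_ecm = 0.1, K_p = 25)
  st2 <- ecm_exchange(st, ecm, 2000)
  expect_equal(st2$free + st2$bound, st$free + st$bound, tolerance = 1e-12)
  expect_equal(st2$bound[1] / st2$free[1], 25, tolerance = 1e-3)

  # higher K_p at equal total -> larger bound fraction
  st_a <- ecm_exchange(st, list(k_on_ecm = 0.1, K_p = 1), 2000)
  expect_lt(st_a$bound[1], st2$bound[1])

  # empty state unchanged
  st0 <- grid_state(g)
  expect_identical(ecm_exchange(st0, ecm, 10)$bound, st0$bound)
})

test_that("total concentration sums pools and validates the voxel", {
  g <- build_grid(50, 10)
  st <- grid_state(g)
  v <- voxel_index(g, 2L, 2L, 2L)
  st$free[v] <- 0.3
  st$bound[v] <- 0.1
  expect_equal(total_concentration(st, v), 0.4)
  expect_equal(total_concentration(grid_state(g), v), 0)
  expect_error(total_concentration(st, g$n_voxels + 1),
               class = "cxcl12grad_state_error")
  # exchange leaves the total untouched
  st2 <- ecm_exchange(st, list(k_on_ecm = 0.1, K_p = 5), 50)
  expect_equal(total_concentration(st2, v), 0.4)
})

test_that("ECM binding slows effective spreading monotonically in K_p", {
  g <- build_grid(100, 10)
  spread <- function(kp) {
    st <- grid_state(g)
    st$free[voxel_index(g, 5L, 5L, 5L)] <- 100
    ecm <- list(k_on_ecm = 0.5, K_p = kp)
    for (i in 1:200) {
      st <- diffuse(st, g, D = 150, dt = 0.1)
      st <- ecm_exchange(st, ecm, 0.1)
    }
    tot <- st$free + st$bound
    co <- voxel_coords(g, seq_len(g$n_voxels))
    w <- tot / sum(tot)
    mu <- c(sum(w * co$i), sum(w * co$j), sum(w * co$k))
    sum(w * ((co$i - mu[1])^2 + (co$j - mu[2])^2 + (co$k - mu[3])^2))
  }
  v <- vapply(c(0.5, 2, 10), spread, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("diffusion and degradation nearly commute (operator splitting)", {
  g <- build_grid(100, 10)
  st <- grid_state(g)
  st$free[voxel_index(g, 3L, 7L, 5L)] <- 5
  k <- 0.01
  a <- b <- st
  for (i in 1:50) {
    a <- degrade(diffuse(a, g, 150, 0.1), k, 0.1)
    b <- diffuse(degrade(b, k, 0.1), g, 150, 0.1)
  }
  expect_equal(a$free, b$free, tolerance = 1e-10)
})

test_that("closed-system mass is constant and secretion adds exactly S dt", {
  cfg <- tiny_setup2(cells = list(n_secreting = 10, n_scavenging = 0,
                                  n_endothelial = 0),
                     vessel = list(enabled = TRUE))
  sim <- cxcl12grad:::new_simulation(cfg, seed = 1, setup = "setup2")
  sim$exch <- sim$exch[0, ]          # sever the vessel source
  sim <- cxcl12grad:::advance_sim(sim, 1000, S_mode = 2, Cb_mode = 2)
  mb <- cxcl12grad:::mass_balance(sim)
  expect_lt(mb$rel_error, 1e-9)
  # with degradation also off, growth is exactly n_cells * S * dt per step
  cfg2 <- tiny_setup2(cells = list(n_secreting = 10, n_scavenging = 0,
                                   n_endothelial = 0),
                      transport = list(k_deg = 0))
  sim2 <- cxcl12grad:::new_simulation(cfg2, seed = 1, setup = "setup2")
  sim2$exch <- sim2$exch[0, ]
  sim2 <- cxcl12grad:::advance_sim(sim2, 500, S_mode = 2, Cb_mode = 2)
  S <- cfg2$isoforms$alpha$S
  expected <- 10 * S * 0.5 * 500 / molecules_per_nM(1e-12)
  expect_equal(sum(sim2$free) + sum(sim2$bound), expected, tolerance = 1e-9)
})
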