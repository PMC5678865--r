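test_that("circadian cosine hits its maximum, mean and fold change", {
  p <- circadian_params(x_max = 2, x_min = 1, f = 1 / 24, t_start = 9,
                        t_max = 9)
  # printed phase: cosine argument zero at t = t_start - t_max
  expect_equal(circadian_value(p$t_start - p$t_max, p), 2)
  # constant when x_max = x_min
  pc <- circadian_params(1.5, 1.5)
  expect_equal(circadian_value(seq(0, 48, by = 0.5), pc),
               rep(1.5, 97))
  # mean over one full period is (x_max + x_min)/2
  tt <- seq(0, 24, length.out = 10001)[-10001]
  expect_equal(mean(circadian_value(tt, p)), 1.5, tolerance = 1e-6)
  # 2-fold variation when x_max = 2 x_min
  expect_equal(max(circadian_value(tt, p)) / min(circadian_value(tt, p)), 2,
               tolerance = 1e-6)
  # periodic with period 1/f
  expect_equal(circadian_value(tt, p), circadian_value(tt + 24, p),
               tolerance = 1e-12)
})

test_that("phase conventions mirror each other around t_start", {
  pr <- circadian_params(2, 1, t_start = 3, t_max = 9, convention = "printed")
  na <- circadian_params(2, 1, t_start = 3, t_max = 9, convention = "natural")
  expect_equal(circadian_value(3 - 9, pr), 2)
  expect_equal(circadian_value(9 - 3, na), 2)
})

test_that("circadian_from_mean reproduces the requested mean and fold", {
  p <- circadian_from_mean(0.25, fold = 2)
  expect_equal((p$x_max + p$x_min) / 2, 0.25)
  expect_equal(p$x_max / p$x_min, 2)
  expect_error(circadian_params(1, 2), class = "cxcl12grad_config_error")
})

test_that("vessel exchange has the right sign, zero and linearity", {
  expect_equal(vessel_exchange(0.5, 0.5, 0.1, 100, 0.1), 0)
  expect_gt(vessel_exchange(0.5, 0.1, 0.1, 100, 0.1), 0)
  expect_lt(vessel_exchange(0.1, 0.5, 0.1, 100, 0.1), 0)
  expect_equal(vessel_exchange(0.5, 0.1, 0.2, 100, 0.1),
               2 * vessel_exchange(0.5, 0.1, 0.1, 100, 0.1))
})

test_that("vessel boundary condition moves mass with the driving force", {
  g <- build_grid(100, 10)
  v <- place_vessel(g)
  st <- grid_state(g)
  st$free[] <- 0.2
  # blood at zero drains the lining compartments
  st2 <- apply_vessel_bc(st, v, g, c_blood = 0, p = 0.1, dt = 0.1)
  expect_lt(sum(st2$free), sum(st$free))
  # uniform tissue at the blood level: no flux anywhere
  st3 <- apply_vessel_bc(st, v, g, c_blood = 0.2, p = 0.1, dt = 0.1)
  expect_equal(st3$free, st$free)
  # delivery when blood exceeds tissue, confined to exchange voxels
  st4 <- apply_vessel_bc(st, v, g, c_blood = 1, p = 0.1, dt = 0.1)
  changed <- which(st4$free != st$free)
  expect_setequal(changed, v$exchange$voxel)
  expect_true(all(st4$free[changed] > 0.2))
})

test_that("steady vessel-fed profile matches the 1D diffusion-degradation form", {
  # quasi-1D: hold the x = 1 plane at C0, diffuse + degrade to steady state;
  # the analytic no-flux profile is C0 cosh((L - x)/l)/cosh(L/l), l = sqrt(D/k)
  g <- build_grid(200, 10)
  D <- 50; k <- 0.005; C0 <- 1
  st <- grid_state(g)
  for (i in 1:4000) {
    st$free[1, , ] <- C0
    st <- degrade(diffuse(st, g, D, 0.5), k, 0.5)
  }
  st$free[1, , ] <- C0
  prof <- vapply(1:20, function(i) mean(st$free[i, , ]), numeric(1))
  x <- (1:20 - 1) * 10     # distance from the held plane's center
  l <- sqrt(D / k)
  ana <- C0 * cosh((190 - x) / l) / cosh(190 / l)
  expect_true(all(diff(prof) < 0))
  expect_equal(prof / prof[1], ana / ana[1], tolerance = 0.05)
})

test_that("radial concentration decays monotonically from a source vessel", {
  cfg <- tiny_setup2(cells = list(n_secreting = 0, n_scavenging = 0,
                                  n_endothelial = 0))
  sim <- cxcl12grad:::new_simulation(cfg, seed = 1, setup = "setup2")
  sim <- cxcl12grad:::advance_sim(sim, 7200, S_mode = 2, Cb_mode = 2)
  st <- cxcl12grad:::sim_state(sim)
  prof <- radial_profile(st, sim$grid, sim$vessel)
  expect_true(all(diff(prof$total_nM) < 0))
})
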