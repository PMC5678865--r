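test_that("cluster run with no secreting cells gives zero gradient and mass", {
  cfg <- tiny_setup1(clusters = list(n_secreting = 0),
                     schedule = list(setup1 = list(max_time_h = 0.5)))
  r <- run_setup1(cfg, seed = 1)
  expect_true(r$converged)
  expect_equal(r$final_gradient, 0)
  expect_equal(max(r$total$total_nM_voxels), 0)
})

test_that("cluster run produces a forming gradient with tidy accessors", {
  cfg <- tiny_setup1(schedule = list(setup1 = list(
    steady_threshold = 1e-4, max_time_h = 1)))
  r <- run_setup1(cfg, seed = 1)
  expect_s3_class(r, "setup1_result")
  expect_gt(r$final_gradient, 0)        # source side is the high side
  expect_lt(r$mass_balance$rel_error, 1e-9)
  td <- tidy(r)
  expect_true(all(c("time_h", "value", "metric", "isoform") %in% names(td)))
  gl <- glance(r)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$final_gradient_nM_per_um, r$final_gradient)
  expect_s3_class(autoplot(r), "ggplot")
  # gradient history is non-decreasing while the plume forms
  expect_true(all(diff(td$value) > -1e-9))
})

test_that("vascularized run is silent with all sources off", {
  cfg <- tiny_setup2(
    cells = list(n_secreting = 0, n_scavenging = 0, n_endothelial = 0),
    isoforms = list(alpha = list(blood_mean = 0)),
    schedule = list(setup2 = list(stage2_hours = 0.5)))
  r <- run_setup2(cfg, seed = 1)
  expect_equal(max(abs(r$gradients$value_nM_per_um)), 0)
  expect_equal(max(r$profiles$total_nM), 0)
})

test_that("vascularized run reports both gradient metrics and profiles", {
  cfg <- tiny_setup2(schedule = list(setup2 = list(stage2_hours = 0.5)))
  r <- run_setup2(cfg, seed = 2)
  expect_s3_class(r, "setup2_result")
  expect_setequal(unique(r$gradients$metric),
                  c("blood_tissue", "endothelial_tissue"))
  expect_equal(r$gradients$sign, sign(r$gradients$value_nM_per_um))
  # radial profiles start at the first tissue compartment, 10 um out
  expect_equal(min(r$profiles$distance_um), 10)
  expect_lt(r$mass_balance$rel_error, 1e-8)
  expect_s3_class(autoplot(r), "ggplot")
  gl <- glance(r)
  expect_true(is.logical(gl$sign_constant))
})

test_that("composition sweep is reproducible and consistent with single runs", {
  cfg <- tiny_setup2(schedule = list(setup2 = list(stage2_hours = 0.5)))
  sw1 <- sweep_composition(cfg, n_secreting = 10, n_scavenging = c(5, 20),
                           replicates = 1, seed = 3)
  sw2 <- sweep_composition(cfg, n_secreting = 10, n_scavenging = c(5, 20),
                           replicates = 1, seed = 3)
  expect_identical(sw1$summary, sw2$summary)
  expect_identical(nrow(sw1$summary), 2L)

  # a 1x1 sweep equals the matching single run's signed max gradient
  sw <- sweep_composition(cfg, n_secreting = 10, n_scavenging = 5,
                          replicates = 1, seed = 3)
  cfg1 <- cxcl12grad:::modify_deep(cfg, list(cells = list(
    n_secreting = 10, n_scavenging = 5)))
  cfg1 <- cxcl12grad:::validate_config(cfg1)
  r <- run_setup2(cfg1, seed = cxcl12grad:::derive_seed(3, 1001))
  bt <- r$gradients[r$gradients$metric == "blood_tissue", ]
  expect_equal(sw$summary$value,
               bt$value_nM_per_um[which.max(abs(bt$value_nM_per_um))])
  expect_s3_class(autoplot(sw), "ggplot")
  expect_false(any(sw$summary$exact_zero))
})
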