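test_that("identical seeds give bit-identical stacks and cohorts", {
  specs <- default_layer_specs()
  g <- small_geometry()
  s1 <- generate_surface_stack(specs, seed = 101, geometry = g)
  s2 <- generate_surface_stack(specs, seed = 101, geometry = g)
  expect_identical(s1$surfaces, s2$surfaces)
  expect_identical(s1$truth, s2$truth)
  spec <- cohort_spec(n_ad = 3, n_ctl = 3, seed = 7)
  c1 <- generate_cohort(spec, specs, g)
  c2 <- generate_cohort(spec, specs, g)
  expect_identical(lapply(c1$stacks, `[[`, "surfaces"),
                   lapply(c2$stacks, `[[`, "surfaces"))
  expect_identical(c1$covariates, c2$covariates)
})

test_that("surfaces never cross across many seeds", {
  specs <- default_layer_specs()
  g <- scan_geometry(24, 24, 11.7, 46.9)
  for (seed in 1:100) {
    st <- generate_surface_stack(specs, seed = seed, geometry = g,
                                 subject_roughness = runif(10, -8, 8))
    for (k in 1:10)
      expect_true(all(st$surfaces[[k + 1]] >= st$surfaces[[k]] - 1e-9))
  }
})

test_that("zero amplitude with flat bases gives constant maps and fd exactly 2", {
  specs <- lapply(default_layer_specs(amplitude = 0), function(s) {
    s$pit_depth_frac <- 0; s
  })
  st <- generate_surface_stack(specs, seed = 11, geometry = small_geometry())
  maps <- subject_roi_maps(st, small_params())
  fds <- vapply(maps, function(m) fractal_dimension(m)$fd, 0)
  expect_identical(unname(fds), rep(2, 10))
  # thickness maps equal the base profiles (up to cumulative-sum round-off)
  expect_equal(raw_thickness(st, 6)$values, matrix(75, 48, 48),
               tolerance = 1e-12)
})

test_that("amplitude on one layer raises only that layer above its smooth baseline", {
  flat0 <- lapply(default_layer_specs(amplitude = 0), function(s) {
    s$pit_depth_frac <- 0; s
  })
  perturbed <- flat0
  perturbed[[1]]$amplitude <- 10
  g <- scan_geometry(96, 96, 11.7, 11.7)
  p <- norm_params(roi_side = 64 * 11.7 / 1000)
  st0 <- generate_surface_stack(flat0, seed = 11, geometry = g)
  st1 <- generate_surface_stack(perturbed, seed = 11, geometry = g)
  # raw thickness of layers 2..10 is untouched by construction
  for (k in 2:10)
    expect_equal(raw_thickness(st1, k)$values, raw_thickness(st0, k)$values,
                 tolerance = 1e-9)
  # on raw maps, only layer 1 departs from the smooth limit
  roi_raw_fd <- function(st, k) {
    tr <- similarity_transform(st$fovea_rc, st$papilla_rc, st$geometry, p)
    fractal_dimension(central_roi(resample(raw_thickness(st, k), tr, p), p))$fd
  }
  raw_fds <- vapply(1:10, function(k) roi_raw_fd(st1, k), 0)
  expect_gt(raw_fds[1], 2.05)
  expect_true(all(abs(raw_fds[-1] - 2) < 1e-9))
  # after the cosine correction, deeper constant layers drape over the
  # rough substrate and inherit tilt-induced roughness, so independence
  # holds only for raw maps; the perturbed layer itself still rises
  ortho_fds <- vapply(subject_roi_maps(st1, p),
                      function(m) fractal_dimension(m)$fd, 0)
  expect_gt(ortho_fds[1], 2.05)
})

test_that("foveal pit thins the inner layers toward the center", {
  st <- generate_surface_stack(default_layer_specs(amplitude = 0), seed = 1,
                               geometry = small_geometry())
  center <- c(24, 24); edge <- c(24, 2)
  for (k in 1:6) {
    v <- raw_thickness(st, k)$values
    expect_lt(v[center[1], center[2]], v[edge[1], edge[2]])
  }
  for (k in 7:10) {
    v <- raw_thickness(st, k)$values
    expect_equal(v[center[1], center[2]], v[edge[1], edge[2]],
                 tolerance = 1e-9)
  }
})

test_that("cohort covariates carry the predicted signed associations", {
  spec <- cohort_spec(n_ad = 150, n_ctl = 150, group_roughness_effect = 0,
                      subject_noise_sd = 0.2, seed = 42)
  co <- generate_cohort(spec, default_layer_specs(loading_scale = 3),
                        small_geometry())
  rho <- co$truth$rho
  expect_lt(cor(rho, co$covariates$mmse), -0.2)
  expect_lt(cor(rho, co$covariates$visual_acuity), -0.2)
  expect_gt(cor(rho, co$covariates$age), 0.2)
  # MMSE respects the group-specific clinical ranges
  ad <- co$covariates$group == "AD"
  expect_true(all(co$covariates$mmse[ad] >= 17 & co$covariates$mmse[ad] <= 29))
  expect_true(all(co$covariates$mmse[!ad] >= 25 & co$covariates$mmse[!ad] <= 31))
  expect_lt(mean(co$covariates$mmse[ad]), mean(co$covariates$mmse[!ad]))
})

test_that("amplitude offsets implement the latent two-factor group model", {
  spec <- cohort_spec(n_ad = 50, n_ctl = 50, group_roughness_effect = 2,
                      subject_noise_sd = 0, seed = 9)
  specs <- default_layer_specs(loading_scale = 2)
  co <- generate_cohort(spec, specs, small_geometry())
  tr <- co$truth
  l1 <- tr$loading_f1; l2 <- tr$loading_f2
  expected <- outer(tr$F1, l1) + outer(tr$F2, l2) +
    ifelse(co$covariates$group == "AD", 2, 0)
  expect_equal(tr$offsets, expected, tolerance = 1e-12)
  # realized amplitudes floored at zero
  amps <- t(vapply(co$stacks, function(s) s$truth$amplitudes, numeric(10)))
  expect_true(all(amps >= 0))
  expect_equal(unname(amps[1, ]),
               pmax(0, 10 + unname(tr$offsets[1, ])), tolerance = 1e-12)
})

test_that("null cohorts have group mean-FD difference centered on zero", {
  diffs <- vapply(1:12, function(i) {
    tab <- cohort_fd_table(cohort_spec(n_ad = 8, n_ctl = 8,
                                       group_roughness_effect = 0,
                                       seed = 300 + i))
    mean(tab$mean_fd_10[tab$group == "AD"]) -
      mean(tab$mean_fd_10[tab$group == "CTL"])
  }, 0)
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)) + 1e-4)
})

test_that("spec validation rejects out-of-domain parameters", {
  expect_error(synthetic_layer_spec(1, 20, hurst = 1.2), "hurst")
  expect_error(synthetic_layer_spec(1, 20, amplitude = -1), "amplitude")
  expect_error(synthetic_layer_spec(1, -5), "nonnegative")
  expect_error(cohort_spec(n_ad = 1), "at least 2")
  expect_error(generate_surface_stack(default_layer_specs()[1:3], seed = 1),
               "10 layer specs")
})
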