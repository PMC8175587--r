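test_that("canonical landmarks give the exact identity transform", {
  g <- small_geometry()
  st <- generate_surface_stack(default_layer_specs(), seed = 1, geometry = g)
  tr <- similarity_transform(st$fovea_rc, st$papilla_rc, g, small_params())
  expect_identical(tr$a, 1 + 0i)
  expect_identical(tr$b, 0 + 0i)
})

test_that("axis length twice the target gives scale factor one half", {
  g <- scan_geometry(128, 512)        # anisotropic scanner grid
  p <- norm_params()
  fovea <- c(63.5, 255.5)
  tilt <- p$target_axis_tilt * pi / 180
  papilla <- fovea + c(2 * 4377 * sin(tilt) / g$pixel_pitch_y,
                       2 * 4377 * cos(tilt) / g$pixel_pitch_x)
  tr <- similarity_transform(fovea, papilla, g, p)
  expect_equal(Mod(tr$a), 0.5, tolerance = 1e-12)
  expect_equal(Arg(tr$a), 0, tolerance = 1e-12)
})

test_that("fitted similarity maps random landmark pairs onto targets to < 1e-6 mm", {
  g <- scan_geometry(128, 512)
  p <- norm_params()
  set.seed(31)
  for (i in 1:25) {
    fovea <- c(runif(1, 30, 90), runif(1, 150, 350))
    papilla <- fovea + c(runif(1, -40, 40), runif(1, 100, 400))
    tr <- similarity_transform(fovea, papilla, g, p)
    f_out <- transform_point(tr, fovea, g)
    p_out <- transform_point(tr, papilla, g)
    center <- tr$fovea_out_rc
    tilt <- p$target_axis_tilt * pi / 180
    target <- center + 4377 * c(sin(tilt), cos(tilt)) / tr$output_pitch
    expect_lt(max(abs(f_out - center)) * tr$output_pitch, 1e-3)   # um
    expect_lt(max(abs(p_out - target)) * tr$output_pitch, 1e-3)
  }
  expect_error(similarity_transform(fovea, fovea, g, p), "degenerate")
})

test_that("resampling a constant map yields the same constant", {
  g <- scan_geometry(64, 96)          # anisotropic input
  p <- norm_params()
  m <- thickness_map(matrix(10, 64, 96), 2, g)
  fovea <- c(31.5, 47.5)
  tilt <- p$target_axis_tilt * pi / 180
  papilla <- fovea + c(4000 * sin(tilt) / g$pixel_pitch_y,
                       4000 * cos(tilt) / g$pixel_pitch_x)
  tr <- similarity_transform(fovea, papilla, g, p)
  out <- resample(m, tr, p)
  expect_true(out$normalized)
  expect_equal(out$geometry$pixel_pitch_x, out$geometry$pixel_pitch_y)
  vals <- out$values[out$valid_mask]
  expect_equal(vals, rep(10, length(vals)), tolerance = 1e-12)
})

test_that("identity transform on an isotropic map leaves values unchanged", {
  g <- small_geometry()
  st <- generate_surface_stack(default_layer_specs(), seed = 2, geometry = g)
  m <- raw_thickness(st, 6)
  tr <- similarity_transform(st$fovea_rc, st$papilla_rc, g, small_params())
  out <- resample(m, tr, small_params())
  expect_identical(out$values, m$values)
})

test_that("pure rotation barely changes a radially symmetric map", {
  g <- scan_geometry(128, 128, 11.7, 11.7)
  p <- norm_params(roi_side = 0.6)
  fovea <- c(63.5, 63.5)
  r2 <- outer(((0:127) - 63.5)^2, ((0:127) - 63.5)^2, `+`) * 11.7^2
  m <- thickness_map(50 + 30 * exp(-r2 / (2 * 300^2)), 1, g)
  tilt <- p$target_axis_tilt * pi / 180
  # papilla rotated 25 degrees away from canonical: transform is a pure
  # rotation by 25 degrees (distance at target length)
  ang <- tilt + 25 * pi / 180
  papilla <- fovea + 4377 * c(sin(ang), cos(ang)) / 11.7
  tr <- similarity_transform(fovea, papilla, g, p)
  expect_equal(Mod(tr$a), 1, tolerance = 1e-9)
  out <- resample(m, tr, p)
  roi_out <- central_roi(out, p)
  roi_in <- central_roi(thickness_map(m$values, 1, g, normalized = TRUE,
                                      fovea_rc = fovea), p)
  rms <- sqrt(mean((roi_out$values - roi_in$values)^2))
  expect_lt(rms / sqrt(mean(roi_in$values^2)), 0.005)
})

test_that("ROI size, centering, and bounds errors behave as specified", {
  p <- norm_params()
  expect_equal(floor(p$roi_side * 1000 / p$output_pitch), 218)
  g <- scan_geometry(512, 512, 11.7, 11.7)
  m <- thickness_map(matrix(1, 512, 512), 1, g, normalized = TRUE,
                     fovea_rc = c(255.5, 255.5))
  roi <- central_roi(m, p)
  expect_equal(dim(roi$values), c(218L, 218L))
  # fovea pixel lands within one pixel of the ROI center
  expect_lt(abs(roi$fovea_rc[1] - (218 - 1) / 2), 1)
  expect_lt(abs(roi$fovea_rc[2] - (218 - 1) / 2), 1)
  # ROI exceeding the map is an error naming the extent
  small <- thickness_map(matrix(1, 100, 100), 1,
                         scan_geometry(100, 100, 11.7, 11.7),
                         normalized = TRUE, fovea_rc = c(49.5, 49.5))
  expect_error(central_roi(small, p), "exceeds map extent")
  expect_error(central_roi(thickness_map(matrix(1, 100, 100), 1,
                                         scan_geometry(100, 100, 11.7, 11.7)),
                           p), "normalized")
})

test_that("no invalid source pixel ever contributes to a valid output pixel", {
  g <- scan_geometry(64, 64, 11.7, 11.7)
  p <- norm_params(roi_side = 0.3)
  vals <- matrix(100, 64, 64)
  mask <- matrix(TRUE, 64, 64); mask[20:28, 30:40] <- FALSE
  vals[!mask] <- 1e6          # poison: must never leak into valid output
  m <- thickness_map(vals, 1, g, valid_mask = mask)
  fovea <- c(31.5, 31.5)
  tilt <- p$target_axis_tilt * pi / 180
  ang <- tilt + 10 * pi / 180
  papilla <- fovea + 3000 * c(sin(ang), cos(ang)) / 11.7
  tr <- similarity_transform(fovea, papilla, g, p)
  out <- resample(m, tr, p)
  expect_true(all(abs(out$values[out$valid_mask] - 100) < 1e-9))
  expect_gt(sum(!out$valid_mask), 0)
})

test_that("two subjects differing by a similarity agree after normalization", {
  # subject B is subject A's retina scanned rotated/scaled: emulate by
  # resampling A's map under a known similarity, then normalize both
  g <- scan_geometry(160, 160, 11.7, 11.7)
  p <- norm_params(roi_side = 0.5)
  # smooth-roughness anatomy: interpolation error on high-frequency relief
  # would dominate the geometric comparison
  st <- generate_surface_stack(default_layer_specs(amplitude = 3, hurst = 0.85),
                               seed = 21, geometry = g)
  mapA <- orthogonal_thickness(raw_thickness(st, 6), st)
  foveaA <- st$fovea_rc; papillaA <- st$papilla_rc
  trA <- similarity_transform(foveaA, papillaA, g, p)
  roiA <- central_roi(resample(mapA, trA, p), p)

  # B's acquisition: rotate A by 8 degrees about the fovea (scale 1)
  tilt <- p$target_axis_tilt * pi / 180
  angB <- tilt + 8 * pi / 180
  papillaB_rel <- 4377 * c(sin(angB), cos(angB)) / 11.7
  # build B's map by pulling A through the rotation
  rot <- similarity_transform(foveaA, foveaA + papillaB_rel, g,
                              norm_params(roi_side = p$roi_side))
  mapB <- resample(mapA, rot, p)      # canonical-frame image of B
  mapB$normalized <- FALSE
  trB <- similarity_transform(rot$fovea_out_rc,
                              transform_point(rot, papillaA, g),
                              mapB$geometry, p)
  roiB <- central_roi(resample(mapB, trB, p), p)

  ok <- roiA$valid_mask & roiB$valid_mask
  expect_gt(mean(ok), 0.95)
  rel_rms <- sqrt(mean((roiA$values[ok] - roiB$values[ok])^2)) /
    sqrt(mean(roiA$values[ok]^2))
  expect_lt(rel_rms, 0.01)
})
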