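test_that("gray codings behave as specified", {
  m <- flat_map(35)                              # 35 um everywhere
  enc <- encode_gray(m, "native_depth")
  expect_true(all(enc$gray == 10))               # 35 / 3.5
  expect_equal(enc$G, 256L)
  # constant map under minmax codes to all zeros
  enc2 <- encode_gray(m, "minmax_8bit")
  expect_true(all(enc2$gray == 0))
  # native coding with its absolute (floor-anchored) box grid is invariant
  # to thickness offsets spanning whole boxes: box height h = s G / M is
  # {16, 32, 64} here, so a 64-quantum offset shifts every block by an
  # integer number of boxes and counts are unchanged
  g <- scan_geometry(32, 32, 11.7, 11.7)
  set.seed(5)
  vals <- 50 + matrix(runif(32 * 32, 0, 20), 32, 32)
  m1 <- thickness_map(vals, 1, g, normalized = TRUE)
  m2 <- thickness_map(vals + 64 * 3.5, 1, g, normalized = TRUE)
  for (s in c(2, 4, 8)) {
    c1 <- dbc_count(encode_gray(m1, "native_depth")$gray, s)
    c2 <- dbc_count(encode_gray(m2, "native_depth")$gray, s)
    expect_equal(c2, c1)
  }
})

test_that("box counts match partition arithmetic on degenerate grids", {
  const8 <- matrix(7, 8, 8)
  expect_equal(dbc_count(const8, 2, algorithm = "integer_ratio_dbc"), 16)
  expect_equal(dbc_count(const8, 2, algorithm = "classic_dbc"), 16)
  # 10 x 10 grid, s = 3: integer-ratio covers all pixels with 4 blocks per
  # axis (3, 3, 3, 1); classic truncates to 3 blocks per axis
  const10 <- matrix(1, 10, 10)
  expect_equal(dbc_count(const10, 3, algorithm = "integer_ratio_dbc"), 16)
  expect_equal(dbc_count(const10, 3, algorithm = "classic_dbc"), 9)
  expect_error(dbc_count(const8, 1), "outside")
  expect_error(dbc_count(const8, 5), "outside")
})

test_that("box counts equal the brute-force enumerator on random grids", {
  set.seed(11)
  for (i in 1:60) {
    M <- sample(8:16, 1)
    gray <- matrix(sample(0:255, M * M, replace = TRUE), M, M)
    for (s in 2:(M %/% 2)) {
      expect_equal(dbc_count(gray, s, algorithm = "integer_ratio_dbc"),
                   dbc_count_oracle(gray, s, classic = FALSE))
      expect_equal(dbc_count(gray, s, algorithm = "classic_dbc"),
                   dbc_count_oracle(gray, s, classic = TRUE))
    }
  }
})

test_that("constant maps have fd exactly 2 under every configuration", {
  for (alg in c("integer_ratio_dbc", "classic_dbc"))
    for (cod in c("native_depth", "minmax_8bit")) {
      r <- fractal_dimension(flat_map(42, M = 50), box_config(alg, cod))
      expect_identical(r$fd, 2)
      expect_equal(r$r_squared, 1)
    }
})

test_that("white noise outranks its smoothed version and stays in [2, 3]", {
  g <- scan_geometry(218, 218, 11.7, 11.7)
  set.seed(13)
  noise <- matrix(runif(218^2, 0, 255), 218, 218)
  m_noise <- thickness_map(noise, 1, g, normalized = TRUE)
  smooth <- noise
  for (i in 1:4)    # separable moving-average smoothing
    smooth <- (smooth + rbind(smooth[-1, ], smooth[218, ]) +
               rbind(smooth[1, ], smooth[-218, ])) / 3
  m_smooth <- thickness_map(smooth, 1, g, normalized = TRUE)
  cfg <- box_config(coding = "minmax_8bit")
  fd_noise <- fractal_dimension(m_noise, cfg)$fd
  fd_smooth <- fractal_dimension(m_smooth, cfg)$fd
  expect_gt(fd_noise, 2.5)
  expect_gt(fd_noise, fd_smooth)
  expect_lte(fd_noise, 3)
})

test_that("fd rises with fBm amplitude and falls with hurst (native coding)", {
  g <- scan_geometry(128, 128, 11.7, 11.7)
  fd_at <- function(amp, h, seed) {
    f <- generate_fbm_field(h, 128, 128, c(11.7, 11.7), seed)
    m <- thickness_map(pmax(60 + amp * f, 0), 1, g, normalized = TRUE)
    fractal_dimension(m, box_config())$fd
  }
  amps <- c(3, 8, 20)
  fda <- sapply(amps, function(a) mean(sapply(1:4, function(s) fd_at(a, 0.3, s))))
  expect_true(all(diff(fda) > 0))
  hs <- c(0.2, 0.5, 0.8)
  fdh <- sapply(hs, function(h) mean(sapply(1:4, function(s) fd_at(10, h, s))))
  expect_true(all(diff(fdh) < 0))
})

test_that("fractal_dimension enforces its preconditions", {
  g <- scan_geometry(32, 48, 11.7, 11.7)
  expect_error(fractal_dimension(thickness_map(matrix(1, 32, 48), 1, g)),
               "square")
  gg <- scan_geometry(32, 32, 11.7, 11.7)
  mask <- matrix(TRUE, 32, 32); mask[3, 7] <- FALSE
  expect_error(
    fractal_dimension(thickness_map(matrix(1, 32, 32), 1, gg,
                                    valid_mask = mask)),
    "fully valid")
  expect_error(
    fractal_dimension(flat_map(5, M = 32),
                      box_config(scales = c(2L, 3L))),
    "3 usable scales|at least 3")
})

test_that("fd_result methods expose the log-log fit", {
  g <- scan_geometry(64, 64, 11.7, 11.7)
  f <- generate_fbm_field(0.4, 64, 64, c(11.7, 11.7), seed = 3)
  m <- thickness_map(pmax(50 + 10 * f, 0), 1, g, normalized = TRUE)
  r <- fractal_dimension(m)
  expect_s3_class(r, "fd_result")
  expect_equal(unname(coef(r)["fd"]), r$fd)
  expect_length(residuals(r), length(r$scales_used))
  expect_lt(abs(mean(residuals(r))), 1e-10)     # OLS residuals center on 0
  expect_output(print(r), "fractal dimension")
  expect_output(summary(r), "Box counts")
  expect_true(r$r_squared > 0 && r$r_squared <= 1)
})

test_that("roughness_table aggregates per-subject layer FDs and means", {
  g <- scan_geometry(32, 32, 11.7, 11.7)
  mk <- function(v) thickness_map(matrix(v, 32, 32), 1, g, normalized = TRUE)
  subj <- function(v) { out <- lapply(1:10, function(k) mk(v)); names(out) <- 1:10; out }
  tab <- roughness_table(list(s1 = subj(10), s2 = subj(20)))
  expect_equal(tab$mean_fd_10, c(2, 2))
  expect_equal(tab$mean_fd_9, c(2, 2))
  expect_true(all(tab[, paste0("fd_", 1:10)] == 2))
  # 10- vs 9-layer means differ only through the RPE term
  st <- generate_surface_stack(default_layer_specs(), seed = 14,
                               geometry = small_geometry())
  maps <- subject_roi_maps(st, small_params())
  tb <- roughness_table(list(x = maps))
  expect_equal(tb$mean_fd_10, (9 * tb$mean_fd_9 + tb$fd_10) / 10,
               tolerance = 1e-12)
  # missing layer: per-layer values kept, means flagged absent
  maps_missing <- maps[-4]
  tb2 <- roughness_table(list(x = maps_missing))
  expect_true(is.na(tb2$fd_4))
  expect_true(is.na(tb2$mean_fd_10))
  expect_false(is.na(tb2$fd_5))
})
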