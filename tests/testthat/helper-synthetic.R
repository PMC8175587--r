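# Shared fixtures and independent oracles used across test files.

# Reduced study conditions for replicate-heavy simulations: isotropic
# 48 x 48 grid (11.7 um pitch), 40 px central ROI.
small_geometry <- function() scan_geometry(48, 48, 11.7, 11.7)
small_params <- function() norm_params(roi_side = 40 * 11.7 / 1000)

# One subject through every spatial stage; returns named ROI maps.
subject_roi_maps <- function(stack, params, layers = 1:10, total = FALSE) {
  tr <- similarity_transform(stack$fovea_rc, stack$papilla_rc,
                             stack$geometry, params)
  out <- lapply(layers, function(k)
    central_roi(resample(orthogonal_thickness(raw_thickness(stack, k), stack),
                         tr, params), params))
  names(out) <- as.character(layers)
  if (total)
    out$total <- central_roi(resample(
      orthogonal_thickness(raw_thickness(stack, 0), stack), tr, params),
      params)
  out
}

# Full cohort -> FD table with covariates at the given conditions.
cohort_fd_table <- function(spec, layer_specs = default_layer_specs(),
                            geometry = small_geometry(),
                            params = small_params(),
                            config = box_config()) {
  co <- generate_cohort(spec, layer_specs, geometry)
  maps <- lapply(co$stacks, subject_roi_maps, params = params)
  tab <- roughness_table(maps, config)
  merge(tab, co$covariates, by = "subject_id", sort = FALSE)
}

# Brute-force differential box-count enumerator, written independently of
# the package kernel: explicit loops over block origins.
dbc_count_oracle <- function(gray, s, G = 256, classic = FALSE) {
  M <- nrow(gray)
  h <- s * G / M
  limit <- if (classic) M - M %% s else M
  total <- 0
  r0 <- 1
  while (r0 <= limit) {
    r1 <- min(r0 + s - 1, limit)
    c0 <- 1
    while (c0 <= limit) {
      c1 <- min(c0 + s - 1, limit)
      blk <- gray[r0:r1, c0:c1]
      total <- total + (floor(max(blk) / h) - floor(min(blk) / h) + 1)
      c0 <- c0 + s
    }
    r0 <- r0 + s
  }
  total
}

# Full-enumeration Mann-Whitney oracle: exact p over all choose(n, n1)
# group labelings of the pooled sample (mid-ranks for ties).
mw_oracle <- function(x, y, alternative) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n, n1)
  Ws <- apply(sets, 2, function(idx) sum(r[idx]))
  switch(alternative,
         greater = mean(Ws >= W_obs - 1e-9),
         less = mean(Ws <= W_obs + 1e-9),
         two.sided = min(1, 2 * min(mean(Ws >= W_obs - 1e-9),
                                    mean(Ws <= W_obs + 1e-9))))
}

flat_map <- function(value, M = 32, layer = 1L) {
  g <- scan_geometry(M, M, 11.7, 11.7)
  thickness_map(matrix(value, M, M), layer, g, normalized = TRUE)
}
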