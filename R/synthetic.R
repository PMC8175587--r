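# Synthetic macular cohorts with known ground-truth roughness.  Layer
# thickness = smooth radial base profile (foveal pit on the inner layers)
# plus an amplitude-scaled fractional Brownian perturbation of known Hurst
# exponent; surfaces are built by cumulative summation from the inner
# limiting membrane, which enforces non-crossing structurally.

#' Specification of one synthetic retinal layer
#'
#' @param layer_index Layer 1..10 (NFL .. RPE).
#' @param base_thickness Peripheral thickness of the smooth base profile,
#'   um.
#' @param pit_depth_frac Fraction (0..1) of `base_thickness` removed at the
#'   foveal center; the foveal pit is a radial Gaussian depression applied
#'   to the inner layers only.
#' @param pit_sigma_mm Radial scale of the pit, mm.
#' @param hurst Hurst exponent of the rough perturbation, in (0, 1);
#'   theoretical surface FD of the perturbation alone is `3 - hurst`.
#' @param amplitude RMS of the rough perturbation, um (>= 0).
#' @param loading_f1,loading_f2 Latent-factor loadings: um of extra
#'   amplitude per unit factor score, defining the two-block structure
#'   across layers.
#' @return Object of class `synthetic_layer_spec`.
#' @export
synthetic_layer_spec <- function(layer_index, base_thickness,
                                 pit_depth_frac = 0, pit_sigma_mm = 0.4,
                                 hurst = 0.5, amplitude = 4,
                                 loading_f1 = 0, loading_f2 = 0) {
  layer_index <- as.integer(layer_index)
  stopifnot(layer_index >= 1L, layer_index <= 10L)
  if (hurst <= 0 || hurst >= 1) stop_domain("hurst must be in (0, 1)")
  if (amplitude < 0) stop_domain("amplitude must be >= 0")
  if (base_thickness < 0 || pit_depth_frac < 0 || pit_depth_frac > 1)
    stop_domain("base profile must be nonnegative everywhere")
  structure(list(layer_index = layer_index,
                 base_thickness = base_thickness,
                 pit_depth_frac = pit_depth_frac,
                 pit_sigma_mm = pit_sigma_mm,
                 hurst = hurst, amplitude = amplitude,
                 loading_f1 = loading_f1, loading_f2 = loading_f2),
            class = "synthetic_layer_spec")
}

#' Default 10-layer macular anatomy
#'
#' Smooth layered anatomy with a foveal pit on the inner six layers and the
#' published two-block latent structure: factor 1 loads on the
#' inner/neural block (NFL, GCL, IPL, INL, OPL, ONL, IS/OS, RPE), factor 2
#' on the photoreceptor-related pair (OSL, OPR).  Amplitudes and the Hurst
#' exponent are calibrated so that full-scale maps land in the mildly rough
#' regime (fractal dimensions a little above 2.1) seen on real retinas.
#'
#' @param amplitude Baseline rough-perturbation RMS, um, common to all
#'   layers.
#' @param hurst Common Hurst exponent.
#' @param loading_scale Scale of the latent-factor loadings, um per unit
#'   factor score.
#' @return List of 10 [synthetic_layer_spec()]s.
#' @export
default_layer_specs <- function(amplitude = 10, hurst = 0.3,
                                loading_scale = 1.5) {
  base <- c(20, 30, 30, 28, 26, 75, 25, 18, 18, 22)       # um, NFL..RPE
  pit <- c(rep(0.85, 6), rep(0, 4))                       # inner layers only
  f1 <- c(1, 1, 1, 1, 1, 1, 1, 0, 0, 1) * loading_scale
  f2 <- c(0, 0, 0, 0, 0, 0, 0, 1, 1, 0) * loading_scale
  lapply(1:10, function(k)
    synthetic_layer_spec(k, base[k], pit_depth_frac = pit[k],
                         hurst = hurst, amplitude = amplitude,
                         loading_f1 = f1[k], loading_f2 = f2[k]))
}

# Radial base profile of a layer on a geometry grid, um, centered on the
# fovea position.
base_profile_grid <- function(spec, geometry, fovea_rc) {
  x <- (0:(geometry$n_cols - 1) - fovea_rc[2L]) * geometry$pixel_pitch_x
  y <- (0:(geometry$n_rows - 1) - fovea_rc[1L]) * geometry$pixel_pitch_y
  r2 <- outer(y^2, x^2, `+`)                               # um^2
  sigma <- spec$pit_sigma_mm * 1000
  spec$base_thickness *
    (1 - spec$pit_depth_frac * exp(-r2 / (2 * sigma^2)))
}

#' Generate one synthetic surface stack
#'
#' Builds the 11 boundary surfaces of one eye: the inner limiting membrane
#' is a gentle smooth dome, and each successive surface adds that layer's
#' thickness field (base profile + amplitude-scaled fBm perturbation,
#' clipped at 0), so surfaces can never cross.  The fovea is placed at the
#' grid center and the papilla at the canonical maculopapillary offset
#' (4.377 mm, 6.766 degrees), so the default normalization is exactly
#' determined.  The pre-clip thickness fields and per-layer amplitudes are
#' kept in the `truth` component for verification against downstream
#' stages.
#'
#' @param specs List of 10 [synthetic_layer_spec()]s.
#' @param subject_roughness Per-layer additive amplitude offsets, um
#'   (length 10; the realized amplitude is
#'   `max(0, spec$amplitude + offset)`).  Default 0.
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param geometry A [scan_geometry()].
#' @param subject_id Character id.
#' @param mask_rect Optional `c(row1, row2, col1, col2)` (1-based,
#'   inclusive) rectangle marked as segmentation failure.
#' @return A [surface_stack()] with an extra `truth` component.
#' @export
generate_surface_stack <- function(specs, subject_roughness = rep(0, 10),
                                   seed, geometry = scan_geometry(),
                                   subject_id = "synthetic",
                                   mask_rect = NULL) {
  if (length(specs) != 10L)
    stop_domain("need 10 layer specs, got ", length(specs))
  if (length(subject_roughness) != 10L || any(!is.finite(subject_roughness)))
    stop_domain("subject_roughness must be 10 finite amplitude offsets")

  fovea_rc <- c((geometry$n_rows - 1) / 2, (geometry$n_cols - 1) / 2)
  axis_um <- 4377; tilt <- 6.766 * pi / 180
  # papilla sits on the nasal side: mirrored for left eyes so that the
  # left-right flip restores the canonical maculopapillary offset
  col_sign <- if (geometry$eye == "left") -1 else 1
  papilla_rc <- fovea_rc +
    c(axis_um * sin(tilt) / geometry$pixel_pitch_y,
      col_sign * axis_um * cos(tilt) / geometry$pixel_pitch_x)

  seeds <- derive_seeds(seed, 10L)
  x <- (0:(geometry$n_cols - 1) - fovea_rc[2L]) * geometry$pixel_pitch_x
  y <- (0:(geometry$n_rows - 1) - fovea_rc[1L]) * geometry$pixel_pitch_y
  ilm <- 100 + (outer(y^2, x^2, `+`)) / 1e6 * 2            # gentle dome, um

  amplitudes <- numeric(10L)
  thickness_fields <- pre_clip <- vector("list", 10L)
  surfaces <- vector("list", 11L)
  surfaces[[1L]] <- ilm
  for (k in 1:10) {
    spec <- specs[[k]]
    stopifnot(inherits(spec, "synthetic_layer_spec"))
    amp <- max(0, spec$amplitude + subject_roughness[k])
    amplitudes[k] <- amp
    base <- base_profile_grid(spec, geometry, fovea_rc)
    rough <- if (amp > 0)
      amp * generate_fbm_field(spec$hurst, geometry$n_rows, geometry$n_cols,
                               c(geometry$pixel_pitch_x,
                                 geometry$pixel_pitch_y), seeds[k])
    else 0
    pre_clip[[k]] <- base + rough
    thickness_fields[[k]] <- pmax(pre_clip[[k]], 0)
    surfaces[[k + 1L]] <- surfaces[[k]] + thickness_fields[[k]]
  }

  mask <- matrix(TRUE, geometry$n_rows, geometry$n_cols)
  if (!is.null(mask_rect)) {
    stopifnot(length(mask_rect) == 4L)
    mask[mask_rect[1L]:mask_rect[2L], mask_rect[3L]:mask_rect[4L]] <- FALSE
  }
  stack <- surface_stack(surfaces, geometry, valid_mask = mask,
                         fovea_rc = fovea_rc, papilla_rc = papilla_rc,
                         subject_id = subject_id)
  stack$truth <- list(thickness = thickness_fields, pre_clip = pre_clip,
                      amplitudes = amplitudes, seed = seed)
  stack
}

#' Specification of a synthetic cohort
#'
#' @param n_ad,n_ctl Group sizes (>= 2 each).
#' @param group_roughness_effect Additive increase of every layer's
#'   roughness amplitude in the simulated-AD arm, um.
#' @param subject_noise_sd SD of the per-subject-per-layer amplitude
#'   noise, um.
#' @param covariate_model List of slopes linking covariates to the
#'   subject's mean amplitude elevation (um): `mmse_slope` (< 0),
#'   `va_slope` (< 0), `age_slope` (> 0), plus residual SDs `mmse_sd`,
#'   `va_sd`, `age_sd`.
#' @param seed Integer master seed; identical seeds give bit-identical
#'   cohorts.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ad = 19L, n_ctl = 24L,
                        group_roughness_effect = 0.5,
                        subject_noise_sd = 0.5,
                        covariate_model = list(mmse_slope = -1.2, mmse_sd = 2,
                                               va_slope = -0.08, va_sd = 0.12,
                                               age_slope = 1.0, age_sd = 3),
                        seed = 1L) {
  n_ad <- as.integer(n_ad); n_ctl <- as.integer(n_ctl)
  if (n_ad < 2L || n_ctl < 2L) stop_domain("need at least 2 subjects per group")
  structure(list(n_ad = n_ad, n_ctl = n_ctl,
                 group_roughness_effect = group_roughness_effect,
                 subject_noise_sd = subject_noise_sd,
                 covariate_model = covariate_model,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of surface stacks with covariates
#'
#' Per subject, two independent standard-normal latent factor scores F1 and
#' F2 drive the per-layer roughness amplitude offsets
#' `loading_f1 * F1 + loading_f2 * F2 + group effect + noise` (um, floored
#' so realized amplitudes stay nonnegative), reproducing a two-block factor
#' structure across layers and a group roughness elevation in the
#' simulated-AD arm.  Clinical covariates are drawn with the signed
#' associations expected of an AD cohort: MMSE and visual acuity decrease,
#' and age increases, with the subject's roughness elevation; group MMSE
#' and age distributions match a mild-AD / healthy-control contrast (MMSE
#' about 23.4 +/- 3.1 with range 17 to 29, vs 28.4 +/- 2.0 with range 25 to 31).
#'
#' @param spec A [cohort_spec()].
#' @param layer_specs List of 10 [synthetic_layer_spec()]s.
#' @param geometry A [scan_geometry()].
#' @return List with `stacks` (list of [surface_stack()]) and `covariates`
#'   (`data.frame`: subject_id, group, mmse, visual_acuity, age, sex,
#'   education_level, refractive_error) plus the latent `truth`
#'   (factor scores and amplitude offsets).
#' @export
generate_cohort <- function(spec, layer_specs = default_layer_specs(),
                            geometry = scan_geometry()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_ad + spec$n_ctl
  group <- rep(c("AD", "CTL"), c(spec$n_ad, spec$n_ctl))
  ids <- sprintf("S%03d", seq_len(n))
  cm <- spec$covariate_model

  l1 <- vapply(layer_specs, `[[`, 0, "loading_f1")
  l2 <- vapply(layer_specs, `[[`, 0, "loading_f2")

  seeds <- derive_seeds(spec$seed, 2L)
  draws <- with_seed(seeds[1L], {
    F1 <- stats::rnorm(n); F2 <- stats::rnorm(n)
    noise <- matrix(stats::rnorm(n * 10L, sd = spec$subject_noise_sd), n, 10L)
    mmse_e <- stats::rnorm(n, sd = cm$mmse_sd)
    va_e <- stats::rnorm(n, sd = cm$va_sd)
    age_e <- stats::rnorm(n, sd = cm$age_sd)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    edu <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
    refr <- round(stats::rnorm(n, 0.1, 1.2) * 4) / 4
    list(F1 = F1, F2 = F2, noise = noise, mmse_e = mmse_e, va_e = va_e,
         age_e = age_e, sex = sex, edu = edu, refr = refr)
  })

  offsets <- outer(draws$F1, l1) + outer(draws$F2, l2) + draws$noise +
    ifelse(group == "AD", spec$group_roughness_effect, 0)

  # subject's mean amplitude elevation (um) drives the covariates
  rho <- rowMeans(offsets)
  mmse <- ifelse(group == "AD", 23.4, 28.4) +
    cm$mmse_slope * (rho - mean(rho)) + draws$mmse_e
  mmse <- round(pmin(ifelse(group == "AD", 29, 31),
                     pmax(ifelse(group == "AD", 17, 25), mmse)))
  va <- 0.9 + cm$va_slope * (rho - mean(rho)) + draws$va_e
  va <- pmin(1.2, pmax(0.1, round(va, 2)))
  age <- ifelse(group == "AD", 79.2, 75.7) +
    cm$age_slope * (rho - mean(rho)) + draws$age_e
  age <- round(pmin(92, pmax(62, age)))

  stack_seeds <- derive_seeds(seeds[2L], n)
  stacks <- lapply(seq_len(n), function(i)
    generate_surface_stack(layer_specs, subject_roughness = offsets[i, ],
                           seed = stack_seeds[i], geometry = geometry,
                           subject_id = ids[i]))
  names(stacks) <- ids

  covariates <- data.frame(subject_id = ids, group = group, mmse = mmse,
                           visual_acuity = va, age = age, sex = draws$sex,
                           education_level = draws$edu,
                           refractive_error = draws$refr,
                           stringsAsFactors = FALSE)
  list(stacks = stacks, covariates = covariates,
       truth = list(F1 = draws$F1, F2 = draws$F2, offsets = offsets,
                    loading_f1 = l1, loading_f2 = l2, rho = rho))
}
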