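#' Parameters of the canonical macular frame
#'
#' Spatial normalization places every subject's fovea at the image center
#' and standardizes the maculopapillary axis (fovea to optic-nerve-head
#' center) to a fixed length and tilt, so that the same anatomical region is
#' compared across subjects.  Defaults: axis length 4.377 mm, tilt 6.766
#' degrees, isotropic output pitch 11.7 um/px, and a central analysis square
#' of 2.555 mm.
#'
#' @param target_axis_length Maculopapillary axis length, mm.
#' @param target_axis_tilt Axis tilt below the horizontal, degrees.
#' @param output_pitch Isotropic pitch of the normalized grid, um/px.
#' @param roi_side Side of the central analysis square, mm.
#' @return Object of class `norm_params`.
#' @export
norm_params <- function(target_axis_length = 4.377,
                        target_axis_tilt = 6.766,
                        output_pitch = 11.7,
                        roi_side = 2.555) {
  stopifnot(target_axis_length > 0, output_pitch > 0, roi_side > 0)
  structure(list(target_axis_length = target_axis_length,
                 target_axis_tilt = target_axis_tilt,
                 output_pitch = output_pitch,
                 roi_side = roi_side),
            class = "norm_params")
}

# Physical coordinates: x = col * pixel_pitch_x, y = row * pixel_pitch_y
# (um, y increasing downward).  The similarity is represented as a complex
# map w = a z + b from input physical coordinates to output physical
# coordinates; rotation sense: positive tilt places the papilla below the
# horizontal through the fovea.

#' Fit the similarity transform onto the canonical frame
#'
#' A translation + rotation + isotropic scale is exactly determined by the
#' two landmark constraints: the fovea maps to the output-grid center and
#' the papilla to the point `target_axis_length` away at
#' `target_axis_tilt` degrees below the horizontal.
#'
#' @param fovea_rc,papilla_rc Landmark (row, col) positions, 0-based grid
#'   units of `geometry`.
#' @param geometry Input [scan_geometry()].
#' @param params A [norm_params()].
#' @return Object of class `similarity_transform` with fields `a`, `b`
#'   (complex coefficients), the output grid size and pitch.
#' @export
similarity_transform <- function(fovea_rc, papilla_rc, geometry, params) {
  stopifnot(inherits(geometry, "scan_geometry"), inherits(params, "norm_params"))
  to_phys <- function(rc) complex(real = rc[2L] * geometry$pixel_pitch_x,
                                  imaginary = rc[1L] * geometry$pixel_pitch_y)
  z_f <- to_phys(fovea_rc); z_p <- to_phys(papilla_rc)
  if (Mod(z_p - z_f) < 1e-9)
    stop_domain("degenerate landmarks: fovea and papilla coincide")

  p <- params$output_pitch
  out_cols <- as.integer(round(geometry$n_cols * geometry$pixel_pitch_x / p))
  out_rows <- as.integer(round(geometry$n_rows * geometry$pixel_pitch_y / p))
  center <- complex(real = (out_cols - 1) / 2 * p,
                    imaginary = (out_rows - 1) / 2 * p)
  tilt <- params$target_axis_tilt * pi / 180
  target <- center + params$target_axis_length * 1000 *
    complex(real = cos(tilt), imaginary = sin(tilt))

  a <- (target - center) / (z_p - z_f)
  b <- center - a * z_f
  structure(list(a = a, b = b, out_rows = out_rows, out_cols = out_cols,
                 output_pitch = p,
                 fovea_out_rc = c((out_rows - 1) / 2, (out_cols - 1) / 2)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity_transform: scale %.4f, rotation %.3f deg, output %d x %d @ %.1f um/px\n",
              Mod(x$a), Arg(x$a) * 180 / pi, x$out_rows, x$out_cols,
              x$output_pitch))
  invisible(x)
}

# Apply the fitted transform to a landmark given in input grid units;
# returns output (row, col).
transform_point <- function(transform, rc, geometry) {
  z <- complex(real = rc[2L] * geometry$pixel_pitch_x,
               imaginary = rc[1L] * geometry$pixel_pitch_y)
  w <- transform$a * z + transform$b
  c(Im(w), Re(w)) / transform$output_pitch
}

#' Resample a thickness map into the canonical frame
#'
#' Pulls each output pixel back through the inverse similarity and
#' bilinearly interpolates the source map on an isotropic output grid.
#' Mask handling is conservative: an output pixel is valid only if every
#' source pixel with nonzero interpolation weight is inside the grid and
#' valid; pixels mapping outside the scanned area are masked, never an
#' error.
#'
#' @param map A [thickness_map()] in scanner geometry.
#' @param transform A [similarity_transform()] fitted from the same stack.
#' @param params The [norm_params()] used for the transform.
#' @return A normalized [thickness_map()] with `fovea_rc` at the grid
#'   center.
#' @export
resample <- function(map, transform, params) {
  stopifnot(inherits(map, "thickness_map"),
            inherits(transform, "similarity_transform"))
  g <- map$geometry
  nr_out <- transform$out_rows; nc_out <- transform$out_cols
  p <- transform$output_pitch

  identity_tr <- transform$a == 1 + 0i && transform$b == 0 + 0i &&
    nr_out == g$n_rows && nc_out == g$n_cols &&
    isTRUE(all.equal(c(g$pixel_pitch_x, g$pixel_pitch_y), c(p, p)))
  if (identity_tr) {
    out <- map$values
    valid <- map$valid_mask
  } else {
    # output pixel centers -> input fractional grid coordinates (affine,
    # built from outer sums; no complex matrices on the hot path)
    ar <- Re(transform$a); ai <- Im(transform$a)
    det_a <- ar^2 + ai^2
    xo <- 0:(nc_out - 1) * p - Re(transform$b)
    yo <- 0:(nr_out - 1) * p - Im(transform$b)
    # z = conj(a) w / |a|^2
    src_x <- outer(yo * ai, xo * ar, `+`) / det_a
    src_y <- outer(yo * ar, -xo * ai, `+`) / det_a
    src_c <- src_x / g$pixel_pitch_x
    src_r <- src_y / g$pixel_pitch_y

    r0 <- floor(src_r); c0 <- floor(src_c)
    fr <- src_r - r0;   fc <- src_c - c0

    vals_na <- map$values
    vals_na[!map$valid_mask] <- NA_real_
    nr <- g$n_rows; nc <- g$n_cols
    fetch <- function(ri, ci) {
      lin <- ri + 1 + ci * nr
      lin[ri < 0 | ri >= nr | ci < 0 | ci >= nc] <- NA_real_
      array(vals_na[lin], dim(ri))
    }
    contrib <- function(wgt, val) {
      x <- wgt * val
      x[wgt == 0] <- 0       # zero-weight corners must not force invalidity
      x
    }
    v00 <- fetch(r0,     c0);     v01 <- fetch(r0,     c0 + 1)
    v10 <- fetch(r0 + 1, c0);     v11 <- fetch(r0 + 1, c0 + 1)
    w00 <- (1 - fr) * (1 - fc);   w01 <- (1 - fr) * fc
    w10 <- fr * (1 - fc);         w11 <- fr * fc
    out <- contrib(w00, v00) + contrib(w01, v01) +
           contrib(w10, v10) + contrib(w11, v11)
    valid <- !is.na(out) & (w00 + w01 + w10 + w11) > 0
    out[!valid] <- NA_real_
  }

  out_geom <- scan_geometry(nr_out, nc_out, p, p, g$depth_step, g$eye)
  thickness_map(out, map$layer_index, out_geom, valid_mask = valid,
                normalized = TRUE, fovea_rc = transform$fovea_out_rc)
}

#' Extract the central analysis square
#'
#' Crops the largest standardized square centered on the fovea from a
#' normalized map: side `floor(roi_side / output_pitch)` pixels (2.555 mm at
#' 11.7 um/px gives 218 px).  For an even side the extra pixel is placed on
#' the higher-index side, i.e. ties resolve toward the lower index.
#'
#' @param map A normalized [thickness_map()].
#' @param params The [norm_params()] in force.
#' @return A square [thickness_map()] (still normalized).
#' @export
central_roi <- function(map, params) {
  stopifnot(inherits(map, "thickness_map"))
  if (!map$normalized)
    stop_domain("central_roi requires a spatially normalized map")
  p <- map$geometry$pixel_pitch_x
  side <- as.integer(floor(params$roi_side * 1000 / p))
  fr <- as.integer(floor(map$fovea_rc[1L] + 0.5))
  fc <- as.integer(floor(map$fovea_rc[2L] + 0.5))
  r0 <- fr - side %/% 2L; c0 <- fc - side %/% 2L   # 0-based start
  r1 <- r0 + side - 1L;   c1 <- c0 + side - 1L
  nr <- nrow(map$values); nc <- ncol(map$values)
  if (r0 < 0L || c0 < 0L || r1 >= nr || c1 >= nc)
    stop_domain(sprintf(
      "ROI of %d px exceeds map extent: rows [%d, %d] cols [%d, %d] vs %d x %d grid",
      side, r0, r1, c0, c1, nr, nc))
  rows <- (r0 + 1L):(r1 + 1L); cols <- (c0 + 1L):(c1 + 1L)
  out_geom <- scan_geometry(side, side, p, p, map$geometry$depth_step,
                            map$geometry$eye)
  thickness_map(map$values[rows, cols], map$layer_index, out_geom,
                valid_mask = map$valid_mask[rows, cols],
                normalized = TRUE,
                fovea_rc = c(map$fovea_rc[1L] - r0, map$fovea_rc[2L] - c0))
}
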