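#' Scan geometry of an OCT macular volume
#'
#' Describes the en-face sampling grid of a macular OCT volume: the number of
#' A-scans per B-scan (columns), the number of B-scans (rows), the physical
#' pixel pitches, the axial depth quantum, and which eye was scanned.  The
#' defaults correspond to a 6 x 6 mm macular cube acquired at 512 x 128
#' density with voxel size 11.7 x 46.9 x 3.5 um (horizontal x vertical x
#' depth).
#'
#' The grid convention used throughout the package is `row` = B-scan index
#' (vertical, `pixel_pitch_y` um apart) and `col` = A-scan index (horizontal,
#' `pixel_pitch_x` um apart), with depth z in um increasing away from the
#' vitreous.
#'
#' @param n_rows Number of B-scans (rows of the en-face grid).
#' @param n_cols Number of A-scans per B-scan (columns).
#' @param pixel_pitch_x Horizontal pitch between A-scans, um.
#' @param pixel_pitch_y Vertical pitch between B-scans, um.
#' @param depth_step Axial sampling quantum, um; also the gray-level quantum
#'   of the `native_depth` thickness coding.
#' @param eye `"right"` or `"left"`.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_rows = 128L, n_cols = 512L,
                          pixel_pitch_x = 11.7, pixel_pitch_y = 46.9,
                          depth_step = 3.5, eye = c("right", "left")) {
  eye <- match.arg(eye)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 2L || n_cols < 2L)
    stop_domain("scan grid must be at least 2 x 2")
  if (pixel_pitch_x <= 0 || pixel_pitch_y <= 0 || depth_step <= 0)
    stop_domain("pixel pitches and depth step must be positive")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 pixel_pitch_x = pixel_pitch_x,
                 pixel_pitch_y = pixel_pitch_y,
                 depth_step = depth_step, eye = eye),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("OCT scan geometry: %d x %d (rows x cols), pitch %.1f x %.1f um, depth step %.1f um, %s eye\n",
              x$n_rows, x$n_cols, x$pixel_pitch_y, x$pixel_pitch_x,
              x$depth_step, x$eye))
  invisible(x)
}

geometry_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("n_rows", "n_cols", "pixel_pitch_x",
                                "pixel_pitch_y", "depth_step")],
                   unclass(b)[c("n_rows", "n_cols", "pixel_pitch_x",
                                "pixel_pitch_y", "depth_step")]))
}
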