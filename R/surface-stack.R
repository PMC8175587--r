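#' Boundary-surface stack of one macular OCT volume
#'
#' Container for the eleven boundary surfaces that delimit the ten retinal
#' layers of one eye, from surface 1 (inner limiting membrane, ILM) to
#' surface 11 (outer boundary of the retinal pigment epithelium, OB_RPE),
#' together with the scan geometry, the segmentation validity mask and the
#' foveal / papillary landmark positions.
#'
#' Surfaces are elevation grids `z(row, col)` in um with depth increasing
#' away from the vitreous, so anatomical ordering requires
#' `z_k <= z_(k+1)` at every valid grid point; the constructor enforces this
#' and names the first offending surface pair otherwise.  Landmarks are
#' stored as fractional (row, col) positions in grid units; they are inputs
#' (ground truth for synthetic data, upstream detections for real data), not
#' something this package detects.
#'
#' @param surfaces List of 11 numeric matrices (um), innermost first.
#' @param geometry A [scan_geometry()].
#' @param valid_mask Logical matrix, `TRUE` where segmentation succeeded.
#'   Defaults to all-valid.
#' @param fovea_rc,papilla_rc Numeric pairs `c(row, col)`, 0-based fractional
#'   grid coordinates of the foveal fossa and optic-nerve-head centers.  The
#'   papilla may lie outside the sampled grid.
#' @param subject_id Character scalar.
#' @return An object of class `surface_stack`.
#' @seealso [raw_thickness()], [write_stack()], [flip_left_eye()]
#' @export
surface_stack <- function(surfaces, geometry, valid_mask = NULL,
                          fovea_rc, papilla_rc, subject_id = "subject") {
  if (!inherits(geometry, "scan_geometry"))
    stop_domain("geometry must be a scan_geometry object")
  if (!is.list(surfaces) || length(surfaces) != 11L)
    stop_domain("a surface stack needs exactly 11 boundary surfaces, got ",
                length(surfaces))
  dims <- c(geometry$n_rows, geometry$n_cols)
  for (k in seq_along(surfaces)) {
    s <- surfaces[[k]]
    if (!is.matrix(s) || !is.numeric(s))
      stop_domain("surface ", k, " is not a numeric matrix")
    if (!identical(dim(s), dims) && !identical(dim(s), as.integer(dims)))
      stop_domain("surface ", k, " has shape ", nrow(s), " x ", ncol(s),
                  " but geometry says ", dims[1L], " x ", dims[2L])
    storage.mode(surfaces[[k]]) <- "double"
  }
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, dims[1L], dims[2L])
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), dim(surfaces[[1L]])))
    stop_domain("valid_mask must be a logical matrix matching the grid shape")
  fovea_rc <- as.numeric(fovea_rc); papilla_rc <- as.numeric(papilla_rc)
  if (length(fovea_rc) != 2L || length(papilla_rc) != 2L)
    stop_domain("landmarks must be (row, col) pairs")
  obj <- structure(list(geometry = geometry, surfaces = surfaces,
                        valid_mask = valid_mask, fovea_rc = fovea_rc,
                        papilla_rc = papilla_rc,
                        subject_id = as.character(subject_id)),
                   class = "surface_stack")
  check_surface_order(obj)
  obj
}

# Anatomical ordering: at valid points each surface must lie at or below the
# previous one.  Error message names the offending pair (used by readers).
check_surface_order <- function(stack, tol = 1e-9) {
  v <- stack$valid_mask
  for (k in 1:10) {
    d <- stack$surfaces[[k + 1L]] - stack$surfaces[[k]]
    if (any(d[v] < -tol, na.rm = TRUE))
      stop_domain("crossing surfaces: surface ", k, " > surface ", k + 1L,
                  " at ", sum(d[v] < -tol, na.rm = TRUE), " valid grid points")
  }
  invisible(TRUE)
}

#' @export
print.surface_stack <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("surface_stack '%s': 11 surfaces on %d x %d grid (%s eye), %.1f%% valid\n",
              x$subject_id, g$n_rows, g$n_cols, g$eye,
              100 * mean(x$valid_mask)))
  cat(sprintf("  fovea at (%.1f, %.1f), papilla at (%.1f, %.1f) [row, col]\n",
              x$fovea_rc[1L], x$fovea_rc[2L], x$papilla_rc[1L], x$papilla_rc[2L]))
  invisible(x)
}

#' Mirror a left-eye stack into right-eye orientation
#'
#' Left eyes are left-right flipped so that temporal and nasal retina occupy
#' the same grid columns in every subject.  Columns of all surfaces and of
#' the mask are reversed, landmark columns are reflected
#' (`col -> n_cols - 1 - col`), and the eye label becomes `"right"`.  The
#' operation is an involution on the grids: flipping twice restores them.
#' Applying it to a right eye is a no-op with a warning.
#'
#' @param stack A [surface_stack()].
#' @return The flipped `surface_stack`.
#' @export
flip_left_eye <- function(stack) {
  stopifnot(inherits(stack, "surface_stack"))
  if (stack$geometry$eye != "left") {
    warning("flip_left_eye: stack is already right-eye oriented; no-op")
    return(stack)
  }
  nc <- stack$geometry$n_cols
  rev_cols <- function(m) m[, nc:1, drop = FALSE]
  stack$surfaces <- lapply(stack$surfaces, rev_cols)
  stack$valid_mask <- rev_cols(stack$valid_mask)
  stack$fovea_rc[2L] <- nc - 1 - stack$fovea_rc[2L]
  stack$papilla_rc[2L] <- nc - 1 - stack$papilla_rc[2L]
  stack$geometry$eye <- "right"
  stack
}
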