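#' Per-layer thickness map
#'
#' En-face grid of one retinal layer's thickness in um, with a validity mask
#' (points where upstream segmentation failed never enter statistics), the
#' scan geometry, and a flag saying whether the map has been spatially
#' normalized to the canonical macular frame.
#'
#' @param values Numeric matrix of thicknesses, um; invalid cells may hold
#'   `NA`.
#' @param layer_index Integer 1..10, innermost (NFL) to outermost (RPE);
#'   0 denotes the total retina (surface 11 minus surface 1).
#' @param geometry A [scan_geometry()] (for normalized maps, the isotropic
#'   output geometry).
#' @param valid_mask Logical matrix; defaults to `!is.na(values)`.
#' @param normalized Logical flag.
#' @param fovea_rc Optional (row, col) of the fovea in this map's grid.
#' @return Object of class `thickness_map`.
#' @export
thickness_map <- function(values, layer_index, geometry, valid_mask = NULL,
                          normalized = FALSE, fovea_rc = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  layer_index <- as.integer(layer_index)
  if (is.na(layer_index) || layer_index < 0L || layer_index > 10L)
    stop_domain("layer_index must be in 0..10 (0 = total retina)")
  if (is.null(valid_mask)) valid_mask <- !is.na(values)
  stopifnot(identical(dim(valid_mask), dim(values)))
  if (any(values[valid_mask] < -1e-9, na.rm = TRUE))
    stop_domain("negative thickness at valid grid points")
  values[!valid_mask] <- NA_real_
  structure(list(values = values, layer_index = layer_index,
                 geometry = geometry, valid_mask = valid_mask,
                 normalized = isTRUE(normalized),
                 fovea_rc = fovea_rc),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("thickness_map layer %d%s: %d x %d, %.1f%% valid, mean %.1f um [%.1f, %.1f]\n",
              x$layer_index, if (x$normalized) " (normalized)" else "",
              nrow(x$values), ncol(x$values), 100 * mean(x$valid_mask),
              mean(v), min(v), max(v)))
  invisible(x)
}

layer_names <- function() c("NFL", "GCL", "IPL", "INL", "OPL", "ONL",
                            "IS/OS", "OSL", "OPR", "RPE")

#' Raw (axial) thickness of one layer
#'
#' The raw thickness at each scanned point is the depth separation of the
#' layer's two bounding surfaces measured along the A-scan direction:
#' `z_(k+1) - z_k` um.  On tilted layers this overestimates the true
#' thickness; see [orthogonal_thickness()] for the cosine correction.
#'
#' @param stack A [surface_stack()].
#' @param layer_index Layer 1..10, or 0 for the total retina
#'   (surface 11 minus surface 1).
#' @return A [thickness_map()] carrying the stack's validity mask.
#' @export
raw_thickness <- function(stack, layer_index) {
  stopifnot(inherits(stack, "surface_stack"))
  layer_index <- as.integer(layer_index)
  if (layer_index < 0L || layer_index > 10L)
    stop_domain("layer_index must be in 0..10")
  if (layer_index == 0L) {
    vals <- stack$surfaces[[11L]] - stack$surfaces[[1L]]
  } else {
    vals <- stack$surfaces[[layer_index + 1L]] - stack$surfaces[[layer_index]]
  }
  vals <- pmax(vals, 0)          # guard tiny negatives from round-off
  thickness_map(vals, layer_index, stack$geometry,
                valid_mask = stack$valid_mask,
                fovea_rc = stack$fovea_rc)
}

#' Orthogonal (tilt-corrected) thickness
#'
#' Raw axial thickness overestimates true thickness wherever the layer is
#' tilted with respect to the scanning beam: if the layer's mid-surface
#' makes angle theta with the en-face plane, the true thickness is the raw
#' thickness times cos(theta).  The local tilt is taken from the gradient of
#' the layer mid-surface `(z_k + z_(k+1))/2` in physical units, estimated by
#' central differences (one-sided at grid borders), so that
#' `cos(theta) = 1 / sqrt(1 + (dz/dx)^2 + (dz/dy)^2)`.  Grid points whose
#' stencil neighbor is masked are differenced one-sided away from the mask;
#' if neither neighbor along an axis is valid that gradient component is 0.
#'
#' The correction never increases thickness: output <= raw pointwise, with
#' equality exactly where the local gradient vanishes.  A layer displaced by
#' a smooth undulation common to both bounding surfaces keeps its
#' orthogonal thickness (up to discretization): undulating like a flag does
#' not change how thick the flag is.
#'
#' @param raw A [raw_thickness()] map.
#' @param stack The [surface_stack()] the raw map came from.
#' @return A [thickness_map()] of corrected thicknesses.
#' @export
orthogonal_thickness <- function(raw, stack) {
  stopifnot(inherits(raw, "thickness_map"), inherits(stack, "surface_stack"))
  if (!geometry_equal(raw$geometry, stack$geometry))
    stop_domain("raw map and stack disagree on scan geometry")
  k <- raw$layer_index
  if (k == 0L) {
    mid <- (stack$surfaces[[1L]] + stack$surfaces[[11L]]) / 2
  } else {
    mid <- (stack$surfaces[[k]] + stack$surfaces[[k + 1L]]) / 2
  }
  g <- stack$geometry
  gx <- masked_gradient(mid, stack$valid_mask, g$pixel_pitch_x, along = "col")
  gy <- masked_gradient(mid, stack$valid_mask, g$pixel_pitch_y, along = "row")
  cos_theta <- 1 / sqrt(1 + gx^2 + gy^2)
  out <- raw
  out$values <- raw$values * cos_theta
  out
}

# Gradient of grid z along rows or cols, spacing `pitch` um, central
# differences, one-sided at borders and next to masked cells, 0 where no
# valid neighbor exists along the axis.
masked_gradient <- function(z, mask, pitch, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") {
    t(masked_gradient(t(z), t(mask), pitch, "col"))
  } else {
    n <- ncol(z)
    zl <- cbind(NA_real_, z[, -n, drop = FALSE])   # left neighbor
    zr <- cbind(z[, -1, drop = FALSE], NA_real_)   # right neighbor
    ml <- cbind(FALSE, mask[, -n, drop = FALSE])
    mr <- cbind(mask[, -1, drop = FALSE], FALSE)
    grad <- matrix(0, nrow(z), n)
    both <- ml & mr
    grad[both] <- (zr[both] - zl[both]) / (2 * pitch)
    onlyr <- !ml & mr
    grad[onlyr] <- (zr[onlyr] - z[onlyr]) / pitch
    onlyl <- ml & !mr
    grad[onlyl] <- (z[onlyl] - zl[onlyl]) / pitch
    grad[!mask] <- 0
    grad
  }
}
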