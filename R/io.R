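#' Write / read a surface stack in the plain-text exchange format
#'
#' One directory per subject: `surface_01.csv` ... `surface_11.csv` hold the
#' elevation grids (um, one CSV row per B-scan, no header), `mask.csv` the
#' 0/1 validity grid, and `meta.json` the scan geometry, landmarks and
#' subject id.  Grids are written with shortest round-trip decimal
#' representation, so a write-read cycle reproduces the stack bit for bit.
#' `read_stack()` re-validates shapes and the anatomical surface ordering
#' and names the offending surface pair on failure.
#'
#' @param stack A [surface_stack()].
#' @param path Directory to create/read (created if absent on write).
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   the `surface_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "surface_stack"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (k in 1:11)
    write_grid_csv(stack$surfaces[[k]],
                   file.path(path, sprintf("surface_%02d.csv", k)))
  data.table::fwrite(data.table::as.data.table(stack$valid_mask * 1L),
                     file.path(path, "mask.csv"), col.names = FALSE)
  g <- stack$geometry
  # landmark coordinates as %.17g strings: shortest-exact decimal so the
  # JSON header round-trips doubles bit for bit
  meta <- list(format = "retroughness-stack-v1",
               subject_id = stack$subject_id,
               geometry = unclass(g),
               fovea_rc = sprintf("%.17g", stack$fovea_rc),
               papilla_rc = sprintf("%.17g", stack$papilla_rc))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# 17-significant-digit CSV grid writer: decimal representation that
# round-trips IEEE doubles exactly (fread parses at full precision).
write_grid_csv <- function(m, path) {
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = ",")), path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file))
    stop_domain("not a stack directory (no meta.json): ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  g <- meta$geometry
  geometry <- scan_geometry(g$n_rows, g$n_cols, g$pixel_pitch_x,
                            g$pixel_pitch_y, g$depth_step, g$eye)
  surfaces <- vector("list", 11L)
  for (k in 1:11) {
    f <- file.path(path, sprintf("surface_%02d.csv", k))
    if (!file.exists(f)) stop_domain("missing surface ", k, " in ", path)
    surfaces[[k]] <- as.matrix(data.table::fread(f, header = FALSE))
    dimnames(surfaces[[k]]) <- NULL
  }
  mask <- as.matrix(data.table::fread(file.path(path, "mask.csv"),
                                      header = FALSE)) == 1L
  dimnames(mask) <- NULL
  surface_stack(surfaces, geometry, valid_mask = mask,
                fovea_rc = as.numeric(meta$fovea_rc),
                papilla_rc = as.numeric(meta$papilla_rc),
                subject_id = meta$subject_id)
}

#' Adapter stub for a deposited layer-thickness dataset
#'
#' Reads an externally downloaded archive of per-layer macular thickness
#' maps into [thickness_map()] objects.  The expected layout is one CSV grid
#' per subject and layer named `<subject>_layer<k>.csv` (um, no header),
#' accompanied by `geometry.json` describing the sampling grid.  The layout
#' of the actual public deposit is not fully documented, so this adapter is
#' a thin, best-effort reader: unrecognized layouts raise an error listing
#' the files found, and the function is never exercised by the package's own
#' analyses, which use synthetic cohorts.
#'
#' @param path Directory containing the downloaded dataset.
#' @return A list of `thickness_map` objects, named `<subject>_layer<k>`.
#' @export
read_figshare_thickness <- function(path) {
  if (!dir.exists(path))
    stop_domain("dataset not present at '", path,
                "'; download it manually and pass its directory")
  gfile <- file.path(path, "geometry.json")
  files <- list.files(path, pattern = "_layer[0-9]+\\.csv$")
  if (!file.exists(gfile) || length(files) == 0L)
    stop_domain("unrecognized dataset layout under '", path, "'; found: ",
                paste(utils::head(list.files(path), 20L), collapse = ", "))
  g <- jsonlite::read_json(gfile, simplifyVector = TRUE)
  geometry <- scan_geometry(g$n_rows, g$n_cols,
                            g$pixel_pitch_x %||% 11.7,
                            g$pixel_pitch_y %||% 46.9,
                            g$depth_step %||% 3.5)
  maps <- lapply(files, function(f) {
    vals <- as.matrix(data.table::fread(file.path(path, f), header = FALSE))
    dimnames(vals) <- NULL
    if (any(vals[!is.na(vals)] < 0))
      stop_domain("negative thickness in ", f)
    layer <- as.integer(sub(".*_layer([0-9]+)\\.csv$", "\\1", f))
    thickness_map(vals, layer_index = layer, geometry = geometry,
                  valid_mask = !is.na(vals))
  })
  names(maps) <- sub("\\.csv$", "", files)
  maps
}
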