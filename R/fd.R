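#' Configuration of the box-counting roughness estimator
#'
#' The roughness of a thickness map is estimated as the fractal dimension of
#' its grayscale relief by differential box counting (DBC): the map is coded
#' as integer gray levels, partitioned into `s x s` spatial blocks, and over
#' each block the number of gray-direction boxes of height `h = s G / M`
#' spanned by the block's min-max range is accumulated; the fractal
#' dimension is the slope of `ln N_r` against `ln(1/r)` with scale ratio `r` equal to `s/M`.
#'
#' Two border conventions are provided: `classic_dbc` truncates incomplete
#' border blocks, while `integer_ratio_dbc` covers the borders with shrunken
#' blocks so that every pixel is counted at every scale.  Two thickness
#' codings are provided: `native_depth` (gray = thickness / depth quantum,
#' rounded; comparable across subjects) and `minmax_8bit` (per-map affine
#' stretch of the valid min-max range onto 0..255).  The gray range `G` is fixed at 256
#' for both codings so the box height is comparable across subjects.
#'
#' @param algorithm Border variant.
#' @param coding Thickness-to-gray coding.
#' @param scales Integer box sizes, strictly increasing, all at least 2.
#'   `NULL` (default) selects `default_box_scales()` of the map side.
#' @param fit_range Subset of `scales` used in the log-log regression;
#'   `NULL` means all scales.  At least 3 scales are required.
#' @return Object of class `box_config`.
#' @export
box_config <- function(algorithm = c("integer_ratio_dbc", "classic_dbc"),
                       coding = c("native_depth", "minmax_8bit"),
                       scales = NULL, fit_range = NULL) {
  algorithm <- match.arg(algorithm)
  coding <- match.arg(coding)
  if (!is.null(scales)) {
    scales <- as.integer(scales)
    if (any(scales < 2L) || is.unsorted(scales, strictly = TRUE))
      stop_domain("scales must be strictly increasing integers >= 2")
  }
  if (!is.null(fit_range)) {
    fit_range <- as.integer(fit_range)
    if (!is.null(scales) && !all(fit_range %in% scales))
      stop_domain("fit_range must be a subset of scales")
    if (length(fit_range) < 3L)
      stop_domain("fit_range needs at least 3 scales")
  }
  structure(list(algorithm = algorithm, coding = coding,
                 scales = scales, fit_range = fit_range, G = 256L),
            class = "box_config")
}

#' Default box-size schedule for an `M` x `M` map
#'
#' Integer sizes approximately geometric (`2, 3, 4, 6, 8, 12, ...`) capped
#' at `M/4`, a compromise keeping several blocks per axis at the coarsest
#' scale while spanning over a decade of scales.
#'
#' @param M Image side, pixels.
#' @return Integer vector of box sizes.
#' @export
default_box_scales <- function(M) {
  k <- 0:12
  s <- sort(unique(c(2L * 2L^k, 3L * 2L^k)))
  s <- s[s <= max(4L, M %/% 4L) & s <= M %/% 2L]
  if (length(s) < 3L) s <- c(2L, 3L, 4L)[c(2L, 3L, 4L) <= M %/% 2L]
  as.integer(s)
}

#' Code a thickness map as integer gray levels
#'
#' `native_depth` divides thickness by the axial depth quantum of the scan
#' (3.5 um by default geometry) and rounds, so gray levels are physical
#' depth samples and adding a whole number of quanta to a map shifts but
#' does not reshape its relief.  `minmax_8bit` stretches the valid range
#' onto 0..255; a constant map codes to all zeros.
#'
#' @param map A [thickness_map()] with at least one valid pixel.
#' @param coding `"native_depth"` or `"minmax_8bit"`.
#' @return List with `gray` (integer matrix, `NA` at invalid pixels) and
#'   `G` (gray range, 256).
#' @export
encode_gray <- function(map, coding = c("native_depth", "minmax_8bit")) {
  coding <- match.arg(coding)
  stopifnot(inherits(map, "thickness_map"))
  v <- map$values
  if (!any(map$valid_mask)) stop_domain("no valid pixels to encode")
  if (coding == "native_depth") {
    gray <- round(v / map$geometry$depth_step)
  } else {
    rng <- range(v[map$valid_mask])
    gray <- if (rng[2L] > rng[1L])
      round(255 * (v - rng[1L]) / (rng[2L] - rng[1L]))
    else v * 0
  }
  gray[!map$valid_mask] <- NA_real_
  list(gray = gray, G = 256L)
}

#' Differential box count at one scale
#'
#' Partitions an `M x M` gray grid into `s x s` blocks (`classic_dbc`:
#' truncate incomplete border blocks; `integer_ratio_dbc`: cover borders
#' with shrunken blocks so every pixel is counted), stacks boxes of height
#' `h = s G / M` in the gray direction, and sums over blocks
#' `n_r = floor(max/h) - floor(min/h) + 1` (gray level 0 occupies box 0).
#'
#' @param gray Integer gray matrix (square, no `NA`).
#' @param s Box size in pixels, `2 <= s <= M/2`.
#' @param G Gray range (256).
#' @param algorithm Border variant.
#' @return Total box count `N_r` (at least the number of blocks).
#' @export
dbc_count <- function(gray, s, G = 256L,
                      algorithm = c("integer_ratio_dbc", "classic_dbc")) {
  algorithm <- match.arg(algorithm)
  M <- nrow(gray)
  if (ncol(gray) != M) stop_domain("dbc_count needs a square grid")
  s <- as.integer(s)
  if (s < 2L || s > M %/% 2L)
    stop_domain("box size s = ", s, " outside [2, M/2] for M = ", M)
  if (anyNA(gray)) stop_domain("gray grid contains NA; ROI must be fully valid")
  dbc_count_cpp(gray, s, as.double(G), algorithm == "classic_dbc")
}

#' Fractal dimension of a thickness map
#'
#' The central estimator of the package: grayscale differential
#' box-counting fractal dimension of a (square, fully valid) thickness map,
#' the package's roughness index.  `fd` is the ordinary-least-squares slope
#' of `ln N_r` on `ln(1/r)` (scale ratio `r` equal to `s/M`) over the configured scales; a
#' constant map has `fd = 2` exactly, and any non-constant map must fall in
#' `[2, 3]` (asserted, with a small discretization tolerance, on every
#' call).  Values slightly above 2 indicate mild roughness, as seen on real
#' retinal layers.
#'
#' @param map A square, fully valid [thickness_map()] (typically the
#'   [central_roi()] of a normalized map).
#' @param config A [box_config()].
#' @return Object of class `fd_result` with components `fd`, `counts`,
#'   `scales_used`, `r_squared`, `config`, and the log-log regression data.
#' @examples
#' g <- scan_geometry(64, 64, 11.7, 11.7)
#' flat <- thickness_map(matrix(50, 64, 64), 1, g, normalized = TRUE)
#' fractal_dimension(flat, box_config())$fd   # exactly 2
#' @export
fractal_dimension <- function(map, config = box_config()) {
  stopifnot(inherits(map, "thickness_map"), inherits(config, "box_config"))
  M <- nrow(map$values)
  if (ncol(map$values) != M)
    stop_domain("fractal_dimension needs a square map; got ",
                nrow(map$values), " x ", ncol(map$values))
  if (!all(map$valid_mask))
    stop_domain("fractal_dimension needs a fully valid map (",
                sum(!map$valid_mask), " invalid pixels)")

  enc <- encode_gray(map, config$coding)
  scales <- config$scales %||% default_box_scales(M)
  scales <- scales[scales <= M %/% 2L]
  fit_scales <- config$fit_range %||% scales
  fit_scales <- fit_scales[fit_scales %in% scales]
  if (length(fit_scales) < 3L)
    stop_domain("fewer than 3 usable scales for the log-log fit")

  counts <- vapply(scales, function(s)
    dbc_count(enc$gray, s, enc$G, config$algorithm), 0)
  names(counts) <- scales

  constant <- length(unique(as.vector(enc$gray))) == 1L
  # Effective scale ratio r = 1 / (blocks per axis): the grid really is
  # covered by nb x nb spatial cells, so a constant map has slope 2 exactly
  # under both border variants (r = s/M would leave remainder jitter that
  # biases near-smooth maps below 2).
  nb <- if (config$algorithm == "integer_ratio_dbc")
    ceiling(M / fit_scales) else M %/% fit_scales
  x <- log(nb)                                   # ln(1/r)
  y <- log(counts[as.character(fit_scales)])
  if (constant) {
    fd <- 2; r2 <- 1
  } else {
    fit <- stats::lm.fit(cbind(1, x), y)
    fd <- unname(fit$coefficients[2L])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  }
  tol <- 0.05   # discretization slack on the theoretical [2, 3] range
  if (fd < 2 - tol || fd > 3 + tol)
    stop("estimated fd = ", round(fd, 4),
         " outside [2, 3]: map too degenerate for box counting")

  structure(list(fd = fd, counts = counts, scales_used = fit_scales,
                 r_squared = r2, config = config, M = M,
                 log_inv_r = x, log_counts = unname(y),
                 layer_index = map$layer_index),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("Box-counting fractal dimension: fd = %.4f (R^2 = %.4f)\n",
              x$fd, x$r_squared))
  cat(sprintf("  %s, %s coding, %d x %d map, scales {%s}\n",
              x$config$algorithm, x$config$coding, x$M, x$M,
              paste(x$scales_used, collapse = ", ")))
  invisible(x)
}

#' @export
summary.fd_result <- function(object, ...) {
  cat(sprintf("Grayscale DBC fractal dimension estimate\n"))
  print(object)
  tab <- data.frame(s = as.integer(names(object$counts)),
                    N_r = unname(object$counts))
  tab$in_fit <- tab$s %in% object$scales_used
  cat("\nBox counts by scale:\n")
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @export
coef.fd_result <- function(object, ...) {
  c(fd = object$fd, r_squared = object$r_squared)
}

#' @export
residuals.fd_result <- function(object, ...) {
  fit <- stats::lm.fit(cbind(1, object$log_inv_r), object$log_counts)
  unname(fit$residuals)
}

#' @export
plot.fd_result <- function(x, ...) {
  plot(x$log_inv_r, x$log_counts,
       xlab = "ln(1/r)", ylab = expression(ln ~ N[r]),
       main = sprintf("DBC log-log fit: fd = %.4f", x$fd), ...)
  graphics::abline(stats::lm(x$log_counts ~ x$log_inv_r), lty = 2)
  invisible(x)
}

#' Per-subject, per-layer roughness table
#'
#' Applies [fractal_dimension()] to every (subject, layer) ROI map and
#' assembles the cohort roughness table: one FD column per layer plus each
#' subject's mean FD over the 10 layers and over the 9 neural layers
#' (excluding the pigment epithelium).  A subject with any missing or
#' failed layer keeps its per-layer values but gets `NA` means.
#'
#' @param maps Named list (subjects) of lists (layers 1..10, optionally
#'   `"total"`) of square, fully valid [thickness_map()]s.
#' @param config A [box_config()].
#' @return `data.frame` with columns `subject_id`, `fd_1` .. `fd_10`
#'   (`fd_total` if supplied), `mean_fd_10`, `mean_fd_9`; attribute
#'   `"long"` holds the long form with per-map `r_squared`.
#' @export
roughness_table <- function(maps, config = box_config()) {
  stopifnot(is.list(maps), length(maps) > 0L)
  subjects <- names(maps) %||% as.character(seq_along(maps))
  long <- list()
  rows <- lapply(seq_along(maps), function(i) {
    subj <- maps[[i]]
    fds <- rep(NA_real_, 10L); r2s <- rep(NA_real_, 10L)
    named <- !is.null(names(subj)) && any(nzchar(names(subj)))
    for (k in 1:10) {
      m <- if (named) {
        if (as.character(k) %in% names(subj)) subj[[as.character(k)]]
      } else if (length(subj) >= k) subj[[k]]
      if (is.null(m)) next
      res <- tryCatch(fractal_dimension(m, config), error = function(e) NULL)
      if (!is.null(res)) { fds[k] <- res$fd; r2s[k] <- res$r_squared }
    }
    fd_total <- NA_real_
    if ("total" %in% names(subj)) {
      res <- tryCatch(fractal_dimension(subj[["total"]], config),
                      error = function(e) NULL)
      if (!is.null(res)) fd_total <- res$fd
    }
    long[[length(long) + 1L]] <<- data.frame(
      subject_id = subjects[i], layer = 1:10, fd = fds, r_squared = r2s)
    c(fds, fd_total,
      mean_fd_10 = if (anyNA(fds)) NA_real_ else mean(fds),
      mean_fd_9  = if (anyNA(fds[1:9])) NA_real_ else mean(fds[1:9]))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c(paste0("fd_", 1:10), "fd_total", "mean_fd_10", "mean_fd_9")
  tab <- cbind(subject_id = subjects, tab)
  if (all(is.na(tab$fd_total))) tab$fd_total <- NULL
  attr(tab, "long") <- do.call(rbind, long)
  tab
}
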