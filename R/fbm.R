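#' Spectral synthesis of a fractional Brownian surface
#'
#' Generates a zero-mean, unit-RMS random field whose power spectral density
#' falls off as \eqn{f^{-(2H+2)}}, i.e. an (approximate) fractional Brownian
#' surface with Hurst exponent \eqn{H}.  Such a surface has theoretical
#' fractal dimension \eqn{3 - H}, which makes it a ground-truth fixture for
#' roughness estimators: higher `hurst` means a smoother field and a lower
#' fractal dimension.
#'
#' Synthesis is by the Fourier (spectral) method: independent complex
#' Gaussian spectral coefficients are shaped by the target amplitude spectrum
#' \eqn{f^{-(H+1)}} and transformed back; the real part of the inverse FFT is
#' an exactly Hermitian-symmetrized realization.  Spatial frequencies are
#' computed from the physical pixel pitches, so anisotropic sampling grids
#' produce fields that are isotropic in physical units, not in pixel units.
#'
#' @param hurst Hurst exponent, in (0, 1).
#' @param rows,cols Grid size; both at least 8.
#' @param pixel_pitch_xy Numeric pair `c(px, py)`: horizontal and vertical
#'   pixel pitches in um.
#' @param seed Integer seed; the same seed and parameters reproduce the
#'   field bit for bit.
#' @return A `rows x cols` numeric matrix, zero mean, unit RMS (um if
#'   interpreted as an elevation perturbation of amplitude 1 um RMS).
#' @examples
#' f <- generate_fbm_field(0.8, 64, 64, seed = 1)
#' c(mean(f), sqrt(mean(f^2)))
#' @export
generate_fbm_field <- function(hurst, rows, cols,
                               pixel_pitch_xy = c(11.7, 46.9), seed) {
  if (!is.numeric(hurst) || length(hurst) != 1L || is.na(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop_domain("hurst must lie strictly inside (0, 1)")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 8L || cols < 8L)
    stop_domain("rows and cols must both be at least 8")
  px <- pixel_pitch_xy[[1L]]; py <- pixel_pitch_xy[[2L]]
  if (px <= 0 || py <= 0) stop_domain("pixel pitches must be positive")

  # Physical spatial frequencies (cycles/um) on the FFT grid; the shaped
  # amplitude spectrum depends only on (hurst, grid, pitches), so it is
  # memoized across calls.
  key <- paste(hurst, rows, cols, px, py, sep = "|")
  amp <- .fbm_cache[[key]]
  if (is.null(amp)) {
    fx <- fft_freq(cols, px)
    fy <- fft_freq(rows, py)
    f <- sqrt(outer(fy^2, fx^2, `+`))
    amp <- matrix(0, rows, cols)
    nz <- f > 0
    amp[nz] <- f[nz]^(-(hurst + 1))
    .fbm_cache[[key]] <- amp
  }

  spec <- with_seed(seed, {
    re <- matrix(stats::rnorm(rows * cols), rows, cols)
    im <- matrix(stats::rnorm(rows * cols), rows, cols)
    complex(real = re, imaginary = im)
  })
  field <- Re(stats::fft(amp * spec, inverse = TRUE))
  field <- field - mean(field)
  rms <- sqrt(mean(field^2))
  if (rms == 0) stop("degenerate fBm realization (zero field)")
  field / rms
}

# FFT frequency ordering for n samples at pitch d (um): 0, 1/(n d), ...,
# Nyquist, then negative frequencies, as stacked by R's fft().
fft_freq <- function(n, d) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * d)
}

.fbm_cache <- new.env(parent = emptyenv())
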