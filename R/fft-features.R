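#' Two-dimensional discrete Fourier transform of a patch
#'
#' Computes the unnormalized forward 2D DFT
#' \deqn{F(l,k) = \sum_{p_x=0}^{N-1}\sum_{p_y=0}^{N-1} I(p_x,p_y)\,
#'   e^{-2\pi i (k p_x + l p_y)/N}}
#' of a square patch with even side N, exploiting separability: a 1D FFT is
#' applied to every row, then to every column of the row result. Rows index
#' \eqn{p_y} (vertical position) and columns \eqn{p_x}, so the output matrix
#' holds \eqn{F(l,k)} at row l + 1, column k + 1 (0-based frequencies l, k).
#'
#' @param patch Numeric N x N matrix, N even.
#' @return Complex N x N matrix of DFT coefficients (no 1/N^2 factor).
#' @seealso [shift_center()], [magnitude()], [spectral_features()]
#' @export
dft2 <- function(patch) {
  x <- unclass(patch)
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    abort("dft2() needs a square matrix.", class = "patchfreq_bad_input")
  }
  if (nrow(x) %% 2L != 0L) {
    abort("dft2() needs an even side length.", class = "patchfreq_bad_input")
  }
  # rows first (transform along p_x), then columns (along p_y)
  mvfft(t(mvfft(t(x))))
}

#' Shift the zero-frequency bin to the center of the spectrum
#'
#' Swaps the quadrants of an even-sized spectrum so that the (0,0) frequency
#' bin lands at (N/2, N/2) (0-based). On even sizes the shift is an
#' involution: applying it twice restores the input.
#'
#' @param spectrum Square complex or numeric matrix with even side.
#' @return Matrix of the same shape with quadrants swapped.
#' @export
shift_center <- function(spectrum) {
  n <- nrow(spectrum)
  if (!is.matrix(spectrum) || n != ncol(spectrum) || n %% 2L != 0L) {
    abort("shift_center() needs a square matrix with even side.",
      class = "patchfreq_bad_input"
    )
  }
  h <- n %/% 2L
  idx <- c((h + 1L):n, 1L:h)
  spectrum[idx, idx, drop = FALSE]
}

#' Magnitude of a complex spectrum
#'
#' Elementwise modulus `sqrt(Re^2 + Im^2)`. No logarithmic scaling is
#' applied: the profile sums operate on raw magnitudes.
#'
#' @param spectrum Complex (or numeric) matrix.
#' @return Non-negative numeric matrix of the same shape.
#' @export
magnitude <- function(spectrum) {
  Mod(spectrum)
}

# Cached rasterization of the profile geometry for a given side length.
# Radial: 0-based pixel (r, c) belongs to radius bin round(dist to center)
# if it lies in the upper half-plane (row <= center row), is not the center
# itself, and its bin is within 1..N/2.
# Angular: 180 lines at 1 degree spacing, N/2 unit-radius samples each,
# nearest-pixel rounding, indices clamped into the grid (only near-axis
# samples at the largest radius fall outside an N-pixel grid).
profile_geometry <- function(n) {
  key <- as.character(n)
  geom <- profile_geometry_cache[[key]]
  if (!is.null(geom)) {
    return(geom)
  }
  ctr <- n %/% 2L # 0-based center index
  rmax <- n %/% 2L
  rows <- rep(0:(n - 1L), times = n)
  cols <- rep(0:(n - 1L), each = n)
  d <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  bin <- as.integer(round(d))
  keep <- rows <= ctr & !(rows == ctr & cols == ctr) & bin >= 1L & bin <= rmax
  radial_lin <- rows[keep] + n * cols[keep] + 1L # column-major linear index
  radial_bin <- bin[keep]

  ang_k <- rep(0:179, each = rmax)
  ang_r <- rep(seq_len(rmax), times = 180L)
  theta <- ang_k * pi / 180
  srow <- ctr - round(ang_r * sin(theta))
  scol <- ctr + round(ang_r * cos(theta))
  srow <- pmin(pmax(srow, 0L), n - 1L)
  scol <- pmin(pmax(scol, 0L), n - 1L)
  ang_lin <- as.integer(srow + n * scol + 1L)

  geom <- list(
    rmax = rmax,
    radial_lin = radial_lin,
    radial_bin = radial_bin,
    ang_lin = ang_lin,
    ang_k = ang_k
  )
  profile_geometry_cache[[key]] <- geom
  geom
}
profile_geometry_cache <- new.env(parent = emptyenv())

#' Radial profile: magnitude sums over semicircles
#'
#' Sums the shifted magnitude spectrum over semicircular annuli centered on
#' the zero-frequency bin. A pixel in the upper half-plane (row index at or
#' above the center row, the zero-frequency bin itself excluded) contributes
#' to the bin `round(d)` of its Euclidean distance d to the center; bins run
#' 1..N/2 and farther corner pixels are discarded. One half-plane suffices
#' because the spectrum of a real image is conjugate-symmetric.
#'
#' @param mag Shifted N x N magnitude spectrum (N even).
#' @return Numeric vector of length N/2 (16 for the 32 x 32 input); entry
#'   `r` holds the sum for radius `r`.
#' @export
radial_sums <- function(mag) {
  check_mag(mag)
  g <- profile_geometry(nrow(mag))
  sums <- numeric(g$rmax)
  agg <- tapply(mag[g$radial_lin], g$radial_bin, sum)
  sums[as.integer(names(agg))] <- as.numeric(agg)
  sums
}

#' Angular profile: magnitude sums along radial lines
#'
#' Sums the shifted magnitude spectrum along 180 straight lines from the
#' spectrum center to the outer semicircle, one per degree. Line k (angle
#' `k * pi/180`, k = 0..179) is sampled at integer radii r = 1..N/2 at the
#' nearest pixel `(row = c - round(r sin), col = c + round(r cos))`; sample
#' indices are clamped into the grid, which affects only near-axis samples
#' at the outermost radius. Every (angle, radius) sample contributes exactly
#' once; pixels shared between neighboring lines are not deduplicated.
#'
#' @param mag Shifted N x N magnitude spectrum (N even).
#' @return Numeric vector of length 180.
#' @export
angular_sums <- function(mag) {
  check_mag(mag)
  g <- profile_geometry(nrow(mag))
  as.numeric(rowsum(mag[g$ang_lin], g$ang_k))
}

check_mag <- function(mag) {
  if (!is.matrix(mag) || !is.numeric(mag) || nrow(mag) != ncol(mag) ||
    nrow(mag) %% 2L != 0L) {
    abort("Expected a square numeric magnitude matrix with even side.",
      class = "patchfreq_bad_input"
    )
  }
  invisible(mag)
}

#' Summary statistics of a spectral profile
#'
#' The five per-profile statistics: mean, maximum, 0-based index of the
#' maximum (first index on ties), population variance (divide by length),
#' and range (max minus min).
#'
#' @param profile Numeric vector, length at least 1.
#' @return Named numeric vector `c(mean, max, argmax, var, range)`.
#' @export
#' @examples
#' profile_stats(c(1, 2, 3))
profile_stats <- function(profile) {
  if (length(profile) < 1L || !is.numeric(profile)) {
    abort("Profile must be a non-empty numeric vector.",
      class = "patchfreq_bad_input"
    )
  }
  m <- max(profile)
  c(
    mean = mean(profile),
    max = m,
    argmax = which.max(profile) - 1,
    var = mean((profile - mean(profile))^2),
    range = m - min(profile)
  )
}

#' The ten spectral features of a patch
#'
#' Full Fourier branch: 2D DFT, center shift, magnitude, radial and angular
#' profiles, and the five statistics of each profile. The result is ordered
#' radial-profile statistics first, then angular, each as
#' (mean, max, argmax, var, range).
#'
#' @param patch 32 x 32 numeric matrix (any even square side is accepted).
#' @return Named numeric vector of length 10 (`srad_*`, `sang_*`).
#' @export
#' @examples
#' spectral_features(matrix(runif(32 * 32), 32))
spectral_features <- function(patch) {
  mag <- magnitude(shift_center(dft2(patch)))
  out <- c(profile_stats(radial_sums(mag)), profile_stats(angular_sums(mag)))
  names(out) <- feature_names("fft")
  out
}
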