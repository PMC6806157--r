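#' One step of the 1D orthonormal Haar transform
#'
#' Splits an even-length signal into half-length approximation and detail
#' bands: `approx[i] = (x[2i] + x[2i+1])/sqrt(2)`,
#' `detail[i] = (x[2i] - x[2i+1])/sqrt(2)` (0-based pairs). The orthonormal
#' 1/sqrt(2) scaling preserves the sum of squares exactly, which makes
#' energy conservation across the full decomposition a testable identity.
#'
#' @param values Numeric vector of even length >= 2.
#' @return List with `approx` and `detail`, each half the input length.
#' @export
#' @examples
#' haar_step_1d(c(1, 1))
haar_step_1d <- function(values) {
  n <- length(values)
  if (n < 2L || n %% 2L != 0L) {
    abort("haar_step_1d() needs an even length >= 2.",
      class = "patchfreq_bad_input"
    )
  }
  odd <- values[seq(1L, n, by = 2L)]
  even <- values[seq(2L, n, by = 2L)]
  list(approx = (odd + even) / sqrt(2), detail = (odd - even) / sqrt(2))
}

# one separable 2D Haar level: rows first, then columns of the row result;
# returns the four quadrant channels of the decimated image
haar_level_2d <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  odd <- seq(1L, n, by = 2L)
  even <- seq(2L, n, by = 2L)
  # transform every row: left half approx, right half detail
  ra <- (x[, odd, drop = FALSE] + x[, even, drop = FALSE]) / sqrt(2)
  rd <- (x[, odd, drop = FALSE] - x[, even, drop = FALSE]) / sqrt(2)
  # then every column of both halves
  a <- (ra[odd, , drop = FALSE] + ra[even, , drop = FALSE]) / sqrt(2)
  hh <- (ra[odd, , drop = FALSE] - ra[even, , drop = FALSE]) / sqrt(2)
  v <- (rd[odd, , drop = FALSE] + rd[even, , drop = FALSE]) / sqrt(2)
  d <- (rd[odd, , drop = FALSE] - rd[even, , drop = FALSE]) / sqrt(2)
  list(A = a, H = hh, V = v, D = d)
}

#' Multi-level separable 2D Haar decomposition
#'
#' Decimates a square patch into 3 * levels + 1 channels. At each level the
#' rows are transformed first, then the columns of the row result (the
#' order matters for the transform type); the approximation channel is
#' recursed. Channel naming: `A<levels>` is the final approximation, and
#' `H<l>`, `V<l>`, `D<l>` carry the horizontal, vertical and diagonal edge
#' information of level l. With a 32-pixel side and 3 levels this yields 10
#' channels of sizes 4, 4, 4, 4, 8, 8, 8, 16, 16, 16.
#'
#' @param patch Square numeric matrix whose side is divisible by
#'   `2^levels`.
#' @param levels Number of decimation levels (default 3).
#' @return Named list of channel matrices, ordered
#'   `A3, H3, V3, D3, H2, V2, D2, H1, V1, D1` for `levels = 3`
#'   (approximation first, then details coarse-to-fine).
#' @export
#' @examples
#' names(haar_fwt2(matrix(runif(32 * 32), 32)))
haar_fwt2 <- function(patch, levels = 3L) {
  x <- unclass(patch)
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    abort("haar_fwt2() needs a square matrix.", class = "patchfreq_bad_input")
  }
  levels <- as.integer(levels)
  if (levels < 1L || nrow(x) %% (2L^levels) != 0L) {
    abort(
      paste0("Side ", nrow(x), " is not divisible by 2^", levels, "."),
      class = "patchfreq_bad_input"
    )
  }
  per_level <- vector("list", levels)
  for (l in seq_len(levels)) {
    step <- haar_level_2d(x)
    x <- step$A
    per_level[[l]] <- step[c("H", "V", "D")]
    names(per_level[[l]]) <- paste0(c("H", "V", "D"), l)
  }
  # approximation first, then detail triples from the coarsest level down
  out <- c(
    stats::setNames(list(x), paste0("A", levels)),
    unlist(rev(per_level), recursive = FALSE)
  )
  out
}

#' Mean absolute energy of a wavelet channel
#'
#' Subband energy \eqn{E = \frac{1}{NM} \sum_p |W(p)|} with N x M the
#' channel's own dimensions.
#'
#' @param channel Non-empty numeric matrix (or vector).
#' @return Non-negative scalar.
#' @export
channel_energy <- function(channel) {
  if (length(channel) < 1L || !is.numeric(channel)) {
    abort("channel_energy() needs a non-empty numeric channel.",
      class = "patchfreq_bad_input"
    )
  }
  mean(abs(channel))
}

#' The ten wavelet features of a patch
#'
#' Three-level Haar decomposition followed by the mean-absolute energy of
#' each of the 10 channels, in the canonical order
#' `A3, H3, V3, D3, H2, V2, D2, H1, V1, D1`.
#'
#' @param patch 32 x 32 numeric matrix (any side divisible by 8).
#' @return Named numeric vector of length 10 (`fwt_*`), all entries >= 0.
#' @export
#' @examples
#' wavelet_features(matrix(1, 32, 32))
wavelet_features <- function(patch) {
  dec <- haar_fwt2(patch, levels = 3L)
  out <- vapply(dec, channel_energy, numeric(1))
  names(out) <- feature_names("fwt")
  out
}
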