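#' Configuration of the synthetic patch generator
#'
#' Parameters of the seeded generator that emulates SPR sensor patches.
#' Positives are a Gaussian blob (the particle binding's intensity step)
#' surrounded by a radially decaying sinusoidal ring pattern (the wave-like
#' excitation around a binding); negatives mix featureless noise,
#' low-frequency plane-wave "vibration" patterns, and oriented streak
#' artifacts — the signal classes that cause false detections upstream.
#' All defaults are the package's own choices of plausible magnitudes;
#' they are exposed here precisely so they can be questioned.
#'
#' @param patch_size Side length of generated patches (detection-stage
#'   patches are 48; the classifier crops to 32).
#' @param blob_amplitude Range the blob peak amplitude is drawn from
#'   (intensity above background).
#' @param blob_sigma Range of the blob's Gaussian sigma, pixels.
#' @param ring_fraction Ring amplitude as a fraction of the blob
#'   amplitude.
#' @param ring_wavelength Range of the ring wavelength, pixels.
#' @param ring_decay Exponential decay length of the ring envelope,
#'   pixels.
#' @param background Background intensity level.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param negative_mix Probabilities of the three negative variants
#'   (pure noise, vibration sinusoid, linear streak); must sum to 1.
#' @param vibration_amplitude Range of the plane-sinusoid amplitude.
#' @param streak_amplitude Range of the streak amplitude.
#' @param streak_width Range of the streak Gaussian half-width, pixels.
#' @param center_jitter Maximum absolute offset of the blob center from
#'   the patch center, pixels (uniform in ±jitter).
#' @param balance Fraction of positive patches in a generated dataset.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A list of class `patchfreq_synth_config`.
#' @export
synth_config <- function(patch_size = 48L,
                         blob_amplitude = c(0.05, 0.25),
                         blob_sigma = c(2, 5),
                         ring_fraction = 0.4,
                         ring_wavelength = c(4, 10),
                         ring_decay = 8,
                         background = 0.5,
                         noise_sd = 0.02,
                         negative_mix = c(
                           noise = 0.5, vibration = 0.3,
                           streak = 0.2
                         ),
                         vibration_amplitude = c(0.02, 0.08),
                         streak_amplitude = c(0.05, 0.15),
                         streak_width = c(1, 3),
                         center_jitter = 3,
                         balance = 0.5,
                         seed = 1L) {
  cfg <- list(
    patch_size = as.integer(patch_size),
    blob_amplitude = blob_amplitude, blob_sigma = blob_sigma,
    ring_fraction = ring_fraction, ring_wavelength = ring_wavelength,
    ring_decay = ring_decay, background = background, noise_sd = noise_sd,
    negative_mix = negative_mix,
    vibration_amplitude = vibration_amplitude,
    streak_amplitude = streak_amplitude, streak_width = streak_width,
    center_jitter = center_jitter, balance = balance, seed = as.integer(seed)
  )
  if (cfg$patch_size < 8L) {
    abort("`patch_size` must be at least 8.", class = "patchfreq_bad_config")
  }
  if (length(cfg$negative_mix) != 3L ||
    abs(sum(cfg$negative_mix) - 1) > 1e-9 || any(cfg$negative_mix < 0)) {
    abort("`negative_mix` must be three non-negative fractions summing to 1.",
      class = "patchfreq_bad_config"
    )
  }
  if (cfg$balance < 0 || cfg$balance > 1) {
    abort("`balance` must lie in [0, 1].", class = "patchfreq_bad_config")
  }
  hi <- cfg$background + max(cfg$blob_amplitude) * (1 + cfg$ring_fraction)
  if (hi > 1.5) {
    abort("Amplitudes place pixel values far outside [0, 1].",
      class = "patchfreq_bad_config"
    )
  }
  structure(cfg, class = "patchfreq_synth_config")
}

draw_range <- function(range) {
  if (length(range) == 1L) range else runif(1L, range[1], range[2])
}

# distance of every pixel (0-based integer grid) to a given center
pixel_distances <- function(n, center) {
  rows <- matrix(0:(n - 1L), n, n)
  cols <- t(rows)
  sqrt((rows - center[1])^2 + (cols - center[2])^2)
}

#' Generate one synthetic positive patch
#'
#' A particle binding: Gaussian blob of amplitude A and width sigma on the
#' background, surrounded by a decaying ring pattern
#' `B exp(-d/tau) cos(2 pi d / lambda)` whose crest is aligned with the
#' blob center (B = `ring_fraction * A`), plus Gaussian noise, clamped to
#' \[0, 1\]. Blob parameters are drawn per patch from the config ranges;
#' the center is jittered around the patch center. Consumes the current
#' RNG stream — seed it (or use [generate_patches()]) for reproducibility.
#'
#' @param config A [synth_config()].
#' @return A `patch_size` x `patch_size` matrix in \[0, 1\].
#' @export
make_positive <- function(config = synth_config()) {
  n <- config$patch_size
  ctr <- (n - 1) / 2 + runif(2L, -config$center_jitter, config$center_jitter)
  a <- draw_range(config$blob_amplitude)
  sigma <- draw_range(config$blob_sigma)
  lambda <- draw_range(config$ring_wavelength)
  b <- config$ring_fraction * a
  d <- pixel_distances(n, ctr)
  img <- config$background +
    a * exp(-d^2 / (2 * sigma^2)) +
    b * exp(-d / config$ring_decay) * cos(2 * pi * d / lambda)
  finish_patch(img, config)
}

#' Generate one synthetic negative patch
#'
#' One of three artifact classes, drawn with the configured mix: pure
#' noise on the background; a low-amplitude plane sinusoid with an integer
#' number of cycles across the patch (sensor vibration); or an oriented
#' Gaussian-profile streak. Noise is added to every variant.
#'
#' @inheritParams make_positive
#' @param kind Force a specific variant (`"noise"`, `"vibration"`,
#'   `"streak"`) instead of drawing one from the mix.
#' @return A `patch_size` x `patch_size` matrix in \[0, 1\].
#' @export
make_negative <- function(config = synth_config(), kind = NULL) {
  n <- config$patch_size
  if (is.null(kind)) {
    kind <- sample(names(config$negative_mix), 1L, prob = config$negative_mix)
  }
  rows <- matrix(0:(n - 1L), n, n)
  cols <- t(rows)
  img <- matrix(config$background, n, n)
  if (kind == "vibration") {
    amp <- draw_range(config$vibration_amplitude)
    # integer cycle counts keep the pattern on an exact frequency bin
    fr <- sample(0:3, 1L)
    fc <- sample(0:3, 1L)
    if (fr == 0L && fc == 0L) fr <- sample(1:3, 1L)
    phase <- runif(1L, 0, 2 * pi)
    img <- img + amp * sin(2 * pi * (fr * rows + fc * cols) / n + phase)
  } else if (kind == "streak") {
    amp <- draw_range(config$streak_amplitude)
    width <- draw_range(config$streak_width)
    theta <- runif(1L, 0, pi)
    offset <- runif(1L, -n / 4, n / 4)
    ctr <- (n - 1) / 2
    # signed distance to a line through the (offset) center at angle theta
    dist <- (rows - ctr) * cos(theta) - (cols - ctr) * sin(theta) + offset
    img <- img + amp * exp(-dist^2 / (2 * width^2))
  } else if (kind != "noise") {
    abort("`kind` must be noise, vibration or streak.",
      class = "patchfreq_bad_config"
    )
  }
  finish_patch(img, config)
}

finish_patch <- function(img, config) {
  n <- config$patch_size
  if (config$noise_sd > 0) {
    img <- img + rnorm(n * n, sd = config$noise_sd)
  }
  as_patch(pmin(pmax(img, 0), 1))
}

#' Generate a labelled set of synthetic patches in memory
#'
#' Draws `n` patches with exactly `round(n * balance)` positives, shuffles
#' their order, and returns them with labels. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @param n Number of patches (>= 2).
#' @return List with `patches` (list of matrices) and `labels` (integer
#'   0/1 vector).
#' @export
generate_patches <- function(config = synth_config(), n) {
  if (n < 2L) {
    abort("`n` must be at least 2.", class = "patchfreq_bad_input")
  }
  n_pos <- round(n * config$balance)
  with_seed(config$seed, {
    labels <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
    patches <- lapply(labels, function(lab) {
      if (lab == 1L) make_positive(config) else make_negative(config)
    })
    list(patches = patches, labels = labels)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` 8-bit grayscale PNG patches plus a `manifest.csv`
#' (`path,label`) into `out_dir`. The 8-bit quantization deliberately
#' exercises the same normalization path real sensor patches take through
#' [read_patch()]. Byte-identical across runs with the same config.
#'
#' @inheritParams generate_patches
#' @param out_dir Output directory (created if missing).
#' @return The manifest tibble (`path`, `label`), with paths into
#'   `out_dir`; also written as `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(config = synth_config(), n, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste0("Cannot create output directory: ", out_dir),
      class = "patchfreq_bad_output"
    )
  }
  set <- generate_patches(config, n)
  paths <- file.path(out_dir, sprintf("patch_%05d.png", seq_len(n)))
  for (i in seq_len(n)) {
    write_patch(set$patches[[i]], paths[i], bits = 8L)
  }
  manifest <- tibble::tibble(path = paths, label = set$labels)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"),
    progress = FALSE
  )
  manifest
}
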