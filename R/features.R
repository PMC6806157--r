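#' Extract canonical feature vectors from patches
#'
#' Runs the Fourier and/or wavelet branches on each patch and assembles a
#' feature table with one row per patch. Inputs larger than 32 x 32 are
#' center-cropped first (never padded). `patches` may be a list of numeric
#' matrices or a manifest tibble with columns `path` and `label`, in which
#' case the images are read from disk.
#'
#' @param patches List of numeric matrices, or a manifest tibble
#'   (`path`, `label`) as returned by [load_manifest()].
#' @param features Which branch: `"both"` (20 features, default), `"fft"`
#'   (10 spectral) or `"fwt"` (10 wavelet energies).
#' @param labels Optional integer vector of 0/1 labels (ignored when
#'   `patches` is a manifest, which carries its own).
#' @param size Classifier input side; patches are center-cropped to
#'   `size` x `size` (default 32).
#' @return A tibble: optional `label` column plus one numeric column per
#'   feature, named per [feature_names()].
#' @export
#' @examples
#' pats <- replicate(3, matrix(runif(32 * 32), 32), simplify = FALSE)
#' extract_features(pats, features = "fwt")
extract_features <- function(patches, features = c("both", "fft", "fwt"),
                             labels = NULL, size = 32L) {
  features <- match.arg(features)
  if (is.data.frame(patches)) {
    labels <- patches$label
    patches <- lapply(patches$path, read_patch)
  }
  if (!is.list(patches) || length(patches) < 1L) {
    abort("`patches` must be a non-empty list of matrices or a manifest.",
      class = "patchfreq_bad_input"
    )
  }
  rows <- lapply(patches, function(p) {
    p <- center_crop(p, size)
    switch(features,
      both = c(spectral_features(p), wavelet_features(p)),
      fft = spectral_features(p),
      fwt = wavelet_features(p)
    )
  })
  tbl <- tibble::as_tibble(do.call(rbind, rows))
  if (!is.null(labels)) {
    if (length(labels) != nrow(tbl) || !all(labels %in% c(0L, 1L))) {
      abort("`labels` must be 0/1 and match the number of patches.",
        class = "patchfreq_bad_label"
      )
    }
    tbl <- dplyr::bind_cols(tibble::tibble(label = as.integer(labels)), tbl)
  }
  tbl
}
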