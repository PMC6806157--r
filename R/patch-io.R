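#' Read a grayscale patch from a PNG or TIFF file
#'
#' Reads a single-channel 8- or 16-bit image and returns its pixels as a
#' numeric matrix with intensities normalized to \[0, 1\] by the dtype
#' maximum (255 or 65535). The matrix is row-major with origin at the top
#' left, matching the on-screen orientation of the image.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix (class `patchfreq_patch`) with values in
#'   \[0, 1\].
#' @export
#' @examples
#' p <- tempfile(fileext = ".png")
#' write_patch(matrix(runif(32 * 32), 32), p)
#' patch <- read_patch(p)
#' range(patch)
read_patch <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    abort("`path` must be a single file path.", class = "patchfreq_bad_input")
  }
  if (!file.exists(path)) {
    abort(
      paste0("Patch file does not exist: ", path),
      class = "patchfreq_missing_file"
    )
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, info = TRUE)
      bps <- attr(x, "bits.per.sample")
      if (!is.null(bps) && !bps %in% c(8L, 16L)) {
        abort(
          paste0("Unsupported TIFF bit depth: ", bps, " (need 8 or 16)."),
          class = "patchfreq_bad_depth"
        )
      }
      x
    },
    abort(
      paste0("Unsupported image format: .", ext, " (need PNG or TIFF)."),
      class = "patchfreq_bad_format"
    )
  )
  if (length(dim(img)) == 3L) {
    # drop a trivial single channel; refuse genuine multi-channel images
    if (dim(img)[3] == 1L) {
      img <- img[, , 1L]
    } else {
      abort(
        paste0(
          "Expected a single-channel grayscale image, got ",
          dim(img)[3], " channels."
        ),
        class = "patchfreq_multichannel"
      )
    }
  }
  # readPNG/readTIFF divide by the dtype maximum, so values are already
  # in [0, 1]; guard against out-of-range data anyway
  if (anyNA(img) || min(img) < 0 || max(img) > 1) {
    abort("Pixel values outside [0, 1] after normalization.",
      class = "patchfreq_bad_pixels"
    )
  }
  as_patch(img)
}

#' Write a patch to a PNG or TIFF file
#'
#' Quantizes intensities in \[0, 1\] to the requested bit depth and writes a
#' single-channel grayscale image. Reading the file back with [read_patch()]
#' recovers each value to within half a quantization step.
#'
#' @param patch Numeric matrix with values in \[0, 1\].
#' @param path Output path; format chosen by extension (`.png`, `.tif(f)`).
#' @param bits Bit depth, 8 (default) or 16; PNG output is always 8-bit,
#'   16-bit output requires TIFF.
#' @return `path`, invisibly.
#' @export
write_patch <- function(patch, path, bits = 8L) {
  patch <- as_patch(patch)
  if (!bits %in% c(8L, 16L)) {
    abort("`bits` must be 8 or 16.", class = "patchfreq_bad_depth")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits != 8L) {
      abort("16-bit output is supported for TIFF only.",
        class = "patchfreq_bad_depth"
      )
    }
    png::writePNG(unclass(patch), target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(unclass(patch), where = path,
      bits.per.sample = as.integer(bits)
    )
  } else {
    abort(
      paste0("Unsupported image format: .", ext, " (need PNG or TIFF)."),
      class = "patchfreq_bad_format"
    )
  }
  invisible(path)
}

as_patch <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("A patch must be a numeric matrix.", class = "patchfreq_bad_input")
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    abort("A patch must have at least one row and column.",
      class = "patchfreq_bad_input"
    )
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 1) {
    abort("Patch intensities must lie in [0, 1].",
      class = "patchfreq_bad_pixels"
    )
  }
  class(x) <- c("patchfreq_patch", class(unclass(x)))
  x
}

#' Crop the central region of a patch
#'
#' Cuts a `size` x `size` window from the center of a patch, with the
#' top-left corner at offsets `(floor((H - size)/2), floor((W - size)/2))`.
#' Detection-stage patches (48 x 48) are reduced to the 32 x 32 classifier
#' input this way. Patches smaller than `size` are an error: the input is
#' never padded, because zero-padding introduces spectral interpolation
#' artifacts that measurably degrade Fourier-feature classification.
#'
#' @param patch Numeric matrix.
#' @param size Side length of the output (default 32).
#' @return A `size` x `size` matrix with values copied unchanged.
#' @export
#' @examples
#' center_crop(matrix(runif(48 * 48), 48))[1:2, 1:2]
center_crop <- function(patch, size = 32L) {
  patch <- as_patch(patch)
  size <- as.integer(size)
  h <- nrow(patch)
  w <- ncol(patch)
  if (h < size || w < size) {
    abort(
      paste0(
        "Patch (", h, "x", w, ") is smaller than the crop size ", size,
        "; padding is not supported."
      ),
      class = "patchfreq_too_small"
    )
  }
  r0 <- (h - size) %/% 2L
  c0 <- (w - size) %/% 2L
  as_patch(patch[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size), drop = FALSE])
}

#' Load a dataset manifest
#'
#' Reads a CSV with header `path,label` listing patch image files and their
#' expert labels (1 = particle binding present, 0 = none). Rows are kept in
#' file order.
#'
#' @param path Manifest CSV path.
#' @return A tibble with columns `path` (character) and `label` (integer,
#'   0/1).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Manifest does not exist: ", path),
      class = "patchfreq_missing_file"
    )
  }
  df <- readr::read_csv(path,
    col_types = readr::cols(
      path = readr::col_character(),
      label = readr::col_double()
    ),
    progress = FALSE
  )
  if (!identical(names(df), c("path", "label"))) {
    abort("Manifest must have exactly the columns `path,label`.",
      class = "patchfreq_bad_manifest"
    )
  }
  if (nrow(df) > 0) {
    if (anyNA(df$path) || anyNA(df$label) || any(!nzchar(df$path))) {
      abort("Manifest rows must have a non-empty path and a label.",
        class = "patchfreq_bad_manifest"
      )
    }
    if (!all(df$label %in% c(0, 1))) {
      abort("Manifest labels must be 0 or 1.",
        class = "patchfreq_bad_label"
      )
    }
  }
  dplyr::mutate(df, label = as.integer(.data$label))
}

#' Write and read feature tables
#'
#' A feature table is a tibble with one row per patch: an optional `label`
#' column (0/1) followed by one numeric column per feature. The CSV
#' round-trip preserves values to full double precision (better than 12
#' significant digits) and preserves column and row order.
#'
#' @param table Feature table tibble (feature columns, optional `label`).
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(table, path) {
  check_feature_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Feature table does not exist: ", path),
      class = "patchfreq_missing_file"
    )
  }
  header <- strsplit(readr::read_lines(path, n_max = 1L), ",")[[1]]
  if (anyDuplicated(header)) {
    abort("Feature table has duplicate column names.",
      class = "patchfreq_bad_table"
    )
  }
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  )
  if ("label" %in% names(df)) {
    df <- dplyr::mutate(df, label = as.integer(.data$label))
  }
  check_feature_table(df)
  df
}

check_feature_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) < 1L) {
    abort("Feature table must be a data frame with at least one row.",
      class = "patchfreq_bad_table"
    )
  }
  feat <- setdiff(names(table), "label")
  if (length(feat) < 1L) {
    abort("Feature table must have at least one feature column.",
      class = "patchfreq_bad_table"
    )
  }
  if (anyDuplicated(names(table))) {
    abort("Feature table has duplicate column names.",
      class = "patchfreq_bad_table"
    )
  }
  ok <- vapply(table[feat], is.numeric, logical(1))
  if (!all(ok)) {
    abort("Feature columns must be numeric.", class = "patchfreq_bad_table")
  }
  if ("label" %in% names(table) && !all(table$label %in% c(0L, 1L))) {
    abort("Labels must be 0 or 1.", class = "patchfreq_bad_label")
  }
  invisible(table)
}

# split a feature table into the numeric matrix + labels the learners use
table_to_matrix <- function(table) {
  check_feature_table(table)
  feat <- setdiff(names(table), "label")
  list(
    x = as.matrix(table[feat]),
    y = if ("label" %in% names(table)) as.integer(table$label) else NULL,
    names = feat
  )
}
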