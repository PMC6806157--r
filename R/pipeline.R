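# extract only the features an extraction plan produces, canonical order
extract_planned <- function(patch, plan) {
  vals <- numeric(0)
  if (any(c("radial_sums", "angular_sums") %in% plan)) {
    mag <- magnitude(shift_center(dft2(patch)))
    if ("radial_sums" %in% plan) {
      vals <- c(vals, profile_stats(radial_sums(mag)))
    }
    if ("angular_sums" %in% plan) {
      vals <- c(vals, profile_stats(angular_sums(mag)))
    }
  }
  if ("energies" %in% plan) {
    vals <- c(vals, unname(wavelet_features(patch)))
  }
  names(vals) <- feature_names("both")[plan_feature_indices(plan) + 1L]
  vals
}

#' Classify a single patch end to end
#'
#' The deployment path: center-crop the patch to the classifier input
#' size, run the extraction stages of `plan`, and predict with the model.
#' A 48 x 48 detection patch and its pre-cropped 32 x 32 center give
#' identical results. The model must have been trained on exactly the
#' features the plan produces, in canonical order.
#'
#' @param patch Numeric matrix, side >= 32.
#' @param model A `patchfreq_tree` or `patchfreq_forest`.
#' @param plan An [extraction_plan()]; defaults to all 20 features.
#' @return Class 0 or 1.
#' @export
classify_patch <- function(patch, model, plan = extraction_plan(0:19)) {
  feats <- extract_planned(center_crop(patch, 32L), plan)
  if (length(feats) != model$n_features) {
    abort(
      paste0(
        "Plan produces ", length(feats), " features but the model expects ",
        model$n_features, "."
      ),
      class = "patchfreq_dim_mismatch"
    )
  }
  predict(model, unname(feats))[1L]
}

benchmark_stage_labels <- c("Transf.", "PT", "Sum", "DT", "Total")

#' Benchmark feature extraction and classification
#'
#' Times the extraction stages on seeded uniform-random grayscale patches:
#' `batches` batches of `batch_size` images each are generated and every
#' image is pushed through the plan's stages. Times are wall-clock
#' (monotonic high-resolution clock), reported in nanoseconds per image,
#' decomposed into transform (`Transf.`: DFT and/or Haar), post-transform
#' (`PT`: shift and magnitude), summing (`Sum`: profiles, statistics,
#' energies) and tree (`DT`: prediction, if a model is supplied). Absolute
#' values are informational only — they depend entirely on the host.
#'
#' @param plan An [extraction_plan()].
#' @param batch_size Images per batch (default 25).
#' @param batches Number of batches (default 40; defaults give 1000 runs).
#' @param model Optional model to time prediction with.
#' @param seed Seed for the random images.
#' @param size Image side (default 32, the extractor input size).
#' @return A tibble of class `patchfreq_benchmark`: `stage`, `mean_ns`,
#'   `sd_ns`, with attribute `runs = batches * batch_size`.
#' @export
run_benchmark <- function(plan = extraction_plan(0:19), batch_size = 25L,
                          batches = 40L, model = NULL, seed = 1L,
                          size = 32L) {
  if (batch_size < 1L || batches < 1L) {
    abort("`batch_size` and `batches` must be >= 1.",
      class = "patchfreq_bad_input"
    )
  }
  fft_needed <- any(c("radial_sums", "angular_sums") %in% plan)
  fwt_needed <- "energies" %in% plan
  per_batch <- matrix(0, nrow = batches, ncol = 4L)
  tick <- function() Sys.time()
  with_seed(seed, {
    for (b in seq_len(batches)) {
      imgs <- replicate(batch_size, matrix(runif(size * size), size, size),
        simplify = FALSE
      )
      acc <- numeric(4L)
      for (img in imgs) {
        t0 <- tick()
        spec <- if (fft_needed) dft2(img) else NULL
        dec <- if (fwt_needed) haar_fwt2(img) else NULL
        t1 <- tick()
        mag <- if (fft_needed) magnitude(shift_center(spec)) else NULL
        t2 <- tick()
        feats <- numeric(0)
        if (fft_needed) {
          if ("radial_sums" %in% plan) {
            feats <- c(feats, profile_stats(radial_sums(mag)))
          }
          if ("angular_sums" %in% plan) {
            feats <- c(feats, profile_stats(angular_sums(mag)))
          }
        }
        if (fwt_needed) {
          feats <- c(feats, vapply(dec, channel_energy, numeric(1)))
        }
        t3 <- tick()
        if (!is.null(model)) {
          predict(model, unname(feats))
        }
        t4 <- tick()
        acc <- acc + as.numeric(c(t1 - t0, t2 - t1, t3 - t2, t4 - t3))
      }
      per_batch[b, ] <- acc / batch_size * 1e9
    }
  })
  means <- colMeans(per_batch)
  sds <- if (batches > 1L) apply(per_batch, 2L, sd) else rep(NA_real_, 4L)
  total_per_batch <- rowSums(per_batch)
  out <- tibble::tibble(
    stage = benchmark_stage_labels,
    mean_ns = c(means, mean(total_per_batch)),
    sd_ns = c(sds, if (batches > 1L) sd(total_per_batch) else NA_real_)
  )
  attr(out, "runs") <- batches * batch_size
  class(out) <- c("patchfreq_benchmark", class(out))
  out
}

#' @export
print.patchfreq_benchmark <- function(x, ...) {
  cat("<patchfreq_benchmark>", attr(x, "runs"), "runs\n")
  NextMethod()
}

#' Run the full synthetic pipeline in one call
#'
#' Generates a synthetic dataset, splits it, extracts features for the
#' train and test halves through the same code path, trains a tree (or a
#' forest when `config$n_trees > 1` and `model = "forest"`), and evaluates
#' on the held-out half. Everything derives from the generator seed, so
#' repeated calls are bit-identical. Note that features must be extracted
#' on the platform where the classifier will run: the profile sums
#' accumulate thousands of floating-point terms and platform-specific
#' rounding can move values across learned thresholds.
#'
#' @param synth A [synth_config()] (its `seed` drives everything).
#' @param n Number of patches to generate (default 4000).
#' @param split Fraction of patches used for training (default 0.7).
#' @param features Feature set: `"both"`, `"fft"` or `"fwt"`.
#' @param config A [train_config()].
#' @param model `"tree"` (default) or `"forest"`.
#' @param quiet Suppress per-stage log lines.
#' @return A list of class `patchfreq_report`: `metrics` (one-row tibble
#'   from [evaluate_model()]), `model`, `train`, `test` (feature tables),
#'   `features`, `n_train`, `n_test`.
#' @export
end_to_end <- function(synth = synth_config(), n = 4000L, split = 0.7,
                       features = c("both", "fft", "fwt"),
                       config = train_config(), model = c("tree", "forest"),
                       quiet = FALSE) {
  features <- match.arg(features)
  model <- match.arg(model)
  say <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", paste0(...))
  }
  say("synth", "generating ", n, " patches (seed ", synth$seed, ")")
  set <- generate_patches(synth, n)
  n_train <- floor(n * split)
  if (n_train < 1L || n_train >= n) {
    abort("`split` leaves an empty train or test set.",
      class = "patchfreq_bad_config"
    )
  }
  idx_train <- seq_len(n_train)
  say("extract", "features = ", features, ", train n = ", n_train,
    ", test n = ", n - n_train
  )
  tr <- extract_features(set$patches[idx_train],
    features = features, labels = set$labels[idx_train]
  )
  te <- extract_features(set$patches[-idx_train],
    features = features, labels = set$labels[-idx_train]
  )
  say("train", model, ", max_depth = ", config$max_depth)
  fit <- if (model == "forest") train_forest(tr, config) else train_tree(tr, config)
  metrics <- evaluate_model(fit, te)
  say(
    "evaluate", "accuracy = ", sprintf("%.4f", metrics$accuracy),
    ", precision = ", sprintf("%.4f", metrics$precision),
    ", recall = ", sprintf("%.4f", metrics$recall)
  )
  structure(
    list(
      metrics = metrics, model = fit, train = tr, test = te,
      features = features, n_train = n_train, n_test = n - n_train
    ),
    class = "patchfreq_report"
  )
}

#' @export
print.patchfreq_report <- function(x, ...) {
  cat(
    "<patchfreq_report>", x$features, "features, train", x$n_train,
    "/ test", x$n_test, "\n"
  )
  print(x$metrics)
  invisible(x)
}
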