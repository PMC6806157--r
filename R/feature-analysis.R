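#' Rank features by PCA explained variance
#'
#' Standardizes each feature to zero mean and unit deviation (constant
#' columns become all-zero and carry no variance), runs a principal
#' component analysis, and scores feature i as
#' \deqn{s_i = \sum_j \mathrm{EVR}_j \cdot L_{ij}^2}
#' where \eqn{\mathrm{EVR}_j} is component j's explained-variance ratio and
#' \eqn{L_{ij}} its loading on feature i — the share of total variance the
#' feature accounts for across the principal axes. Features are returned
#' most-important first; ties break toward the smaller column index.
#'
#' @param table Feature table tibble (a `label` column, if present, is
#'   ignored for the ranking).
#' @return A tibble of class `patchfreq_ranking`, one row per feature in
#'   rank order: `rank`, `index` (0-based canonical position in `table`),
#'   `feature` (name), `score`.
#' @export
rank_features_pca <- function(table) {
  m <- table_to_matrix(table)
  x <- m$x
  if (nrow(x) < 2L) {
    abort("PCA ranking needs at least two rows.", class = "patchfreq_bad_input")
  }
  mu <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  z <- sweep(x, 2L, mu)
  keep <- s > 0
  z[, keep] <- sweep(z[, keep, drop = FALSE], 2L, s[keep], "/")
  z[, !keep] <- 0
  p <- prcomp(z, center = FALSE, scale. = FALSE)
  evr <- p$sdev^2 / sum(p$sdev^2)
  scores <- as.numeric(p$rotation^2 %*% evr)
  ord <- order(-scores, seq_along(scores))
  out <- tibble::tibble(
    rank = seq_along(ord),
    index = ord - 1L,
    feature = m$names[ord],
    score = scores[ord]
  )
  class(out) <- c("patchfreq_ranking", class(out))
  out
}

#' Incremental-subset accuracy curve
#'
#' For k = 1..d trains a tree on the k highest-ranked features of the
#' training table and records its accuracy on the held-out test table —
#' the standard diagnostic for deciding how many features are worth
#' extracting. A single fixed train/test split is used (no
#' cross-validation), matching how the classifier is deployed.
#'
#' @param train,test Labelled feature tables over the same feature space.
#' @param ranking A [rank_features_pca()] result for that feature space.
#' @param config A [train_config()].
#' @return A tibble of class `patchfreq_curve` with columns `k` (1..d) and
#'   `accuracy`.
#' @export
accuracy_curve <- function(train, test, ranking, config = train_config()) {
  m_tr <- table_to_matrix(train)
  if (is.null(m_tr$y) || !"label" %in% names(test)) {
    abort("Both tables need a `label` column.", class = "patchfreq_bad_label")
  }
  if (!setequal(ranking$feature, m_tr$names) ||
    !all(ranking$feature %in% names(test))) {
    abort("Ranking does not match the tables' feature space.",
      class = "patchfreq_dim_mismatch"
    )
  }
  d <- length(m_tr$names)
  acc <- vapply(seq_len(d), function(k) {
    feats <- ranking$feature[seq_len(k)]
    fit <- train_tree(train[c("label", feats)], config)
    accuracy(confusion(predict(fit, test[feats]), test$label))
  }, numeric(1))
  out <- tibble::tibble(k = seq_len(d), accuracy = acc)
  class(out) <- c("patchfreq_curve", class(out))
  out
}

# canonical stage graph: which pipeline stages produce which canonical
# feature indices, and what they depend on
extraction_stages <- function() {
  list(
    dft2 = character(0),
    shift = "dft2",
    magnitude = "shift",
    radial_sums = "magnitude",
    angular_sums = "magnitude",
    haar_fwt2 = character(0),
    energies = "haar_fwt2"
  )
}

#' Minimal extraction plan for a feature subset
#'
#' Given canonical feature indices (0..19), returns the smallest
#' dependency-closed set of extraction stages that produces exactly those
#' features. Radial-profile statistics (indices 0-4) need the Fourier
#' branch up to `radial_sums`; angular statistics (5-9) additionally need
#' `angular_sums`; wavelet energies (10-19) need only `haar_fwt2` and
#' `energies`. Dropping the angular profile removes the most expensive
#' summation stage, which is the main lever for trading accuracy against
#' extraction time.
#'
#' @param selected Integer vector of canonical feature indices in 0..19.
#' @return Character vector of stage names (class
#'   `patchfreq_extraction_plan`), in canonical pipeline order, a subset of
#'   `dft2, shift, magnitude, radial_sums, angular_sums, haar_fwt2,
#'   energies`.
#' @export
#' @examples
#' extraction_plan(0:4) # radial statistics only: no angular_sums
extraction_plan <- function(selected) {
  selected <- unique(as.integer(selected))
  if (length(selected) == 0L) {
    abort("At least one feature must be selected.",
      class = "patchfreq_bad_input"
    )
  }
  if (any(selected < 0L | selected > 19L)) {
    abort("Feature indices must lie in 0..19.", class = "patchfreq_bad_input")
  }
  stages <- character(0)
  if (any(selected <= 4L)) stages <- c(stages, "radial_sums")
  if (any(selected >= 5L & selected <= 9L)) {
    stages <- c(stages, "angular_sums")
  }
  if (any(selected >= 10L)) stages <- c(stages, "energies")
  # close under dependencies
  graph <- extraction_stages()
  repeat {
    deps <- unique(unlist(graph[stages]))
    grown <- union(stages, deps)
    if (setequal(grown, stages)) break
    stages <- grown
  }
  out <- intersect(names(graph), stages) # canonical order
  class(out) <- c("patchfreq_extraction_plan", class(out))
  out
}

# canonical 0-based feature indices a plan produces, in canonical order
plan_feature_indices <- function(plan) {
  idx <- integer(0)
  if ("radial_sums" %in% plan) idx <- c(idx, 0:4)
  if ("angular_sums" %in% plan) idx <- c(idx, 5:9)
  if ("energies" %in% plan) idx <- c(idx, 10:19)
  sort(idx)
}

#' @export
print.patchfreq_extraction_plan <- function(x, ...) {
  cat("<extraction plan>", paste(unclass(x), collapse = " -> "), "\n")
  invisible(x)
}
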