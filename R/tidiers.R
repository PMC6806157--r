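#' Tidy a trained tree into its node table
#'
#' One row per node: `id`, `is_leaf`, `feature` (0-based index into the
#' training feature order, `NA` for leaves), `feature_name`, `threshold`,
#' `left`/`right` child ids, `class` (leaves) and `depth`.
#'
#' @param x A `patchfreq_tree`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy patchfreq_tree
#' @export
tidy.patchfreq_tree <- function(x, ...) {
  dplyr::mutate(
    x$nodes,
    feature_name = ifelse(is.na(.data$feature), NA_character_,
      x$feature_names[.data$feature + 1L]
    ),
    .after = "feature"
  )
}

#' @rdname tidy.patchfreq_tree
#' @method tidy patchfreq_forest
#' @export
tidy.patchfreq_forest <- function(x, ...) {
  dplyr::bind_rows(lapply(x$trees, tidy), .id = "tree")
}

#' One-row summary of a trained tree or forest
#'
#' @param x A `patchfreq_tree` or `patchfreq_forest`.
#' @param ... Unused.
#' @return A tibble with `n_nodes`, `n_leaves`, `depth`, `max_depth`,
#'   `n_features` (and `n_trees` for forests).
#' @method glance patchfreq_tree
#' @export
glance.patchfreq_tree <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_leaves = sum(x$nodes$is_leaf),
    depth = tree_depth(x),
    max_depth = x$config$max_depth,
    n_features = x$n_features
  )
}

#' @rdname glance.patchfreq_tree
#' @method glance patchfreq_forest
#' @export
glance.patchfreq_forest <- function(x, ...) {
  per_tree <- dplyr::bind_rows(lapply(x$trees, glance))
  tibble::tibble(
    n_trees = x$n_trees,
    n_nodes = sum(per_tree$n_nodes),
    n_leaves = sum(per_tree$n_leaves),
    depth = max(per_tree$depth),
    max_depth = x$config$max_depth,
    n_features = x$n_features
  )
}
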