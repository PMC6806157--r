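MODEL_FORMAT <- "patchfreq-model"
MODEL_VERSION <- 1L

#' Save and load trained models as JSON
#'
#' Serializes a tree or forest to a versioned JSON schema. Thresholds are
#' written with 17 significant digits, which reconstructs the exact IEEE
#' double on load, so a save/load round-trip predicts identically to the
#' original model on every input.
#'
#' @param model A `patchfreq_tree` or `patchfreq_forest`.
#' @param path JSON file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  payload <- if (inherits(model, "patchfreq_tree")) {
    list(type = "tree", model = tree_payload(model))
  } else if (inherits(model, "patchfreq_forest")) {
    list(
      type = "forest", n_trees = model$n_trees,
      model = lapply(model$trees, tree_payload)
    )
  } else {
    abort("save_model() needs a patchfreq_tree or patchfreq_forest.",
      class = "patchfreq_bad_model"
    )
  }
  payload <- c(
    list(
      format = MODEL_FORMAT, version = MODEL_VERSION,
      feature_names = model$feature_names,
      config = unclass(model$config)
    ),
    payload
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = I(17), null = "null", na = "null"
  )
  invisible(path)
}

tree_payload <- function(tree) {
  list(root = tree$root, nodes = tree$nodes)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Model file does not exist: ", path),
      class = "patchfreq_missing_file"
    )
  }
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      abort(paste0("Cannot parse model JSON: ", conditionMessage(e)),
        class = "patchfreq_bad_model"
      )
    }
  )
  if (!identical(payload$format, MODEL_FORMAT)) {
    abort("Not a patchfreq model file.", class = "patchfreq_bad_model")
  }
  if (!identical(as.integer(payload$version), MODEL_VERSION)) {
    abort(
      paste0(
        "Unsupported model version ", payload$version,
        " (this build reads version ", MODEL_VERSION, ")."
      ),
      class = "patchfreq_bad_version"
    )
  }
  config <- do.call(
    train_config,
    payload$config[c("max_depth", "n_trees", "seed", "criterion")]
  )
  feats <- as.character(payload$feature_names)
  if (identical(payload$type, "tree")) {
    rebuild_tree(payload$model, feats, config)
  } else if (identical(payload$type, "forest")) {
    # simplifyVector collapses the tree list into a data frame with a
    # list-column of node tables; support both shapes
    tree_payloads <- if (is.data.frame(payload$model)) {
      lapply(seq_len(nrow(payload$model)), function(i) {
        list(root = payload$model$root[[i]], nodes = payload$model$nodes[[i]])
      })
    } else {
      payload$model
    }
    trees <- lapply(tree_payloads, rebuild_tree, feats = feats, config = config)
    structure(
      list(
        trees = trees, n_trees = length(trees), feature_names = feats,
        n_features = length(feats), config = config
      ),
      class = "patchfreq_forest"
    )
  } else {
    abort("Unknown model type.", class = "patchfreq_bad_model")
  }
}

rebuild_tree <- function(payload, feats, config) {
  nodes <- tibble::as_tibble(payload$nodes)
  needed <- c(
    "id", "is_leaf", "feature", "threshold", "left", "right",
    "class", "depth"
  )
  if (!all(needed %in% names(nodes))) {
    abort("Model node table is missing fields.", class = "patchfreq_bad_model")
  }
  nodes <- dplyr::mutate(
    nodes,
    dplyr::across(c("id", "feature", "left", "right", "class", "depth"),
      as.integer
    ),
    is_leaf = as.logical(.data$is_leaf),
    threshold = as.numeric(.data$threshold)
  )
  structure(
    list(
      nodes = nodes, root = as.integer(payload$root), feature_names = feats,
      n_features = length(feats), config = config
    ),
    class = "patchfreq_tree"
  )
}
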