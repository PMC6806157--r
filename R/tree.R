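#' Training configuration for trees and forests
#'
#' Bundles the training hyperparameters. The default depth cap of 12 keeps
#' single-prediction latency negligible on embedded targets while costing
#' little accuracy; deeper trees buy no clear benefit for this problem.
#'
#' @param max_depth Maximum tree depth (root at depth 0); default 12.
#' @param n_trees Number of bagged trees for [train_forest()] (typical
#'   choices 1, 10 or 100); default 10.
#' @param seed Integer seed controlling bootstrap resampling; training is a
#'   pure function of (data, config).
#' @param criterion Split impurity; only `"gini"` is implemented.
#' @return A list of class `patchfreq_config`.
#' @export
train_config <- function(max_depth = 12L, n_trees = 10L, seed = 1L,
                         criterion = "gini") {
  max_depth <- as.integer(max_depth)
  if (is.na(max_depth) || max_depth < 1L) {
    abort("`max_depth` must be a positive integer.",
      class = "patchfreq_bad_config"
    )
  }
  if (!identical(criterion, "gini")) {
    abort("Only the Gini criterion is implemented.",
      class = "patchfreq_bad_config"
    )
  }
  structure(
    list(
      max_depth = max_depth, n_trees = as.integer(n_trees),
      seed = as.integer(seed), criterion = criterion
    ),
    class = "patchfreq_config"
  )
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Greedy binary CART on a numeric matrix. Splits minimize the weighted
# Gini impurity of the children; candidate thresholds are midpoints
# between consecutive distinct sorted values. A node splits whenever it is
# impure, below the depth cap, and at least one feature varies — zero-gain
# splits are allowed (required e.g. for XOR-structured data, where every
# depth-1 split is gain-free but depth 2 separates perfectly). Ties are
# broken toward the smaller feature index, then the smaller threshold.
grow_tree <- function(x, y, max_depth) {
  nodes <- list()
  n_nodes <- 0L

  new_node <- function(rec) {
    n_nodes <<- n_nodes + 1L
    rec$id <- n_nodes
    nodes[[n_nodes]] <<- rec
    n_nodes
  }

  best_split <- function(idx) {
    best <- NULL
    yi <- y[idx]
    n <- length(idx)
    for (j in seq_len(ncol(x))) {
      xs <- x[idx, j]
      o <- order(xs)
      xs <- xs[o]
      ys <- yi[o]
      cut <- which(xs[-n] < xs[-1L]) # split after these sorted positions
      if (length(cut) == 0L) next
      n_l <- cut
      n_r <- n - cut
      pos_l <- cumsum(ys)[cut]
      pos_r <- sum(ys) - pos_l
      g_l <- 1 - (pos_l / n_l)^2 - ((n_l - pos_l) / n_l)^2
      g_r <- 1 - (pos_r / n_r)^2 - ((n_r - pos_r) / n_r)^2
      g <- (n_l * g_l + n_r * g_r) / n
      k <- which.min(g) # first (smallest threshold) on ties
      if (is.null(best) || g[k] < best$gini) {
        best <- list(
          gini = g[k], feature = j,
          threshold = (xs[cut[k]] + xs[cut[k] + 1L]) / 2
        )
      }
    }
    best
  }

  grow <- function(idx, depth) {
    yi <- y[idx]
    n_pos <- sum(yi)
    maj <- if (n_pos > length(yi) - n_pos) 1L else 0L # tie -> negative class
    pure <- n_pos == 0L || n_pos == length(yi)
    split <- if (!pure && depth < max_depth) best_split(idx) else NULL
    if (is.null(split)) {
      return(new_node(list(
        is_leaf = TRUE, feature = NA_integer_, threshold = NA_real_,
        left = NA_integer_, right = NA_integer_, class = maj, depth = depth
      )))
    }
    go_left <- x[idx, split$feature] <= split$threshold
    left <- grow(idx[go_left], depth + 1L)
    right <- grow(idx[!go_left], depth + 1L)
    new_node(list(
      is_leaf = FALSE, feature = split$feature - 1L, # 0-based in the model
      threshold = split$threshold, left = left, right = right,
      class = NA_integer_, depth = depth
    ))
  }

  root <- grow(seq_along(y), 0L)
  list(nodes = nodes, root = root)
}

#' Train a depth-limited decision tree
#'
#' Greedy binary CART with the Gini criterion on a labelled feature table.
#' Internal nodes route an observation left when
#' `feature value <= threshold`; thresholds are midpoints between observed
#' values and are kept at full double precision, because classifications
#' near a threshold are sensitive to platform-level floating-point
#' differences and a rounded exported tree would not reproduce the trained
#' one. Training is deterministic: the same table and config always yield
#' the same tree.
#'
#' @param table Feature table tibble with a `label` column (0/1).
#' @param config A [train_config()].
#' @return An object of class `patchfreq_tree` with a node table (tibble:
#'   `id`, `is_leaf`, `feature` (0-based), `threshold`, `left`, `right`,
#'   `class`, `depth`), the feature names seen at training, and the config.
#' @export
#' @examples
#' tbl <- tibble::tibble(label = c(0L, 1L), f1 = c(0, 1))
#' fit <- train_tree(tbl, train_config(max_depth = 1))
#' predict(fit, tbl)
train_tree <- function(table, config = train_config()) {
  m <- table_to_matrix(table)
  if (is.null(m$y)) {
    abort("Training requires a `label` column.", class = "patchfreq_bad_label")
  }
  grown <- grow_tree(m$x, m$y, config$max_depth)
  nodes <- dplyr::bind_rows(lapply(grown$nodes, tibble::as_tibble))
  nodes <- dplyr::arrange(nodes, .data$id)
  structure(
    list(
      nodes = nodes, root = grown$root, feature_names = m$names,
      n_features = length(m$names), config = config
    ),
    class = "patchfreq_tree"
  )
}

#' Depth of a trained tree
#'
#' Maximum node depth over all nodes (a single-leaf tree has depth 0).
#'
#' @param model A `patchfreq_tree` or `patchfreq_forest`.
#' @return Integer depth.
#' @export
tree_depth <- function(model) {
  if (inherits(model, "patchfreq_forest")) {
    return(max(vapply(model$trees, tree_depth, integer(1))))
  }
  max(model$nodes$depth)
}

# feature matrix from newdata in the model's training column order
newdata_matrix <- function(model, newdata) {
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L)
  }
  if (is.data.frame(newdata)) {
    missing <- setdiff(model$feature_names, names(newdata))
    if (length(missing) > 0L) {
      abort(
        paste0(
          "newdata lacks training features: ",
          paste(missing, collapse = ", ")
        ),
        class = "patchfreq_dim_mismatch"
      )
    }
    newdata <- as.matrix(newdata[model$feature_names])
  }
  if (ncol(newdata) != model$n_features) {
    abort(
      paste0(
        "Feature dimension mismatch: model expects ", model$n_features,
        ", got ", ncol(newdata), "."
      ),
      class = "patchfreq_dim_mismatch"
    )
  }
  newdata
}

descend <- function(nodes, root, xrow) {
  i <- root
  while (!nodes$is_leaf[i]) {
    i <- if (xrow[nodes$feature[i] + 1L] <= nodes$threshold[i]) {
      nodes$left[i]
    } else {
      nodes$right[i]
    }
  }
  nodes$class[i]
}

#' Predict classes with a trained tree
#'
#' Root-to-leaf descent; an observation goes left when its feature value is
#' less than or equal to the node threshold.
#'
#' @param object A `patchfreq_tree`.
#' @param newdata Feature table tibble, numeric matrix, or a single
#'   numeric vector; columns must match the training features.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions.
#' @export
predict.patchfreq_tree <- function(object, newdata, ...) {
  xm <- newdata_matrix(object, newdata)
  out <- integer(nrow(xm))
  for (i in seq_len(nrow(xm))) {
    out[i] <- descend(object$nodes, object$root, xm[i, ])
  }
  out
}

#' @export
print.patchfreq_tree <- function(x, ...) {
  cat(
    "<patchfreq_tree> depth", tree_depth(x), "/", x$config$max_depth,
    "-", nrow(x$nodes), "nodes,", sum(x$nodes$is_leaf), "leaves,",
    x$n_features, "features\n"
  )
  invisible(x)
}

#' Train a bagged forest of depth-limited trees
#'
#' Trains `config$n_trees` CART trees, each on a bootstrap resample of the
#' rows (drawn with replacement, sized like the input). All features are
#' available at every split; the ensemble averages over resampling only.
#' The bootstrap draws come from a private RNG stream seeded with
#' `config$seed`, so the same (table, config) always reproduces the same
#' forest.
#'
#' @inheritParams train_tree
#' @return An object of class `patchfreq_forest` (list of
#'   `patchfreq_tree`).
#' @export
train_forest <- function(table, config = train_config()) {
  m <- table_to_matrix(table)
  if (is.null(m$y)) {
    abort("Training requires a `label` column.", class = "patchfreq_bad_label")
  }
  if (config$n_trees < 1L) {
    abort("`n_trees` must be >= 1.", class = "patchfreq_bad_config")
  }
  n <- nrow(table)
  boots <- with_seed(
    config$seed,
    replicate(config$n_trees, sample.int(n, n, replace = TRUE),
      simplify = FALSE
    )
  )
  trees <- lapply(boots, function(idx) train_tree(table[idx, ], config))
  structure(
    list(
      trees = trees, n_trees = config$n_trees,
      feature_names = m$names, n_features = length(m$names), config = config
    ),
    class = "patchfreq_forest"
  )
}

#' Predict classes with a forest (majority vote)
#'
#' Each tree votes; the majority class wins. Vote ties return class 0
#' ("no particle"): in a screening setting the conservative default on an
#' undecided patch is the negative class.
#'
#' @param object A `patchfreq_forest`.
#' @inheritParams predict.patchfreq_tree
#' @return Integer vector of 0/1 predictions.
#' @export
predict.patchfreq_forest <- function(object, newdata, ...) {
  xm <- newdata_matrix(object, newdata)
  votes <- vapply(
    object$trees, function(tr) predict(tr, xm),
    integer(nrow(xm))
  )
  votes <- matrix(votes, nrow = nrow(xm))
  as.integer(rowSums(votes) > object$n_trees / 2)
}

#' @export
print.patchfreq_forest <- function(x, ...) {
  cat(
    "<patchfreq_forest>", x$n_trees, "trees, depth cap",
    x$config$max_depth, "-", x$n_features, "features\n"
  )
  invisible(x)
}
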