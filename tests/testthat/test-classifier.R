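test_that("train_tree handles separable, degenerate and XOR data", {
  # one binary feature matching the labels: depth 1, perfect
  tbl <- tibble::tibble(label = rep(c(0L, 1L), 5), f1 = rep(c(0, 1), 5))
  fit <- train_tree(tbl)
  expect_identical(tree_depth(fit), 1L)
  expect_identical(predict(fit, tbl), tbl$label)

  # all labels identical: a single leaf at depth 0
  same <- tibble::tibble(label = rep(1L, 4), f1 = rnorm(4))
  leaf <- train_tree(same)
  expect_identical(tree_depth(leaf), 0L)
  expect_identical(nrow(leaf$nodes), 1L)
  expect_identical(predict(leaf, same), rep(1L, 4))

  # XOR: no depth-1 axis split helps, depth 2 is perfect
  xor <- tibble::tibble(
    label = c(0L, 1L, 1L, 0L),
    f1 = c(0, 0, 1, 1), f2 = c(0, 1, 0, 1)
  )
  # oracle: enumerate every axis-aligned depth-1 split
  best1 <- 0
  for (j in 1:2) {
    for (thr in c(0.5)) {
      pred_l <- as.integer(xor[[j + 1]] > thr)
      best1 <- max(best1, mean(pred_l == xor$label), mean((1L - pred_l) == xor$label))
    }
  }
  expect_lte(best1, 0.75)
  d1 <- train_tree(xor, train_config(max_depth = 1))
  expect_lte(mean(predict(d1, xor) == xor$label), 0.75)
  d2 <- train_tree(xor, train_config(max_depth = 2))
  expect_identical(predict(d2, xor), xor$label)
})

test_that("training is deterministic and respects the depth cap", {
  for (seed in 1:10) {
    tbl <- separable_table(n = 80, d = 5, shift = 0.8, seed = seed)
    cfg <- train_config(max_depth = 4L)
    a <- train_tree(tbl, cfg)
    b <- train_tree(tbl, cfg)
    expect_identical(a$nodes, b$nodes)
    expect_lte(tree_depth(a), 4L)
  }
})

test_that("tree predictions follow the <=-goes-left convention", {
  tbl <- tibble::tibble(label = c(0L, 1L), f1 = c(0, 1))
  fit <- train_tree(tbl)
  expect_identical(fit$nodes$threshold[!fit$nodes$is_leaf], 0.5)
  expect_identical(predict(fit, 0.5), 0L) # exactly at the threshold: left
  expect_identical(predict(fit, 0.5 + 1e-12), 1L)
  expect_error(predict(fit, matrix(1, 1, 3)), class = "patchfreq_dim_mismatch")
})

test_that("forests bootstrap deterministically and vote with ties negative", {
  tbl <- separable_table(n = 100, d = 4, seed = 2)
  cfg <- train_config(max_depth = 6L, n_trees = 10L, seed = 5L)
  f1 <- train_forest(tbl, cfg)
  f2 <- train_forest(tbl, cfg)
  expect_identical(
    lapply(f1$trees, function(t) t$nodes),
    lapply(f2$trees, function(t) t$nodes)
  )
  # a forest of one tree is that bootstrapped tree
  one <- train_forest(tbl, train_config(n_trees = 1L, seed = 5L))
  boot <- with(list(), {
    set.seed(5L)
    idx <- sample.int(100, 100, replace = TRUE)
    train_tree(tbl[idx, ], train_config(n_trees = 1L, seed = 5L))
  })
  x <- as.matrix(tbl[-1])
  expect_identical(predict(one, x), predict(boot, x))

  # separable data: ensemble is within a few points of the single tree
  tree_acc <- mean(predict(train_tree(tbl, cfg), tbl) == tbl$label)
  forest_acc <- mean(predict(f1, tbl) == tbl$label)
  expect_gte(forest_acc, tree_acc - 0.05)

  # tie vote -> class 0: two stumps forced to disagree
  stump <- function(cls_left, cls_right) {
    nodes <- tibble::tibble(
      id = 1:3, is_leaf = c(TRUE, TRUE, FALSE),
      feature = c(NA, NA, 0L), threshold = c(NA, NA, 0.5),
      left = c(NA, NA, 1L), right = c(NA, NA, 2L),
      class = c(cls_left, cls_right, NA), depth = c(1L, 1L, 0L)
    )
    structure(
      list(
        nodes = nodes, root = 3L, feature_names = "f1",
        n_features = 1L, config = train_config()
      ),
      class = "patchfreq_tree"
    )
  }
  forced <- structure(
    list(
      trees = list(stump(0L, 0L), stump(1L, 1L)), n_trees = 2L,
      feature_names = "f1", n_features = 1L, config = train_config()
    ),
    class = "patchfreq_forest"
  )
  expect_identical(predict(forced, 0.3), 0L)
})

test_that("trees agree with an independent CART implementation on held-out data", {
  skip_if_not_installed("rpart")
  tbl <- synth_features(n = 300, seed = 11)
  train <- tbl[1:200, ]
  test <- tbl[201:300, ]
  ours <- train_tree(train, train_config(max_depth = 6L))
  acc_ours <- mean(predict(ours, test) == test$label)
  ref <- rpart::rpart(factor(label) ~ ., data = train, method = "class",
    control = rpart::rpart.control(
      maxdepth = 6, cp = 0, minsplit = 2, minbucket = 1, xval = 0
    )
  )
  acc_ref <- mean(
    as.integer(as.character(predict(ref, test, type = "class"))) == test$label
  )
  expect_lt(abs(acc_ours - acc_ref), 0.06)
})

test_that("exported if-else code is faithful at every depth", {
  tbl <- tibble::tibble(label = 1L, f1 = 0)
  leaf <- train_tree(tbl)
  code <- export_if_else(leaf, "always_one")
  expect_identical(
    length(gregexpr("return", code$code, fixed = TRUE)[[1]]), 1L
  )
  expect_identical(predict_exported(code, 0.7), 1L)

  tbl <- synth_features(n = 300, seed = 11)
  for (depth in c(1L, 3L, 6L, 12L)) {
    fit <- train_tree(tbl, train_config(max_depth = depth))
    code <- export_if_else(fit)
    # one condition line per internal node, one return per leaf
    expect_identical(
      sum(gregexpr("if \\(features\\[", code$code)[[1]] > 0) +
        length(gregexpr("return [01];", code$code)[[1]]),
      nrow(fit$nodes)
    )
    set.seed(depth)
    x <- matrix(rnorm(500 * fit$n_features, sd = 3), 500)
    expect_identical(predict_exported(code, x), predict(fit, x))
  }
})

test_that("model JSON round-trips exactly and rejects bad files", {
  tbl <- synth_features(n = 300, seed = 11)
  d <- withr::local_tempdir()
  p <- file.path(d, "m.json")
  fit <- train_tree(tbl, train_config(max_depth = 8L))
  save_model(fit, p)
  back <- load_model(p)
  expect_identical(back$nodes$threshold, fit$nodes$threshold)
  x <- matrix(rnorm(200 * 20), 200)
  expect_identical(predict(back, x), predict(fit, x))

  forest <- train_forest(tbl, train_config(max_depth = 4L, n_trees = 3L))
  save_model(forest, p)
  fback <- load_model(p)
  expect_identical(predict(fback, x), predict(forest, x))

  # truncated file
  txt <- readLines(p, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1, 50), p)
  expect_error(load_model(p), class = "patchfreq_bad_model")
  # version mismatch
  save_model(fit, p)
  j <- jsonlite::read_json(p)
  j$version <- 99L
  jsonlite::write_json(j, p, auto_unbox = TRUE)
  expect_error(load_model(p), class = "patchfreq_bad_version")
})

test_that("tidy and glance summarize models", {
  tbl <- separable_table(n = 40, d = 3, seed = 9)
  fit <- train_tree(tbl, train_config(max_depth = 3L))
  td <- tidy(fit)
  expect_true(all(c("feature_name", "threshold", "class") %in% names(td)))
  expect_identical(nrow(td), nrow(fit$nodes))
  g <- glance(fit)
  expect_identical(g$depth, tree_depth(fit))
  expect_identical(g$n_nodes, nrow(fit$nodes))
  forest <- train_forest(tbl, train_config(n_trees = 3L))
  expect_identical(glance(forest)$n_trees, 3L)
  expect_identical(dplyr::n_distinct(tidy(forest)$tree), 3L)
})
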