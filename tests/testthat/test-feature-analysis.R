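test_that("PCA ranking recovers a dominant axis and demotes constants", {
  # two correlated features along one dominant axis + three constants
  set.seed(12)
  t_var <- rnorm(200)
  tbl <- tibble::tibble(
    f1 = 3 * t_var + rnorm(200, sd = 0.1),
    f2 = t_var + rnorm(200, sd = 1),
    c1 = rep(1, 200), c2 = rep(0, 200), c3 = rep(2.5, 200)
  )
  rk <- rank_features_pca(tbl)
  expect_setequal(rk$index, 0:4)
  expect_false(is.unsorted(rev(rk$score)))
  expect_setequal(tail(rk$feature, 3), c("c1", "c2", "c3"))
  expect_equal(tail(rk$score, 3), rep(0, 3))

  # hand oracle on 2 standardized features with correlation rho:
  # eigenvalues (1 ± rho), equal loadings 1/sqrt(2) -> both scores 1/2
  two <- tbl[c("f1", "f2")]
  rk2 <- rank_features_pca(two)
  expect_equal(rk2$score, c(0.5, 0.5), tolerance = 1e-12)
  expect_setequal(rk2$index, 0:1)

  # hub feature of the correlation structure ranks first: f1 = z1 + z2
  # correlates with both f2 = z1 and f3 = z2, which are independent
  set.seed(13)
  z1 <- rnorm(500)
  z2 <- rnorm(500)
  hub <- tibble::tibble(f1 = z1 + z2, f2 = z1, f3 = z2)
  rk3 <- rank_features_pca(hub)
  expect_identical(rk3$feature[1], "f1")
  # independent oracle: scores from an explicit eigendecomposition of the
  # correlation matrix
  ev <- eigen(stats::cor(as.matrix(hub)))
  oracle <- as.numeric(ev$vectors^2 %*% (ev$values / sum(ev$values)))
  expect_equal(sort(rk3$score, decreasing = TRUE), sort(oracle, decreasing = TRUE),
    tolerance = 1e-9
  )
  expect_identical(which.max(oracle), 1L)
})

test_that("accuracy curves have one point per subset size", {
  tbl <- separable_table(n = 120, d = 5, seed = 21)
  train <- tbl[1:80, ]
  test <- tbl[81:120, ]
  rk <- rank_features_pca(train[-1])
  cv <- accuracy_curve(train, test, rk, train_config(max_depth = 4L))
  expect_identical(cv$k, 1:5)
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))

  # the top-ranked feature separates the classes -> accuracy 1 at k = 1
  set.seed(22)
  base <- rep(c(0, 10), 30)
  perf <- tibble::tibble(
    label = rep(c(0L, 1L), 30),
    f1 = base, # label-aligned
    f2 = base + rnorm(60, sd = 0.01) # correlated twin, also separating
  )
  rkp <- rank_features_pca(perf[-1])
  expect_true(rkp$feature[1] %in% c("f1", "f2"))
  cvp <- accuracy_curve(perf, perf, rkp)
  expect_equal(cvp$accuracy[1], 1)

  # d = 1 -> one point
  one <- perf[c("label", "f1")]
  cv1 <- accuracy_curve(one, one, rank_features_pca(one["f1"]))
  expect_identical(nrow(cv1), 1L)
})

test_that("extraction plans are minimal and dependency-closed", {
  srad_only <- extraction_plan(0:4)
  expect_setequal(
    unclass(srad_only),
    c("dft2", "shift", "magnitude", "radial_sums")
  )
  expect_false("angular_sums" %in% srad_only)

  fwt_only <- extraction_plan(10:19)
  expect_setequal(unclass(fwt_only), c("haar_fwt2", "energies"))

  full <- extraction_plan(0:19)
  expect_setequal(
    unclass(full),
    c(
      "dft2", "shift", "magnitude", "radial_sums", "angular_sums",
      "haar_fwt2", "energies"
    )
  )
  # every plan stage's dependencies are inside the plan
  graph <- list(
    dft2 = character(0), shift = "dft2", magnitude = "shift",
    radial_sums = "magnitude", angular_sums = "magnitude",
    haar_fwt2 = character(0), energies = "haar_fwt2"
  )
  for (sel in list(0L, 7L, 19L, c(0L, 19L), 5:9)) {
    plan <- extraction_plan(sel)
    for (st in plan) {
      expect_true(all(graph[[st]] %in% plan))
    }
  }
  expect_error(extraction_plan(integer(0)), class = "patchfreq_bad_input")
  expect_error(extraction_plan(20L), class = "patchfreq_bad_input")
})

test_that("dropping the angular profile reduces measured extraction cost", {
  bench_full <- run_benchmark(extraction_plan(0:9),
    batch_size = 5L, batches = 4L, seed = 2L
  )
  bench_srad <- run_benchmark(extraction_plan(0:4),
    batch_size = 5L, batches = 4L, seed = 2L
  )
  total <- function(b) b$mean_ns[b$stage == "Total"]
  expect_lt(total(bench_srad), total(bench_full))
})
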