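# Shared fixtures: small seeded patches and feature tables built in code.

random_patch <- function(n = 32L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(n * n), n, n)
}

# a small, clearly separable labelled feature table: positives shifted in
# half of the feature dimensions
separable_table <- function(n = 60L, d = 4L, shift = 3, seed = 7L) {
  set.seed(seed)
  lab <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * d), n, d)
  x[lab == 1L, seq_len(ceiling(d / 2))] <-
    x[lab == 1L, seq_len(ceiling(d / 2))] + shift
  tbl <- tibble::as_tibble(as.data.frame(x))
  names(tbl) <- paste0("f", seq_len(d))
  dplyr::bind_cols(tibble::tibble(label = lab), tbl)
}

# small synthetic patch set with features, cached per options so the
# heavier classifier/analysis tests share one extraction
synth_features <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 300L, seed = 11L, features = "both") {
    key <- paste(n, seed, features, sep = "_")
    if (is.null(cache[[key]])) {
      set <- generate_patches(synth_config(seed = seed), n)
      cache[[key]] <- extract_features(set$patches,
        features = features, labels = set$labels
      )
    }
    cache[[key]]
  }
})

# brute-force Eq.-style double-sum DFT, the independent transform oracle
dft2_bruteforce <- function(img) {
  n <- nrow(img)
  out <- matrix(0 + 0i, n, n)
  for (l in 0:(n - 1)) {
    for (k in 0:(n - 1)) {
      s <- 0 + 0i
      for (py in 0:(n - 1)) {
        for (px in 0:(n - 1)) {
          s <- s + img[py + 1, px + 1] *
            exp(-2i * pi * (k * px + l * py) / n)
        }
      }
      out[l + 1, k + 1] <- s
    }
  }
  out
}
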