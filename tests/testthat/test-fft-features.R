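test_that("dft2 matches the brute-force double sum and its edge cases", {
  # constant image: all energy in the DC bin
  f <- dft2(matrix(1, 32, 32))
  expect_equal(Re(f[1, 1]), 1024)
  expect_lt(max(Mod(f)[-1]), 1e-9)
  # impulse at the origin: flat unit-magnitude spectrum
  imp <- matrix(0, 32, 32)
  imp[1, 1] <- 1
  expect_equal(Mod(dft2(imp)), matrix(1, 32, 32))
  # seeded random 8x8 vs independent O(N^4) summation
  set.seed(42)
  img <- matrix(runif(64), 8)
  ref <- dft2_bruteforce(img)
  expect_lt(max(Mod(dft2(img) - ref)) / max(Mod(ref)), 1e-9)
  expect_error(dft2(matrix(1, 4, 6)), class = "patchfreq_bad_input")
  expect_error(dft2(matrix(1, 7, 7)), class = "patchfreq_bad_input")
})

test_that("Parseval and conjugate symmetry hold for random patches", {
  for (seed in 1:10) {
    img <- random_patch(32L, seed)
    f <- dft2(img)
    expect_equal(sum(Mod(f)^2), 32^2 * sum(img^2), tolerance = 1e-12)
    # F(l,k) = conj(F((-l) mod N, (-k) mod N))
    n <- 32L
    idx <- (n - seq_len(n) + 1L) %% n + 1L
    expect_lt(max(Mod(f - Conj(f[idx, idx]))) / max(Mod(f)), 1e-9)
  }
})

test_that("shift_center swaps quadrants and is an involution", {
  f <- dft2(random_patch(32L, 1))
  s <- shift_center(f)
  expect_identical(s[17, 17], f[1, 1])
  expect_identical(shift_center(shift_center(f)), f)
  g <- matrix(0:15, 4, 4, byrow = TRUE)
  expect_identical(shift_center(g)[3, 3], 0L)
  expect_error(shift_center(matrix(1, 5, 5)), class = "patchfreq_bad_input")
})

test_that("magnitude is the plain complex modulus", {
  m <- magnitude(matrix(c(3 + 4i, 0 + 0i, 0 - 2i, 1 + 0i), 2))
  expect_equal(as.numeric(m), c(5, 0, 2, 1))
  patch <- matrix(1, 32, 32)
  mag <- magnitude(shift_center(dft2(patch)))
  expect_equal(mag[17, 17], abs(sum(patch)))
})

test_that("radial_sums bins upper-half pixels by rounded distance", {
  z <- matrix(0, 32, 32)
  expect_equal(radial_sums(z), rep(0, 16))
  # single magnitude at 0-based (13,16): distance 3, upper half
  z[14, 17] <- 5
  rs <- radial_sums(z)
  expect_equal(rs[3], 5)
  expect_equal(sum(rs), 5)
  # all-ones: entries equal brute-force counts of rounded distances
  counts <- integer(16)
  for (r in 0:31) {
    for (c in 0:31) {
      if (r > 16 || (r == 16 && c == 16)) next
      b <- round(sqrt((r - 16)^2 + (c - 16)^2))
      if (b >= 1 && b <= 16) counts[b] <- counts[b] + 1L
    }
  }
  expect_equal(radial_sums(matrix(1, 32, 32)), as.numeric(counts))
})

test_that("angular_sums follows the 180-line, 16-sample rasterization", {
  expect_equal(angular_sums(matrix(0, 32, 32)), rep(0, 180))
  expect_equal(angular_sums(matrix(1, 32, 32)), rep(16, 180))
  # single magnitude at 0-based (16, 20): brute-force sample enumeration
  z <- matrix(0, 32, 32)
  z[17, 21] <- 2
  expected <- numeric(180)
  for (k in 0:179) {
    th <- k * pi / 180
    for (r in 1:16) {
      row <- min(max(16 - round(r * sin(th)), 0), 31)
      col <- min(max(16 + round(r * cos(th)), 0), 31)
      if (row == 16 && col == 20) expected[k + 1] <- expected[k + 1] + 2
    }
  }
  expect_equal(angular_sums(z), expected)
  expect_gt(expected[1], 0) # the 0-degree line passes through (16,20)
})

test_that("profiles are linear in the magnitude image", {
  set.seed(8)
  m1 <- matrix(runif(1024), 32)
  m2 <- matrix(runif(1024), 32)
  lin <- 2.5 * m1 + 0.7 * m2
  expect_equal(radial_sums(lin), 2.5 * radial_sums(m1) + 0.7 * radial_sums(m2))
  expect_equal(
    angular_sums(lin),
    2.5 * angular_sums(m1) + 0.7 * angular_sums(m2)
  )
})

test_that("profile_stats computes the five statistics with first-max ties", {
  s <- profile_stats(c(1, 2, 3))
  expect_equal(unname(s), c(2, 3, 2, 2 / 3, 2))
  s <- profile_stats(c(4, 4, 4))
  expect_equal(unname(s[c("var", "range", "argmax")]), c(0, 0, 0))
  expect_equal(unname(profile_stats(c(5, 1, 5))["argmax"]), 0)
  expect_error(profile_stats(numeric(0)), class = "patchfreq_bad_input")
})

test_that("a vertical sinusoid peaks at its frequency bin in Srad", {
  for (cycles in c(2, 4, 8)) {
    rows <- matrix(0:31, 32, 32)
    patch <- 0.5 + 0.4 * sin(2 * pi * cycles * rows / 32)
    srad <- radial_sums(magnitude(shift_center(dft2(patch))))
    expect_identical(which.max(srad), as.integer(cycles))
  }
})

test_that("spectral_features equals an independent step-by-step composition", {
  patch <- random_patch(32L, 99)
  got <- spectral_features(patch)
  expect_length(got, 10L)

  # scalar re-implementation sharing no code with the package path
  n <- 32L
  f <- matrix(0 + 0i, n, n)
  for (l in 0:(n - 1)) {
    for (k in 0:(n - 1)) {
      f[l + 1, k + 1] <- sum(patch * exp(-2i * pi *
        (k * matrix(0:(n - 1), n, n, byrow = TRUE) +
          l * matrix(0:(n - 1), n, n)) / n))
    }
  }
  sh <- matrix(0, n, n)
  for (r in 0:(n - 1)) {
    for (c in 0:(n - 1)) {
      sh[(r + n / 2) %% n + 1, (c + n / 2) %% n + 1] <- Mod(f[r + 1, c + 1])
    }
  }
  srad <- numeric(16)
  for (r in 0:(n - 1)) {
    for (c in 0:(n - 1)) {
      if (r > 16 || (r == 16 && c == 16)) next
      b <- round(sqrt((r - 16)^2 + (c - 16)^2))
      if (b >= 1 && b <= 16) srad[b] <- srad[b] + sh[r + 1, c + 1]
    }
  }
  sang <- numeric(180)
  for (k in 0:179) {
    for (r in 1:16) {
      row <- min(max(16 - round(r * sin(k * pi / 180)), 0), 31)
      col <- min(max(16 + round(r * cos(k * pi / 180)), 0), 31)
      sang[k + 1] <- sang[k + 1] + sh[row + 1, col + 1]
    }
  }
  stats5 <- function(v) {
    c(
      mean(v), max(v), which.max(v) - 1,
      mean((v - mean(v))^2), max(v) - min(v)
    )
  }
  expect_equal(unname(got), c(stats5(srad), stats5(sang)), tolerance = 1e-9)

  # all-zero patch: all ten features zero
  expect_equal(unname(spectral_features(matrix(0, 32, 32))), rep(0, 10))
})
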