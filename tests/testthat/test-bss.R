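test_that("whitening yields identity covariance and flags rank deficiency", {
  x <- random_mixing(3, 1) %*% nongaussian_sources(3, 800, seed = 2)
  w <- whiten(x)
  expect_lt(max(abs(tcrossprod(w$z) / (ncol(x) - 1) - diag(3))), 1e-8)
  expect_equal(rowMeans(w$z), rep(0, 3), tolerance = 1e-10)
  dup <- rbind(x, x[1, ])
  expect_error(whiten(dup), class = "mipipe_error_degenerate")
  # whitener . mixing . (sample sqrt covariance of sources) is orthogonal
  s <- nongaussian_sources(3, 2000, seed = 5)
  A <- random_mixing(3, 6)
  K <- whiten(A %*% s)$K
  Cs <- tcrossprod(s - rowMeans(s)) / (ncol(s) - 1)
  e <- eigen(Cs, symmetric = TRUE)
  Q <- K %*% A %*% (e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors))
  expect_lt(max(abs(crossprod(Q) - diag(3))), 1e-6)
})

test_that("fastICA recovers non-Gaussian sources (Amari index)", {
  s <- nongaussian_sources(3, 4000, seed = 11)
  A <- random_mixing(3, 12)
  res <- fastica(A %*% s, contrast_spec(seed = 1))
  expect_true(res$converged)
  expect_lt(amari_index(res$B, A), 0.1)
  # result structure: sources = B (x - mean), unit variance rows
  xc <- A %*% s - rowMeans(A %*% s)
  expect_equal(res$sources, res$B %*% xc, tolerance = 1e-10)
  expect_equal(apply(res$sources, 1, var), rep(1, 3), tolerance = 1e-6)
})

test_that("fastICA on already-independent standardized input gives a signed permutation", {
  s <- nongaussian_sources(3, 20000, seed = 21)
  s <- (s - rowMeans(s)) / apply(s, 1, sd)   # independent, unit variance
  res <- fastica(s, contrast_spec(seed = 3))
  P <- res$B                                 # effective mixing is the identity
  expect_lt(amari_index(P, diag(3)), 2e-2)   # entrywise deviations are < 1e-2
  Pa <- abs(P)
  expect_true(all(abs(apply(Pa, 1, max) - 1) < 1e-2))        # unit gains
  expect_true(all((rowSums(Pa) - apply(Pa, 1, max)) < 2e-2)) # tiny cross-talk
})

test_that("fastICA honors iteration caps, seeds, and bad input", {
  s <- nongaussian_sources(4, 3000, seed = 31)
  x <- random_mixing(4, 32) %*% s
  res <- fastica(x, contrast_spec(max_iterations = 1, seed = 1))
  expect_false(res$converged)
  r1 <- fastica(x, contrast_spec(seed = 9))
  r2 <- fastica(x, contrast_spec(seed = 9))
  expect_identical(r1, r2)
  xna <- x; xna[1, 5] <- NaN
  expect_error(fastica(xna), class = "mipipe_error_data")
  # deflation mode also separates
  rd <- fastica(x, contrast_spec(mode = "deflation", seed = 2))
  expect_lt(amari_index(rd$B, random_mixing(4, 32)), 0.15)
})

test_that("SOBI separates spectrally distinct sinusoids", {
  n <- 2000; tt <- (1:n) / 100
  s <- rbind(sin(2 * pi * 7 * tt), sin(2 * pi * 23 * tt))
  A <- matrix(c(1, 0.5, -0.3, 1), 2, 2)
  res <- sobi(A %*% s, lags = 1:20)
  expect_lt(amari_index(res$B, A), 0.1)
  expect_error(sobi(A %*% s, lags = integer(0)), class = "mipipe_error_parameter")
  expect_error(sobi(A %*% s, lags = 1:1001), class = "mipipe_error_parameter")
  # off-diagonal energy is non-increasing across sweeps
  off <- attr(res, "off_energy")
  expect_true(all(diff(off) <= 1e-10))
  # temporally white sources: runs without error (separation undefined)
  wn <- matrix(rnorm(2 * 1000), 2)
  expect_s3_class(sobi(random_mixing(2, 5) %*% wn, lags = 1:10), "unmixing_result")
})

test_that("Amari index is zero exactly on scaled permutations", {
  expect_equal(amari_index(diag(3), diag(3)), 0)
  P <- diag(c(3, -2, 0.5))[c(2, 3, 1), ]
  expect_equal(amari_index(P, diag(3)), 0)
  expect_error(amari_index(matrix(1, 2, 3), diag(3)), class = "mipipe_error_shape")
  # hand evaluation of the formula for an all-ones product
  expect_equal(amari_index(matrix(1, 3, 3), diag(3)), amari_oracle(matrix(1, 3, 3)))
  withr::with_seed(8, {
    M <- matrix(rnorm(16), 4, 4)
    expect_equal(amari_index(M, diag(4)), amari_oracle(M))
  })
})

test_that("HOS beats SOS on iid non-Gaussian sources and vice versa on colored Gaussians", {
  n <- 1500
  amari_fast <- amari_sobi <- amari_fast_g <- amari_sobi_g <- numeric(20)
  for (r in 1:20) {
    # iid non-Gaussian: fastICA identifiable, SOBI blind
    s <- nongaussian_sources(3, n, seed = 100 + r)
    A <- random_mixing(3, 200 + r)
    x <- A %*% s
    amari_fast[r] <- amari_index(fastica(x, contrast_spec(seed = r))$B, A)
    amari_sobi[r] <- amari_index(sobi(x, lags = 1:20)$B, A)
    # Gaussian AR sources with distinct spectra: SOBI identifiable
    g <- withr::with_seed(300 + r, rbind(
      as.numeric(stats::filter(rnorm(n), 0.9, "recursive")),
      as.numeric(stats::filter(rnorm(n), -0.9, "recursive")),
      as.numeric(stats::filter(rnorm(n), c(0.5, -0.4), "recursive"))))
    xg <- A %*% g
    amari_fast_g[r] <- amari_index(fastica(xg, contrast_spec(seed = r))$B, A)
    amari_sobi_g[r] <- amari_index(sobi(xg, lags = 1:20)$B, A)
  }
  expect_lt(mean(amari_fast), mean(amari_sobi))
  expect_lt(mean(amari_sobi_g), mean(amari_fast_g))
})
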