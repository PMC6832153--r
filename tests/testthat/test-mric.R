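test_that("spectral profiles peak at the tone frequency and integrate to one", {
  x <- tone(10, 100, 4)
  pr <- spectral_profile(x, 100)
  expect_equal(pr$freqs[which.max(pr$power)],
               periodogram_oracle(x, 100)$freq[which.max(periodogram_oracle(x, 100)$power)],
               tolerance = 0.5)
  expect_equal(pracma::trapz(pr$freqs, pr$power), 1, tolerance = 1e-6)
  expect_true(all(pr$power >= 0))
  expect_error(spectral_profile(tone(10, 100, 1.5), 100), class = "mipipe_error_length")
})

test_that("white noise gives an approximately flat profile", {
  x <- withr::with_seed(4, rnorm(16384))
  pr <- spectral_profile(x, 100)
  band <- pr$freqs >= 1 & pr$freqs <= 45
  expect_lt(max(pr$power[band]) / min(pr$power[band]), 3)
})

test_that("the default template is a normalized mu/beta bump pair", {
  tpl <- default_template()
  expect_equal(tpl$freqs[which.max(tpl$weight)], 10.5)
  expect_equal(pracma::trapz(tpl$freqs, tpl$weight), 1, tolerance = 1e-9)
  # Gaussian tail: negligible weight at 45 Hz
  expect_lt(tpl$weight[tpl$freqs == 45], 0.01 * max(tpl$weight))
  w45 <- exp(-(45 - 20)^2 / (2 * 3.5^2)) * 0.6   # direct tail evaluation
  expect_lt(w45, 1e-10)
  expect_error(default_template(seq(0.5, 12, by = 0.5)), class = "mipipe_error_grid")
})

test_that("templates load from two-column files", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "tpl.txt")
  g <- mric_grid()
  write.table(cbind(g, exp(-(g - 11)^2)), p, row.names = FALSE, col.names = FALSE)
  tpl <- read_template(p)
  expect_s3_class(tpl, "mric_template")
  expect_equal(pracma::trapz(tpl$freqs, tpl$weight), 1, tolerance = 1e-9)
})

test_that("mric_score is the Pearson correlation over the grid", {
  tpl <- default_template()
  self <- structure(list(freqs = tpl$freqs, power = tpl$weight),
                    class = "spectral_profile")
  expect_equal(mric_score(self, tpl), 1.0)
  # reflected profile: verify against a hand-written Pearson formula
  refl <- structure(list(freqs = tpl$freqs, power = rev(tpl$weight)),
                    class = "spectral_profile")
  x <- refl$power; y <- tpl$weight
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(mric_score(refl, tpl), hand)
  flat <- structure(list(freqs = tpl$freqs, power = rep(1 / 44.5, length(tpl$freqs))),
                    class = "spectral_profile")
  expect_error(mric_score(flat, tpl), class = "mipipe_error_undefined_correlation")
  # mu-band source scores above broadband noise
  mu <- generate_sources(list(source_spec("mu_burst", 10.5, 2.5)), 1000, 100, 1, 3)
  pink <- generate_sources(list(source_spec("pink_noise")), 1000, 100, 1, 3)
  s_mu <- mric_score(spectral_profile(mu[1, ], 100), tpl)
  s_pink <- mric_score(spectral_profile(pink[1, ], 100), tpl)
  expect_gt(s_mu, s_pink)
})

test_that("sort_sources orders by score, stably, as a row permutation", {
  fs <- 100
  src <- rbind(tone(10, fs, 3.5), tone(40, fs, 3.5))
  ss <- sort_sources(src, fs)
  expect_identical(ss$order, c(1L, 2L))           # 10 Hz first
  expect_identical(ss$sources, src[ss$order, , drop = FALSE])
  expect_true(all(diff(ss$scores) <= 0))
  # single source
  one <- sort_sources(src[1, , drop = FALSE], fs)
  expect_identical(one$order, 1L)
  # equal-score duplicates keep original relative order (stable ties)
  dup <- rbind(a = src[1, ], b = src[1, ], c = src[2, ])
  sd2 <- sort_sources(dup, fs)
  expect_identical(sd2$order[1:2], c(1L, 2L))
  # constant (dead) rows sink to the bottom with -Inf score, no error
  dead <- rbind(src, 0)
  sd3 <- sort_sources(dead, fs)
  expect_identical(sd3$order[3], 3L)
  expect_identical(sd3$scores[3], -Inf)
})

test_that("sorting is invariant to the input row permutation", {
  src <- generate_sources(default_source_specs("left", 5), 700, 100, 1, seed = 17)
  ss <- sort_sources(src, 100)
  for (s in 1:5) {
    perm <- withr::with_seed(s, sample.int(nrow(src)))
    ssp <- sort_sources(src[perm, , drop = FALSE], 100)
    expect_equal(ssp$sources, ss$sources, ignore_attr = TRUE)
    expect_equal(ssp$scores, ss$scores)
    # the reported order is a permutation
    expect_identical(sort(ssp$order), seq_len(nrow(src)))
  }
})
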