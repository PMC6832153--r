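test_that("band-limited sources concentrate power in their declared band", {
  for (case in list(list(kind = "mu_burst", c = 10.5, bw = 2.5, band = c(8, 13)),
                    list(kind = "beta_burst", c = 20, bw = 6, band = c(14, 26)))) {
    fracs <- vapply(1:5, function(s) {
      src <- generate_sources(list(source_spec(case$kind, case$c, case$bw)),
                              4000, 100, label = 1, seed = s)
      p <- periodogram_oracle(src[1, ], 100)
      inb <- p$freq >= case$c - case$bw & p$freq <= case$c + case$bw
      sum(p$power[inb]) / sum(p$power)
    }, numeric(1))
    expect_true(all(fracs >= 0.8), label = paste(case$kind, "in-band fraction"))
    # PSD peak inside the declared band (independent periodogram oracle)
    src <- generate_sources(list(source_spec(case$kind, case$c, case$bw)),
                            1000, 100, label = 1, seed = 99)
    p <- periodogram_oracle(src[1, ], 100)
    peak <- p$freq[which.max(p$power)]
    expect_gte(peak, case$band[1])
    expect_lte(peak, case$band[2])
  }
})

test_that("source generation is seed-deterministic and class gain scales variance", {
  specs <- list(source_spec("mu_burst", 10.5, 2.5, class_gain = c(2, 1)))
  a <- generate_sources(specs, 1000, 100, label = 1, seed = 7)
  b <- generate_sources(specs, 1000, 100, label = 1, seed = 7)
  expect_identical(a, b)
  c2 <- generate_sources(specs, 1000, 100, label = 2, seed = 7)
  ratio <- var(a[1, ]) / var(c2[1, ])
  expect_gt(ratio, 4 * 0.9)
  expect_lt(ratio, 4 * 1.1)
})

test_that("unknown source kinds are rejected", {
  expect_error(source_spec("gamma_burst", 50, 5), class = "mipipe_error_invalid_spec")
  expect_error(source_spec("mu_burst", 10, 2, class_gain = c(1, -1)),
               class = "mipipe_error_invalid_spec")
})

test_that("mix() is exact linear mixing with shape and singularity guards", {
  s <- matrix(rnorm(12), 3, 4)
  expect_identical(mix(s, diag(3)), s)
  expect_error(mix(s, matrix(1, 2, 2)), class = "mipipe_error_shape")
  expect_error(mix(matrix(rnorm(8), 2, 4), matrix(c(1, 1, 0, 0), 2, 2)),
               class = "mipipe_error_singular")
  # brute-force summation oracle on a random 6x6 mixing
  src <- nongaussian_sources(6, 50, seed = 3)
  A <- random_mixing(6, seed = 4)
  got <- mix(src, A)
  want <- matrix(0, 6, 50)
  for (k in 1:6) for (j in 1:6) want[k, ] <- want[k, ] + A[k, j] * src[j, ]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("generate_dataset delivers balanced labelled trials with usable ground truth", {
  cfg <- synthetic_config(n_trials_per_class = 10, seed = 21)
  ts <- generate_dataset(cfg)
  expect_length(ts$trials, 20)
  expect_equal(as.vector(table(ts$labels)), c(10, 10))
  expect_identical(generate_dataset(cfg), ts)   # seeded determinism
  # mixing condition bounded by the configured cap
  sv <- svd(ts$ground_truth$A_left)$d
  expect_lte(max(sv) / min(sv), cfg$mixing_condition_cap)
  # mixing linearity: unmixing with the true inverse recovers sources exactly
  rec <- solve(ts$ground_truth$A_left) %*% ts$trials[[3]][1:9, ]
  expect_lt(max(abs(rec - ts$ground_truth$sources[[3]][1:9, ])), 1e-8)
})

test_that("mu gains are mirrored across hemisphere clusters", {
  cfg <- synthetic_config(n_trials_per_class = 1, seed = 2)
  mu_left <- cfg$specs_left[[1]]
  mu_right <- cfg$specs_right[[1]]
  expect_identical(mu_left$kind, "mu_burst")
  expect_identical(mu_left$class_gain, rev(mu_right$class_gain))
})

test_that("an unreachable condition cap aborts generation", {
  cfg <- synthetic_config(n_trials_per_class = 1, seed = 3, mixing_condition_cap = 1.0001)
  expect_error(generate_dataset(cfg), class = "mipipe_error_generation")
})

test_that("trial sets round-trip through the on-disk format", {
  ts <- generate_dataset(synthetic_config(n_trials_per_class = 2, seed = 42))
  dir <- withr::local_tempdir()
  write_trial_set(ts, dir)
  ts2 <- read_trial_set(dir)
  expect_identical(ts2$trials, ts$trials)
  expect_identical(ts2$labels, ts$labels)
  expect_identical(ts2$ground_truth$sources, ts$ground_truth$sources)
  expect_identical(ts2$ground_truth$A_right, ts$ground_truth$A_right)
  expect_equal(ts2$ground_truth$specs_left, ts$ground_truth$specs_left)
})
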