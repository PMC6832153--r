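# Shared fixture builders. Everything is generated in code at test time.

# A pure tone sampled at fs for `dur` seconds.
tone <- function(freq, fs = 100, dur = 2, phase = 0) {
  sin(2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs) + phase)
}

# Strongly non-Gaussian independent sources (uniform, sawtooth, Laplacian,
# extended cyclically), for ICA recovery checks.
nongaussian_sources <- function(p, n, seed) {
  withr::with_seed(seed, {
    gens <- list(function(n) runif(n) - 0.5,
                 function(n) ((seq_len(n) * 7) %% 101) / 101 - 0.5,
                 function(n) sign(rnorm(n)) * rexp(n),
                 function(n) runif(n)^3 - 0.25,
                 function(n) sample(c(-1, 1), n, replace = TRUE) * runif(n),
                 function(n) rexp(n) - 1)
    do.call(rbind, lapply(seq_len(p), function(i) gens[[(i - 1) %% 6 + 1]](n)))
  })
}

random_mixing <- function(p, seed, cap = 15) {
  withr::with_seed(seed, {
    repeat {
      A <- matrix(rnorm(p * p), p, p)
      if (kappa(A, exact = TRUE) <= cap) return(A)
    }
  })
}

# Small architecture for fast CNN tests.
tiny_spec <- function(input_shape = c(12, 14, 1), dropout = 0) {
  architecture_spec(conv_layers = list(conv_layer(3, c(3, 2), c(1, 1), c(2, 2))),
                    dense_units = 6, dropout = dropout, n_classes = 2,
                    input_shape = input_shape)
}

# Linearly separable image set: class-specific horizontal bands plus noise.
separable_images <- function(n = 24, shape = c(12, 14), seed = 1) {
  withr::with_seed(seed, {
    labs <- rep(1:2, length.out = n)
    x <- array(rnorm(prod(shape) * n, sd = 0.05), c(shape, n))
    half <- floor(shape[1] / 2)
    for (i in seq_len(n)) {
      if (labs[i] == 1) x[seq_len(half), , i] <- x[seq_len(half), , i] + 1
      else x[(half + 1):shape[1], , i] <- x[(half + 1):shape[1], , i] + 1
    }
    image_set(x, labs)
  })
}

# Independent raw-periodogram PSD oracle (one-sided, via stats::fft).
periodogram_oracle <- function(x, fs) {
  n <- length(x)
  P <- Mod(stats::fft(x - mean(x)))^2 / (n * fs)
  nf <- floor(n / 2) + 1
  list(freq = seq(0, fs / 2, length.out = nf), power = P[seq_len(nf)])
}

# Direct evaluation of the Amari error from its formula, written as loops.
amari_oracle <- function(P) {
  m <- nrow(P)
  s <- 0
  for (i in seq_len(m)) s <- s + sum(abs(P[i, ])) / max(abs(P[i, ])) - 1
  for (j in seq_len(m)) s <- s + sum(abs(P[, j])) / max(abs(P[, j])) - 1
  s / (2 * m)
}
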