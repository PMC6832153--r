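# Synthetic EEG with known sources and mixing.
#
# The generator emulates the statistical structure the separation model
# assumes: each cluster of channels records a linear instantaneous mixture
# x(t) = A s(t) of band-limited oscillatory sources (mu 8-13 Hz, beta
# 14-26 Hz), broadband 1/f noise, narrowband line interference, and slow
# blink-like transients. Two-class motor-imagery structure enters as a
# lateralized gain on the mu/beta sources, mirrored between the left and
# right channel clusters.

SOURCE_KINDS <- c("mu_burst", "beta_burst", "pink_noise", "line_noise", "blink")

#' Specify one synthetic source
#'
#' @param kind One of `"mu_burst"`, `"beta_burst"`, `"pink_noise"`,
#'   `"line_noise"`, `"blink"`.
#' @param center_freq Center frequency in Hz (band-limited and line kinds);
#'   for `"blink"` it is the mean blink rate in Hz.
#' @param bandwidth Half-width of the pass band in Hz (band-limited kinds).
#' @param class_gain Length-2 positive vector: amplitude multiplier applied
#'   under class 1 and class 2 respectively.
#' @param amplitude Overall amplitude scale (sources are generated with unit
#'   standard deviation before scaling).
#' @return A `source_spec` object.
#' @examples
#' source_spec("mu_burst", center_freq = 10.5, bandwidth = 2.5,
#'             class_gain = c(0.6, 1))
#' @export
source_spec <- function(kind, center_freq = NA_real_, bandwidth = NA_real_,
                        class_gain = c(1, 1), amplitude = 1) {
  if (!(length(kind) == 1 && kind %in% SOURCE_KINDS)) {
    mp_abort(paste0("unknown source kind: ", paste(kind, collapse = ", ")), "invalid_spec")
  }
  band_limited <- kind %in% c("mu_burst", "beta_burst")
  if (band_limited || kind == "line_noise") {
    mp_assert(is.finite(center_freq) && center_freq >= 0,
              "center_freq must be a nonnegative frequency", "invalid_spec")
  }
  if (band_limited) {
    mp_assert(is.finite(bandwidth) && bandwidth > 0,
              "bandwidth must be > 0 for band-limited kinds", "invalid_spec")
  }
  mp_assert(length(class_gain) == 2 && all(is.finite(class_gain)) && all(class_gain > 0),
            "class_gain must be two positive gains", "invalid_spec")
  mp_assert(is.finite(amplitude) && amplitude > 0, "amplitude must be > 0", "invalid_spec")
  structure(list(kind = kind, center_freq = center_freq, bandwidth = bandwidth,
                 class_gain = as.numeric(class_gain), amplitude = amplitude),
            class = "source_spec")
}

#' Default per-cluster source population
#'
#' Nine sources mirroring a sensorimotor channel cluster: one mu burst, one
#' beta burst, line interference, blink transients, and five 1/f noise
#' sources. The mu/beta class gains encode event-related desynchronization:
#' right-hand imagery (class 1) attenuates the left-hemisphere mu rhythm and
#' vice versa, so gains are mirrored between clusters.
#'
#' @param cluster `"left"` or `"right"`.
#' @param n_sources Number of sources (>= 2); extra slots beyond the five
#'   stereotyped kinds are filled with pink noise.
#' @param mu_gain,beta_gain Attenuation factor applied to the mu (resp.
#'   beta) source under the class contralateral to the cluster.
#' @return List of [source_spec()] objects.
#' @export
default_source_specs <- function(cluster = c("left", "right"), n_sources = 9,
                                 mu_gain = 0.5, beta_gain = 0.7) {
  cluster <- match.arg(cluster)
  mp_assert(is_count(n_sources) && n_sources >= 2, "n_sources must be >= 2", "invalid_spec")
  gains <- function(g) if (cluster == "left") c(g, 1) else c(1, g)
  specs <- list(
    source_spec("mu_burst", 10.5, 2.5, class_gain = gains(mu_gain)),
    source_spec("beta_burst", 20, 6, class_gain = gains(beta_gain)),
    source_spec("line_noise", 40, amplitude = 0.5),
    source_spec("blink", 0.3, amplitude = 3),
    source_spec("pink_noise")
  )
  while (length(specs) < n_sources) specs <- c(specs, list(source_spec("pink_noise")))
  specs[seq_len(n_sources)]
}

# --- individual source waveforms (unit-sd before amplitude/class scaling) ---

# White noise is amplitude-modulated by Hann burst envelopes first and
# band-pass filtered afterwards, so the spectral confinement of the result
# is governed by the filter skirts, not by envelope sidebands.
gen_band_burst <- function(center, bw, n, fs) {
  lo <- max(0.05, center - bw)
  hi <- min(center + bw, 0.499 * fs)
  flt <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  dur <- n / fs
  n_bursts <- sample(1:3, 1)
  env <- rep(0.2, n)
  for (b in seq_len(n_bursts)) {
    blen <- runif(1, 0.5, min(1.5, dur))
    onset <- runif(1, 0, max(dur - blen, 0))
    i0 <- floor(onset * fs) + 1L
    i1 <- min(n, i0 + round(blen * fs) - 1L)
    m <- i1 - i0 + 1L
    env[i0:i1] <- pmax(env[i0:i1], 0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1)))
  }
  pre <- c(rnorm(200), rnorm(n) * env)     # warm-up samples absorb the transient
  y <- as.numeric(signal::filter(flt, pre))[-seq_len(200)]
  y / max(sd(y), .Machine$double.eps)
}

gen_pink <- function(n, fs) {
  f <- seq(0, n - 1) / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]
  shape <- c(0, 1 / sqrt(f[-1]))
  y <- Re(stats::fft(stats::fft(rnorm(n)) * shape, inverse = TRUE)) / n
  y / max(sd(y), .Machine$double.eps)
}

gen_line <- function(freq, n, fs) {
  ph <- runif(1, 0, 2 * pi)
  y <- sin(2 * pi * freq * seq(0, n - 1) / fs + ph)
  y / max(sd(y), .Machine$double.eps)
}

gen_blink <- function(rate, n, fs) {
  dur <- n / fs
  t1 <- runif(1, 0, dur)                      # guarantee at least one event
  times <- t1
  repeat {
    nxt <- times[length(times)] + rexp(1, rate)
    if (nxt > dur) break
    times <- c(times, nxt)
  }
  tau_r <- 0.04; tau_d <- 0.18
  y <- numeric(n)
  tt <- seq(0, n - 1) / fs
  for (tk in times) {
    dt <- tt - tk
    on <- dt >= 0
    y[on] <- y[on] + (exp(-dt[on] / tau_d) - exp(-dt[on] / tau_r))
  }
  y / max(sd(y), .Machine$double.eps)
}

#' Generate source signals
#'
#' Draws one realization per spec. The random waveform itself does not
#' depend on the class label; the label only selects which entry of
#' `class_gain` scales the finished row, so the class-1 and class-2 versions
#' of a seed differ exactly by an amplitude factor.
#'
#' @param specs List of [source_spec()] objects.
#' @param n_samples Number of samples per source.
#' @param fs Sampling rate in Hz.
#' @param label Class label, 1 or 2.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Numeric matrix, one row per spec.
#' @examples
#' s <- generate_sources(default_source_specs("left"), 350, 100, label = 1, seed = 1)
#' dim(s)
#' @export
generate_sources <- function(specs, n_samples, fs, label = 1, seed = 1) {
  mp_assert(is_count(n_samples), "n_samples must be a positive count", "parameter")
  mp_assert(is.finite(fs) && fs > 0, "fs must be > 0", "parameter")
  mp_assert(label %in% c(1, 2), "label must be 1 or 2", "parameter")
  if (!length(specs) || !all(vapply(specs, inherits, logical(1), "source_spec"))) {
    mp_abort("specs must be a nonempty list of source_spec objects", "invalid_spec")
  }
  out <- matrix(0, nrow = length(specs), ncol = n_samples)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    row <- with_seed(derive_seed(seed, paste0("src", i)), switch(
      sp$kind,
      mu_burst   = gen_band_burst(sp$center_freq, sp$bandwidth, n_samples, fs),
      beta_burst = gen_band_burst(sp$center_freq, sp$bandwidth, n_samples, fs),
      pink_noise = gen_pink(n_samples, fs),
      line_noise = gen_line(sp$center_freq, n_samples, fs),
      blink      = gen_blink(sp$center_freq, n_samples, fs),
      mp_abort(paste0("unknown source kind: ", sp$kind), "invalid_spec")
    ))
    out[i, ] <- row * sp$amplitude * sp$class_gain[label]
  }
  rownames(out) <- vapply(specs, `[[`, character(1), "kind")
  out
}

#' Mix sources into channels
#'
#' Instantaneous linear mixing `x = A s`. Square mixing matrices must be
#' non-singular.
#'
#' @param sources Source matrix (sources x samples).
#' @param A Mixing matrix (channels x sources).
#' @return Channel matrix (channels x samples).
#' @export
mix <- function(sources, A) {
  mp_assert(is.matrix(A) && is.matrix(sources), "sources and A must be matrices", "shape")
  if (ncol(A) != nrow(sources)) {
    mp_abort(sprintf("A has %d columns but there are %d source rows",
                     ncol(A), nrow(sources)), "shape")
  }
  if (nrow(A) == ncol(A)) {
    sv <- svd(A, nu = 0, nv = 0)$d
    if (min(sv) <= max(sv) * 1e-12) {
      mp_abort("square mixing matrix is singular", "singular")
    }
  }
  A %*% sources
}

#' Synthetic dataset configuration
#'
#' @param n_sources_per_cluster,n_channels_per_cluster Counts per hemisphere
#'   cluster; channels must be >= sources.
#' @param fs Sampling rate in Hz; must exceed twice the highest source
#'   frequency.
#' @param trial_duration Trial length in seconds.
#' @param n_trials_per_class Trials per class (two classes).
#' @param mixing_condition_cap Upper bound on the condition number of each
#'   random mixing matrix.
#' @param seed Integer seed fixing all randomness.
#' @param specs_left,specs_right Per-cluster source populations; defaults to
#'   [default_source_specs()] with mirrored class gains.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_sources_per_cluster = 9, n_channels_per_cluster = 9,
                             fs = 100, trial_duration = 3.5, n_trials_per_class = 10,
                             mixing_condition_cap = 20, seed = 1,
                             specs_left = default_source_specs("left", n_sources_per_cluster),
                             specs_right = default_source_specs("right", n_sources_per_cluster)) {
  mp_assert(is_count(n_sources_per_cluster) && is_count(n_channels_per_cluster),
            "source/channel counts must be positive integers", "parameter")
  mp_assert(n_channels_per_cluster >= n_sources_per_cluster,
            "need at least as many channels as sources per cluster", "parameter")
  mp_assert(is_count(n_trials_per_class), "n_trials_per_class must be a count", "parameter")
  mp_assert(is.finite(trial_duration) && trial_duration > 0, "trial_duration must be > 0",
            "parameter")
  mp_assert(length(specs_left) == n_sources_per_cluster &&
              length(specs_right) == n_sources_per_cluster,
            "spec lists must have n_sources_per_cluster entries", "invalid_spec")
  maxf <- max(vapply(c(specs_left, specs_right), function(sp) {
    switch(sp$kind,
           mu_burst = , beta_burst = sp$center_freq + sp$bandwidth,
           line_noise = sp$center_freq,
           0)
  }, numeric(1)))
  mp_assert(fs > 2 * maxf, sprintf("fs must exceed twice the max source frequency (%.1f Hz)",
                                   maxf), "parameter")
  mp_assert(is.finite(mixing_condition_cap) && mixing_condition_cap > 1,
            "mixing_condition_cap must be > 1", "parameter")
  structure(list(n_sources_per_cluster = n_sources_per_cluster,
                 n_channels_per_cluster = n_channels_per_cluster,
                 fs = fs, trial_duration = trial_duration,
                 n_trials_per_class = n_trials_per_class,
                 mixing_condition_cap = mixing_condition_cap,
                 seed = as.integer(seed),
                 specs_left = specs_left, specs_right = specs_right),
            class = "synthetic_config")
}

# Rejection-sample a mixing matrix with bounded condition number.
draw_mixing <- function(n_ch, n_src, cap, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    A <- matrix(rnorm(n_ch * n_src), n_ch, n_src)
    sv <- svd(A, nu = 0, nv = 0)$d
    if (max(sv) / min(sv) <= cap) return(A)
  }
  mp_abort(sprintf("could not draw a mixing matrix with condition number <= %g in %d tries",
                   cap, max_tries), "generation")
}

#' Left/right sensorimotor channel names
#'
#' The default 9 + 9 electrode clusters around the sensorimotor cortex.
#' @return List with `left` and `right` character vectors.
#' @export
sensorimotor_channels <- function() {
  list(left  = c("FC5", "FC3", "FC1", "C5", "C3", "C1", "CP5", "CP3", "CP1"),
       right = c("FC2", "FC4", "FC6", "C2", "C4", "C6", "CP2", "CP4", "CP6"))
}

#' Generate a synthetic two-class trial set
#'
#' Each hemisphere cluster gets its own random mixing matrix (condition
#' number bounded by `mixing_condition_cap`); class-dependent mu/beta gains
#' are mirrored across clusters, giving lateralized class structure. Ground
#' truth (sources, mixing matrices, specs) is retained for oracle checks.
#'
#' @param config A [synthetic_config()].
#' @return A `trial_set`: list with `trials` (channel x time matrices),
#'   `labels`, `fs`, `channel_names`, `ground_truth`.
#' @examples
#' ts <- generate_dataset(synthetic_config(n_trials_per_class = 2, seed = 3))
#' length(ts$trials); table(ts$labels)
#' @export
generate_dataset <- function(config) {
  mp_assert(inherits(config, "synthetic_config"), "config must be a synthetic_config",
            "parameter")
  n_ch <- config$n_channels_per_cluster
  n_src <- config$n_sources_per_cluster
  n_samples <- round(config$trial_duration * config$fs)
  A_left <- with_seed(derive_seed(config$seed, "A_left"),
                      draw_mixing(n_ch, n_src, config$mixing_condition_cap))
  A_right <- with_seed(derive_seed(config$seed, "A_right"),
                       draw_mixing(n_ch, n_src, config$mixing_condition_cap))
  n_trials <- 2L * config$n_trials_per_class
  labels <- rep(c(1L, 2L), times = config$n_trials_per_class)
  chans <- sensorimotor_channels()
  ch_names <- c(head(chans$left, n_ch), head(chans$right, n_ch))
  if (n_ch > 9) ch_names <- c(paste0("L", seq_len(n_ch)), paste0("R", seq_len(n_ch)))
  trials <- vector("list", n_trials)
  gt_sources <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    sl <- generate_sources(config$specs_left, n_samples, config$fs, labels[i],
                           seed = derive_seed(config$seed, paste0("trialL", i)))
    sr <- generate_sources(config$specs_right, n_samples, config$fs, labels[i],
                           seed = derive_seed(config$seed, paste0("trialR", i)))
    x <- rbind(mix(sl, A_left), mix(sr, A_right))
    rownames(x) <- ch_names
    trials[[i]] <- x
    gt_sources[[i]] <- rbind(sl, sr)
  }
  new_trial_set(trials, labels, config$fs, ch_names,
                ground_truth = list(A_left = A_left, A_right = A_right,
                                    sources = gt_sources,
                                    specs_left = config$specs_left,
                                    specs_right = config$specs_right),
                seed = config$seed)
}

new_trial_set <- function(trials, labels, fs, channel_names, ground_truth = NULL,
                          seed = NULL) {
  mp_assert(length(trials) == length(labels), "labels length must match trials", "parameter")
  if (length(trials)) {
    dims <- vapply(trials, dim, integer(2))
    mp_assert(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
              "all trials must share the same shape", "shape")
  }
  structure(list(trials = trials, labels = as.integer(labels), fs = fs,
                 channel_names = channel_names, ground_truth = ground_truth,
                 seed = seed),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  nt <- length(x$trials)
  dims <- if (nt) paste(dim(x$trials[[1]]), collapse = " x ") else "0 x 0"
  cat(sprintf("<trial_set> %d trials (%s) at %g Hz; labels: %s; ground truth: %s\n",
              nt, dims, x$fs, paste(table(x$labels), collapse = "/"),
              if (is.null(x$ground_truth)) "no" else "yes"))
  invisible(x)
}

#' Write / read a trial set on disk
#'
#' One little-endian float64 binary file per trial plus a JSON manifest with
#' labels, sampling rate, channel names and ground-truth file paths. The
#' reader reproduces the original object exactly.
#'
#' @param ts A `trial_set`.
#' @param dir Output directory (created if missing).
#' @return `write_trial_set` returns `dir` invisibly; `read_trial_set`
#'   returns the `trial_set`.
#' @export
write_trial_set <- function(ts, dir) {
  mp_assert(inherits(ts, "trial_set"), "ts must be a trial_set", "parameter")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mat <- function(m, path) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(as.vector(m), con, size = 8, endian = "little")
  }
  files <- character(length(ts$trials))
  for (i in seq_along(ts$trials)) {
    files[i] <- sprintf("trial_%04d.bin", i)
    write_mat(ts$trials[[i]], file.path(dir, files[i]))
  }
  gt <- NULL
  if (!is.null(ts$ground_truth)) {
    gt_dir <- file.path(dir, "ground_truth")
    dir.create(gt_dir, showWarnings = FALSE)
    write_mat(ts$ground_truth$A_left, file.path(gt_dir, "A_left.bin"))
    write_mat(ts$ground_truth$A_right, file.path(gt_dir, "A_right.bin"))
    src_files <- character(length(ts$ground_truth$sources))
    for (i in seq_along(src_files)) {
      src_files[i] <- sprintf("sources_%04d.bin", i)
      write_mat(ts$ground_truth$sources[[i]], file.path(gt_dir, src_files[i]))
    }
    gt <- list(A_dim = dim(ts$ground_truth$A_left), src_dim = dim(ts$ground_truth$sources[[1]]),
               source_files = file.path("ground_truth", src_files),
               A_left = "ground_truth/A_left.bin", A_right = "ground_truth/A_right.bin",
               specs_left = lapply(ts$ground_truth$specs_left, unclass),
               specs_right = lapply(ts$ground_truth$specs_right, unclass))
  }
  manifest <- list(format = "mipipe-trialset-v1",
                   n_trials = length(ts$trials),
                   dim = if (length(ts$trials)) dim(ts$trials[[1]]) else c(0L, 0L),
                   labels = ts$labels, fs = ts$fs, channel_names = ts$channel_names,
                   seed = ts$seed, files = files, ground_truth = gt)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_trial_set
#' @export
read_trial_set <- function(dir) {
  path <- file.path(dir, "manifest.json")
  mp_assert(file.exists(path), paste0("no manifest at ", path), "io")
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  read_mat <- function(path, d) {
    con <- file(path, "rb"); on.exit(close(con))
    matrix(readBin(con, "double", n = prod(d), size = 8, endian = "little"), d[1], d[2])
  }
  d <- as.integer(man$dim)
  trials <- lapply(man$files, function(f) {
    m <- read_mat(file.path(dir, f), d)
    rownames(m) <- man$channel_names
    m
  })
  gt <- NULL
  if (!is.null(man$ground_truth) && length(man$ground_truth)) {
    g <- man$ground_truth
    ad <- as.integer(g$A_dim); sdim <- as.integer(g$src_dim)
    relist_specs <- function(df) {
      lapply(seq_len(nrow(df)), function(i)
        source_spec(df$kind[i], df$center_freq[i], df$bandwidth[i],
                    unlist(df$class_gain[i]), df$amplitude[i]))
    }
    gt <- list(A_left = read_mat(file.path(dir, g$A_left), ad),
               A_right = read_mat(file.path(dir, g$A_right), ad),
               sources = lapply(g$source_files, function(f) {
                 m <- read_mat(file.path(dir, f), sdim)
                 m
               }),
               specs_left = relist_specs(g$specs_left),
               specs_right = relist_specs(g$specs_right))
    for (i in seq_along(gt$sources)) {
      rownames(gt$sources[[i]]) <- c(vapply(gt$specs_left, `[[`, character(1), "kind"),
                                     vapply(gt$specs_right, `[[`, character(1), "kind"))
    }
  }
  new_trial_set(trials, as.integer(man$labels), man$fs, man$channel_names,
                ground_truth = gt, seed = man$seed)
}
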