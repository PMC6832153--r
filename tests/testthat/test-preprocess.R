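make_rec <- function(n_ch = 4, n = 1200, fs = 100, markers = NULL,
                     names = c("C3", "C4", "Cz", "Pz")) {
  withr::with_seed(1, eeg_recording(matrix(rnorm(n_ch * n), n_ch), names, fs, markers))
}

test_that("cluster selection returns montage-ordered rows untouched", {
  rec <- make_rec()
  out <- select_clusters(rec, cluster_montage(left = "C3", right = "C4"))
  expect_identical(out$left, rec$data["C3", , drop = FALSE])
  expect_identical(out$right, rec$data["C4", , drop = FALSE])
  # default montage is the 9 + 9 sensorimotor set
  mon <- cluster_montage()
  expect_length(mon$left, 9)
  expect_length(mon$right, 9)
  big <- eeg_recording(matrix(0, 18, 10), c(mon$left, mon$right), 100)
  sel <- select_clusters(big, mon)
  expect_equal(nrow(sel$left), 9)
  expect_equal(nrow(sel$right), 9)
  expect_identical(rownames(sel$right), mon$right)
})

test_that("missing montage channels are reported by name", {
  rec <- make_rec()
  err <- expect_error(select_clusters(rec, cluster_montage()),
                      class = "mipipe_error_missing_channel")
  expect_match(conditionMessage(err), "CP6")
})

test_that("band-pass keeps the pass band and rejects band edges", {
  fs <- 250
  x <- tone(10, fs, dur = 8)
  y <- bandpass(x, fs)                       # defaults 0.5-90 Hz
  keep <- 500:2000                           # skip the filter transient
  expect_equal(sqrt(mean(y[keep]^2)), sqrt(mean(x[keep]^2)), tolerance = 0.05)
  # DC offset is rejected
  dc <- bandpass(rep(5, 2000), fs)
  expect_lt(abs(mean(dc[500:2000])), 0.05)
  # >= 6 dB attenuation at 0.1 Hz and near Nyquist relative to mid-band
  fs2 <- 1000
  mid <- bandpass(tone(10, fs2, 30), fs2)
  lo <- bandpass(tone(0.1, fs2, 30), fs2)
  hi <- bandpass(tone(0.99 * fs2 / 2, fs2, 30), fs2)
  rms <- function(v) sqrt(mean(v[10000:25000]^2))
  expect_lt(rms(lo) / rms(mid), 0.5)
  expect_lt(rms(hi) / rms(mid), 0.5)
  expect_error(bandpass(x, fs, low = 50, high = 40), class = "mipipe_error_cutoff")
  expect_error(bandpass(x, 100, low = 0.5, high = 90), class = "mipipe_error_cutoff")
})

test_that("filtering is per-channel: permuting rows commutes with filtering", {
  x <- matrix(rnorm(3 * 500), 3)
  perm <- c(3, 1, 2)
  a <- bandpass(x, 100, 1, 40)[perm, ]
  b <- bandpass(x[perm, ], 100, 1, 40)
  expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("epoching extracts the 4.5-8 s MI segment per marker", {
  markers <- data.frame(sample = c(1, 201), label = c(1, 2))
  rec <- make_rec(n = 1100, markers = markers)
  ts <- epoch_trials(rec)
  expect_length(ts$trials, 2)
  expect_equal(ncol(ts$trials[[1]]), (8.0 - 4.5) * 100)   # hand-checked: 350
  expect_identical(ts$labels, c(1L, 2L))
  # trial content equals the raw slice
  expect_identical(ts$trials[[2]], rec$data[, (200 + 450 + 1):(200 + 800)])
  # label multiset preserved under any marker ordering
  m2 <- data.frame(sample = c(150, 1, 120), label = c(2L, 1L, 2L))
  ts2 <- epoch_trials(eeg_recording(rec$data, rec$channel_names, rec$fs, m2))
  expect_identical(sort(ts2$labels), sort(m2$label))
})

test_that("epoching edge cases: no markers, window past record end", {
  rec <- make_rec(n = 1000)
  expect_length(epoch_trials(rec)$trials, 0)
  bad <- eeg_recording(rec$data, rec$channel_names, rec$fs,
                       data.frame(sample = 900, label = 1))
  expect_error(epoch_trials(bad), class = "mipipe_error_epoching")
})

test_that("recordings round-trip through delimited text and EDF", {
  rec <- make_rec(n_ch = 3, n = 500, names = c("C3", "C4", "Cz"),
                  markers = data.frame(sample = c(1, 100), label = c(1, 2)))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rec.tsv")
  write_eeg_delim(rec, p)
  r2 <- read_eeg_delim(p)
  expect_identical(r2$channel_names, rec$channel_names)
  expect_equal(r2$fs, rec$fs)
  expect_equal(r2$data, rec$data, tolerance = 1e-12)
  expect_equal(r2$markers$label, rec$markers$label)

  pe <- file.path(dir, "rec.edf")
  write_edf(rec, pe)
  r3 <- read_edf(pe)
  expect_identical(r3$channel_names, rec$channel_names)
  expect_equal(r3$fs, rec$fs)
  # 16-bit quantization: accurate to the amplitude resolution
  expect_lt(max(abs(r3$data - rec$data)), diff(range(rec$data)) / 2^15)
})
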