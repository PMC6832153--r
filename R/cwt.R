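# Continuous wavelet transform with generalized Morse wavelets, sliding
# window scalogram maps, and assembly of the stacked 128x256 trial images.

#' Generalized Morse wavelet scalogram
#'
#' Analytic CWT computed in the frequency domain: the signal is zero-padded
#' to a power of two and multiplied by Morse wavelet filters
#' `psi_hat(w) ~ w^beta * exp(-w^gamma)` (supported on positive frequencies
#' only, peak normalized to 2). The frequency axis is logarithmic from 1 Hz
#' to `0.9 * fs / 2`, with `voices_per_octave` bins per octave.
#'
#' @param signal Numeric vector, length >= 16, all finite.
#' @param fs Sampling rate in Hz.
#' @param gamma,beta Morse shape parameters (> 0); the defaults (3, 20)
#'   give the standard symmetric, Airy-like family.
#' @param voices_per_octave Frequency bins per octave.
#' @return A `scalogram`: list with `freqs` (Hz, ascending), `scales`
#'   (dimensionless, aligned with `freqs`), `times` (s), and nonnegative
#'   `magnitude` (frequency x time).
#' @examples
#' sc <- morse_cwt(sin(2 * pi * 10 * seq(0, 2, by = 0.01)), fs = 100)
#' sc$freqs[which.max(rowMeans(sc$magnitude))]
#' @export
morse_cwt <- function(signal, fs, gamma = 3, beta = 20, voices_per_octave = 12) {
  mp_assert(is.numeric(signal) && length(signal) >= 16, "signal must have >= 16 samples",
            "parameter")
  if (!all(is.finite(signal))) mp_abort("signal contains non-finite samples", "data")
  mp_assert(gamma > 0 && beta > 0, "gamma and beta must be > 0", "parameter")
  mp_assert(is_count(voices_per_octave), "voices_per_octave must be a count", "parameter")
  n <- length(signal)
  n2 <- 2^ceiling(log2(n))
  X <- stats::fft(c(signal, numeric(n2 - n)))
  w_peak <- (beta / gamma)^(1 / gamma)
  fmin <- 1
  fmax <- 0.9 * fs / 2
  n_oct <- log2(fmax / fmin)
  nf <- floor(n_oct * voices_per_octave) + 1L
  freqs <- fmin * 2^((seq_len(nf) - 1) / voices_per_octave)
  scales <- w_peak / (2 * pi * freqs / fs)
  omega <- 2 * pi * seq(0, n2 - 1) / n2
  pos <- seq_len(floor(n2 / 2) + 1L)           # analytic: positive frequencies only
  mag <- matrix(0, nf, n)
  for (j in seq_len(nf)) {
    aw <- scales[j] * omega[pos]
    H <- numeric(n2)
    nz <- aw > 0
    H[pos][nz] <- 2 * exp(beta * (log(aw[nz]) - log(w_peak)) - (aw[nz]^gamma - w_peak^gamma))
    W <- stats::fft(X * H, inverse = TRUE) / n2
    mag[j, ] <- Mod(W[seq_len(n)])
  }
  structure(list(freqs = freqs, scales = scales, times = seq(0, n - 1) / fs,
                 magnitude = mag),
            class = "scalogram")
}

#' Sliding-window stacked scalogram maps
#'
#' Slides a `window`-second window in `step`-second increments over a
#' matrix of (already sorted) sources; within each window, computes the
#' Morse scalogram of every source row and stacks them vertically in row
#' order (the pipeline supplies rows as left-cluster sources followed by
#' right-cluster sources). Within each source block, rows run from high to
#' low frequency, so the vertical image axis carries frequency-by-source
#' information and the horizontal axis carries time.
#'
#' @param sources Source-by-time matrix.
#' @param fs Sampling rate in Hz.
#' @param window,step Window length and hop in seconds. Windows start at
#'   offsets `0, step, 2 step, ...` while `offset + window <= duration`,
#'   giving `floor((duration - window) / step) + 1` windows.
#' @param gamma,beta,voices_per_octave Passed to [morse_cwt()].
#' @return List of stacked magnitude matrices, one per window, with the
#'   window offsets (s) as attribute `offsets`.
#' @export
window_maps <- function(sources, fs, window = 1.0, step = 0.25,
                        gamma = 3, beta = 20, voices_per_octave = 12) {
  mp_assert(is.matrix(sources) && nrow(sources) >= 1, "sources must be a matrix", "parameter")
  duration <- ncol(sources) / fs
  if (window > duration + 1e-9) {
    mp_abort(sprintf("window (%g s) exceeds trial duration (%g s)", window, duration),
             "window")
  }
  k <- floor((duration - window) / step + 1e-9) + 1L
  offsets <- (seq_len(k) - 1) * step
  wlen <- round(window * fs)
  maps <- vector("list", k)
  for (w in seq_len(k)) {
    i0 <- round(offsets[w] * fs)
    idx <- (i0 + 1):(i0 + wlen)
    blocks <- lapply(seq_len(nrow(sources)), function(r) {
      sc <- morse_cwt(sources[r, idx], fs, gamma, beta, voices_per_octave)
      sc$magnitude[rev(seq_along(sc$freqs)), , drop = FALSE]   # high freq on top
    })
    maps[[w]] <- do.call(rbind, blocks)
  }
  attr(maps, "offsets") <- offsets
  maps
}

#' Rescale a stacked map to a 128x256 trial image
#'
#' Bilinear resize to 128 rows by 256 columns followed by min-max
#' normalization into `[0, 1]`. A constant input maps to all zeros.
#'
#' @param map Nonempty numeric matrix.
#' @param trial_id,window_index,label Optional bookkeeping attached to the
#'   image.
#' @return A `trial_image`: list with `pixels` (128x256 in `[0, 1]`),
#'   `window_index`, `trial_id`, `label`.
#' @export
rescale_image <- function(map, trial_id = NA, window_index = NA_integer_, label = NA_integer_) {
  mp_assert(is.matrix(map) && length(map) > 0, "map must be a nonempty matrix", "parameter")
  px <- if (nrow(map) == 128 && ncol(map) == 256) map else {
    EBImage::imageData(EBImage::resize(map, w = 128, h = 256, filter = "bilinear"))
  }
  rng <- range(px)
  px <- if (rng[2] - rng[1] <= 0) matrix(0, 128, 256) else (px - rng[1]) / (rng[2] - rng[1])
  structure(list(pixels = px, window_index = window_index, trial_id = trial_id,
                 label = label),
            class = "trial_image")
}

#' @export
print.trial_image <- function(x, ...) {
  cat(sprintf("<trial_image> 128 x 256, trial %s window %s label %s, range [%.3f, %.3f]\n",
              x$trial_id, x$window_index, x$label, min(x$pixels), max(x$pixels)))
  invisible(x)
}
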