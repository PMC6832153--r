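# Internal helpers shared across modules.

# Signal an error with a package-specific condition class so callers and tests
# can match on `mipipe_error_<what>`.
mp_abort <- function(message, what, ...) {
  rlang::abort(message, class = c(paste0("mipipe_error_", what), "mipipe_error"), ...)
}

mp_assert <- function(cond, message, what) {
  if (!isTRUE(cond)) mp_abort(message, what)
  invisible(TRUE)
}

# Deterministically derive a child seed from a parent seed and a tag.
# Keeps results in [0, 2^31 - 2] so they are valid R integer seeds.
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1, is.finite(seed))
  chars <- utf8ToInt(paste0(tag))
  h <- as.double(seed %% 2147483647)
  for (ch in chars) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram (Hann taper, 50% overlap by default) of a
#' one-dimensional signal. Used internally by [spectral_profile()]; exported
#' because it is also convenient for inspecting synthetic sources.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param seg_len Segment length in samples. Defaults to `min(length(x),
#'   round(fs))`, i.e. one-second segments.
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @return A list with `freq` (Hz, from 0 to `fs/2`) and `power`
#'   (one-sided PSD, signal units squared per Hz).
#' @examples
#' psd <- welch_psd(sin(2 * pi * 10 * seq(0, 4, by = 0.01)), fs = 100)
#' psd$freq[which.max(psd$power)]
#' @export
welch_psd <- function(x, fs, seg_len = min(length(x), round(fs)), overlap = 0.5) {
  n <- length(x)
  mp_assert(n >= seg_len && seg_len >= 8, "signal shorter than one PSD segment", "length")
  mp_assert(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)", "parameter")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  scale <- fs * sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / scale
    p <- p[seq_len(nf)]
    # fold two-sided spectrum into one-sided (DC and Nyquist not doubled)
    inner <- 2:(nf - 1L)
    if (seg_len %% 2 == 1) inner <- 2:nf
    p[inner] <- 2 * p[inner]
    acc <- acc + p
  }
  list(freq = seq(0, by = fs / seg_len, length.out = nf),
       power = acc / length(starts))
}

# Trapezoidal area under y(x).
trapz_area <- function(x, y) pracma::trapz(x, y)
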