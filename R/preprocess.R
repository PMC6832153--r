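# Channel-cluster selection, band-pass filtering, and trial epoching.

#' Continuous multichannel EEG recording
#'
#' @param data Channel-by-time numeric matrix (microvolts).
#' @param channel_names Character vector, one name per row of `data`.
#' @param fs Sampling rate in Hz.
#' @param markers Optional data frame with columns `sample` (1-based sample
#'   index of the trial onset) and `label` (class, 1 or 2).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, channel_names, fs, markers = NULL) {
  mp_assert(is.matrix(data) && is.numeric(data), "data must be a numeric matrix", "parameter")
  mp_assert(length(channel_names) == nrow(data),
            "channel_names length must equal the number of data rows", "parameter")
  mp_assert(is.finite(fs) && fs > 0, "fs must be > 0", "parameter")
  if (is.null(markers)) {
    markers <- data.frame(sample = integer(0), label = integer(0))
  }
  mp_assert(all(c("sample", "label") %in% names(markers)),
            "markers needs columns 'sample' and 'label'", "parameter")
  mp_assert(all(markers$sample >= 1 & markers$sample <= ncol(data)),
            "marker sample indices must lie within the record", "parameter")
  rownames(data) <- channel_names
  structure(list(data = data, channel_names = channel_names, fs = fs,
                 markers = as.data.frame(markers)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples at %g Hz (%.1f s), %d markers\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, nrow(x$markers)))
  invisible(x)
}

#' Left/right channel cluster montage
#'
#' Defaults to the 9 + 9 sensorimotor electrodes used throughout the
#' pipeline (see [sensorimotor_channels()]).
#'
#' @param left,right Ordered channel-name vectors; must be disjoint.
#' @return A `cluster_montage` object.
#' @export
cluster_montage <- function(left = sensorimotor_channels()$left,
                            right = sensorimotor_channels()$right) {
  mp_assert(length(left) > 0 && length(right) > 0, "montage clusters must be nonempty",
            "parameter")
  mp_assert(!anyDuplicated(c(left, right)), "montage clusters must be disjoint", "parameter")
  structure(list(left = left, right = right), class = "cluster_montage")
}

#' Split a recording into hemisphere clusters
#'
#' @param rec An [eeg_recording()].
#' @param montage A [cluster_montage()].
#' @return List with `left` and `right` channel matrices whose rows follow
#'   the montage order exactly; values are untouched.
#' @export
select_clusters <- function(rec, montage = cluster_montage()) {
  mp_assert(inherits(rec, "eeg_recording"), "rec must be an eeg_recording", "parameter")
  mp_assert(inherits(montage, "cluster_montage"), "montage must be a cluster_montage",
            "parameter")
  wanted <- c(montage$left, montage$right)
  missing <- setdiff(wanted, rec$channel_names)
  if (length(missing)) {
    mp_abort(paste0("channels not in recording: ", paste(missing, collapse = ", ")),
             "missing_channel")
  }
  list(left = rec$data[montage$left, , drop = FALSE],
       right = rec$data[montage$right, , drop = FALSE])
}

#' Butterworth band-pass filter
#'
#' Per-channel IIR Butterworth band-pass. The default is a single causal
#' pass of the stated order; `zero_phase = TRUE` switches to
#' forward-backward filtering (which doubles the effective order).
#'
#' @param x Numeric vector or channel-by-time matrix.
#' @param fs Sampling rate in Hz.
#' @param low,high Cut-off frequencies in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth design order (per band edge).
#' @param zero_phase Use `signal::filtfilt` instead of a causal pass.
#' @return Filtered object of the same shape as `x`.
#' @export
bandpass <- function(x, fs, low = 0.5, high = 90, order = 2, zero_phase = FALSE) {
  mp_assert(is.finite(low) && is.finite(high) && low > 0 && low < high,
            "need 0 < low < high", "cutoff")
  if (high >= fs / 2) mp_abort("high cut-off must be below the Nyquist frequency", "cutoff")
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  run <- function(v) {
    if (zero_phase) as.numeric(signal::filtfilt(flt, v))
    else as.numeric(signal::filter(flt, v))
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1, run))
    dimnames(out) <- dimnames(x)
    out
  } else {
    run(x)
  }
}

#' Epoch a recording into labelled trials
#'
#' Extracts, for every marker, the motor-imagery segment
#' `[window_start, window_end)` seconds after trial onset. Sample indices
#' follow the half-open convention `[round(start * fs), round(end * fs))`
#' relative to the marker, so at 100 Hz the default 4.5-8.0 s window yields
#' exactly 350 samples.
#'
#' @param rec An [eeg_recording()] with markers.
#' @param window_start,window_end Segment bounds in seconds after onset.
#' @return A `trial_set` (labels copied from markers, no ground truth).
#' @export
epoch_trials <- function(rec, window_start = 4.5, window_end = 8.0) {
  mp_assert(inherits(rec, "eeg_recording"), "rec must be an eeg_recording", "parameter")
  mp_assert(window_end > window_start && window_start >= 0,
            "need 0 <= window_start < window_end", "parameter")
  i0 <- round(window_start * rec$fs)
  i1 <- round(window_end * rec$fs)
  trials <- vector("list", nrow(rec$markers))
  for (k in seq_len(nrow(rec$markers))) {
    m <- rec$markers$sample[k]
    cols <- (m + i0):(m + i1 - 1L)
    if (max(cols) > ncol(rec$data)) {
      mp_abort(sprintf("window for marker %d (sample %d) runs past the record end", k, m),
               "epoching")
    }
    trials[[k]] <- rec$data[, cols, drop = FALSE]
  }
  new_trial_set(trials, rec$markers$label, rec$fs, rec$channel_names)
}
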