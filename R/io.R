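# Readers and writers for external EEG formats.

#' Read a delimited EEG matrix with a JSON sidecar
#'
#' The matrix file holds samples in rows and channels in columns (no
#' header); the sidecar is a JSON object with `channel_names`, `fs`, and
#' optionally `markers` (array of objects with `sample`, `label`).
#'
#' @param matrix_path Path to the delimited numeric matrix.
#' @param sidecar_path Path to the JSON sidecar; defaults to
#'   `<matrix_path>.json`.
#' @param sep Field separator (default: any whitespace).
#' @return An [eeg_recording()].
#' @export
read_eeg_delim <- function(matrix_path, sidecar_path = paste0(matrix_path, ".json"),
                           sep = "") {
  mp_assert(file.exists(matrix_path), paste0("no such file: ", matrix_path), "io")
  mp_assert(file.exists(sidecar_path), paste0("no such sidecar: ", sidecar_path), "io")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  mp_assert(!is.null(meta$channel_names) && !is.null(meta$fs),
            "sidecar must provide channel_names and fs", "io")
  m <- as.matrix(read.table(matrix_path, sep = sep, header = FALSE))
  mp_assert(ncol(m) == length(meta$channel_names),
            "matrix columns must match channel_names length", "io")
  markers <- NULL
  if (!is.null(meta$markers) && length(meta$markers)) {
    markers <- as.data.frame(meta$markers)
  }
  eeg_recording(t(m), meta$channel_names, meta$fs, markers)
}

#' Write a recording as a delimited matrix plus JSON sidecar
#'
#' @param rec An [eeg_recording()].
#' @param matrix_path Output path for the matrix (samples in rows).
#' @param sidecar_path Output path for the JSON sidecar.
#' @return `matrix_path`, invisibly.
#' @export
write_eeg_delim <- function(rec, matrix_path, sidecar_path = paste0(matrix_path, ".json")) {
  mp_assert(inherits(rec, "eeg_recording"), "rec must be an eeg_recording", "parameter")
  write.table(t(rec$data), matrix_path, sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(channel_names = rec$channel_names, fs = rec$fs)
  if (nrow(rec$markers)) meta$markers <- rec$markers
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(matrix_path)
}

# --- EDF (European Data Format) ------------------------------------------
# Fixed 256-byte header, one 256-byte block per signal, then data records of
# 16-bit little-endian integers mapped linearly from digital to physical
# range. Continuous recordings with a uniform sampling rate only; EDF+
# annotation channels are not interpreted.

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read an EDF file
#'
#' Minimal EDF reader: channel names and sampling rate are taken from the
#' header, samples are scaled to physical units. All signals must share one
#' sampling rate. EDF carries no trial markers; supply them via `markers`.
#'
#' @param path Path to the EDF file.
#' @param markers Optional markers data frame (`sample`, `label`).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, markers = NULL) {
  mp_assert(file.exists(path), paste0("no such file: ", path), "io")
  con <- file(path, "rb"); on.exit(close(con))
  version <- read_ascii(con, 8)
  mp_assert(version == "0", "not an EDF file (version field != '0')", "io")
  invisible(readBin(con, "raw", 80 + 80 + 8 + 8))   # patient, recording, date, time
  invisible(read_ascii(con, 8))                     # header length
  invisible(readBin(con, "raw", 44))                # reserved
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  field <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), character(1))
  labels <- field(16)
  invisible(field(80)); invisible(field(8))         # transducer, physical dim
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  invisible(field(80))                              # prefilter
  spr <- as.integer(field(8))                       # samples per record
  invisible(field(32))                              # reserved
  mp_assert(all(spr == spr[1]), "signals with mixed sampling rates are not supported", "io")
  fs <- spr[1] / rec_dur
  n_total <- n_rec * spr[1]
  data <- matrix(0, ns, n_total)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE, endian = "little")
      data[s, ((r - 1) * spr[1] + 1):(r * spr[1])] <- (d - dig_min[s]) * gain[s] + phys_min[s]
    }
  }
  eeg_recording(data, labels, fs, markers)
}

pad_ascii <- function(x, w) {
  s <- formatC(as.character(x), width = -w)
  mp_assert(all(nchar(s) == w), "EDF header field overflow", "io")
  s
}

#' Write an EDF file
#'
#' Counterpart of [read_edf()]. The physical range is taken from the data;
#' samples are quantized to 16 bits. The record length is one second, so
#' the recording is truncated to a whole number of seconds.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  mp_assert(inherits(rec, "eeg_recording"), "rec must be an eeg_recording", "parameter")
  ns <- nrow(rec$data)
  spr <- as.integer(round(rec$fs))
  mp_assert(abs(spr - rec$fs) < 1e-9, "write_edf needs an integer sampling rate", "io")
  n_rec <- floor(ncol(rec$data) / spr)
  mp_assert(n_rec >= 1, "recording shorter than one EDF record (1 s)", "io")
  x <- rec$data[, seq_len(n_rec * spr), drop = FALSE]
  phys_min <- apply(x, 1, min); phys_max <- apply(x, 1, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  dig_min <- rep(-32768L, ns); dig_max <- rep(32767L, ns)
  header_len <- 256L + 256L * ns
  con <- file(path, "wb"); on.exit(close(con))
  put <- function(x, w) writeBin(charToRaw(paste0(pad_ascii(x, w), collapse = "")), con)
  put("0", 8)
  put("synthetic", 80); put("mipipe export", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(header_len, 8); put("", 44)
  put(n_rec, 8); put("1", 8); put(ns, 4)
  put(rec$channel_names, 16)
  put(rep("", ns), 80); put(rep("uV", ns), 8)
  put(formatC(phys_min, format = "g", digits = 6), 8)
  put(formatC(phys_max, format = "g", digits = 6), 8)
  put(dig_min, 8); put(dig_max, 8)
  put(rep("", ns), 80); put(rep(spr, ns), 8); put(rep("", ns), 32)
  # re-read the formatted physical range so reader and writer agree exactly
  pmin_used <- as.numeric(formatC(phys_min, format = "g", digits = 6))
  pmax_used <- as.numeric(formatC(phys_max, format = "g", digits = 6))
  gain <- (pmax_used - pmin_used) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- x[s, ((r - 1) * spr + 1):(r * spr)]
      d <- round((seg - pmin_used[s]) / gain[s]) + dig_min[s]
      writeBin(as.integer(pmin(pmax(d, dig_min[s]), dig_max[s])), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
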