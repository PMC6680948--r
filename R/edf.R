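#' Write a synthetic record to European Data Format (EDF)
#'
#' Minimal EDF (16-bit) writer for the package's synthetic records: one data
#' record per second, all channels at the record's sampling rate, physical
#' range set symmetrically from the data. A trailing partial second is
#' dropped (EDF stores whole data records only).
#'
#' @param record An `ieeg_record` from [simulate_record()], or a list of
#'   equal-length per-channel numeric vectors.
#' @param path Output file path.
#' @param sampling_rate Required when `record` is a bare list of signals.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path, sampling_rate = NULL) {
  if (inherits(record, "ieeg_record")) {
    signals <- record$signals
    fs <- record$config_echo$sampling_rate
  } else {
    signals <- record
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for bare signal lists", call. = FALSE)
  }
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(fs)
  ns <- length(signals)
  n_rec <- floor(length(signals[[1]]) / fs)
  if (n_rec < 1) stop("record shorter than one EDF data record (1 s)", call. = FALSE)

  pad <- function(s, width) {
    s <- substr(s, 1, width)
    formatC(s, width = -width, flag = " ")
  }
  phys_max <- vapply(signals, function(x) max(abs(x), 1e-6), 0)
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X synthetic record", 80), pad("Startdate 01-JAN-2000", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(as.character(256L * (1L + ns)), 8), pad("", 44),
    pad(as.character(n_rec), 8), pad("1", 8), pad(as.character(ns), 4)
  )
  field <- function(f, width) paste(vapply(seq_len(ns), f, ""), collapse = "")
  hdr <- paste0(
    hdr,
    field(function(i) pad(sprintf("iEEG %d", i), 16), 16),
    field(function(i) pad("synthetic", 80), 80),
    field(function(i) pad("uV", 8), 8),
    field(function(i) pad(sprintf("%-.6g", -phys_max[i]), 8), 8),
    field(function(i) pad(sprintf("%-.6g", phys_max[i]), 8), 8),
    field(function(i) pad("-32768", 8), 8),
    field(function(i) pad("32767", 8), 8),
    field(function(i) pad("", 80), 80),
    field(function(i) pad(as.character(fs), 8), 8),
    field(function(i) pad("", 32), 32)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(pmax(-32768, pmin(32767, round(signals[[i]][idx] * scale[i]))))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Companion reader covering the subset of EDF emitted by [write_edf()]
#' (uniform sampling rate, 16-bit samples); used for round-trip verification
#' of persisted signals.
#'
#' @param path EDF file path.
#' @return List with `signals` (per-channel numeric vectors, physical units)
#'   and `sampling_rate`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) readChar(con, nc, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8)
  as.integer(rd(8)) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  as.numeric(rd(8)) # record duration (1 s)
  ns <- as.integer(rd(4))
  rfield <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  rfield(16); rfield(80); rfield(8)
  phys_min <- as.numeric(rfield(8))
  phys_max <- as.numeric(rfield(8))
  dig_min <- as.numeric(rfield(8))
  dig_max <- as.numeric(rfield(8))
  rfield(80)
  spr <- as.integer(rfield(8))
  rfield(32)
  sig <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little")
      phys <- phys_min[i] + (dig - dig_min[i]) *
        (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      sig[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  list(signals = sig, sampling_rate = spr[1])
}
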