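# Minimal European Data Format (EDF) support: fixed-width ASCII header plus
# little-endian int16 data records, uniform sampling rate across signals.

edf_field <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", width)))
}

#' Read a multichannel recording from an EDF file
#'
#' Supports plain EDF with a uniform sampling rate: every signal must have
#' the same samples-per-record count; mixed per-channel rates raise an
#' explicit unsupported-format error. Digital values are mapped to physical
#' units via the per-signal calibration fields.
#'
#' @param path path to the EDF file.
#' @return an [recording()] object with labels from the signal headers.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  if (version != "0") stop_invalid("not an EDF file (version '", version, "')")
  edf_field(con, 80); edf_field(con, 80)          # patient, recording ids
  edf_field(con, 8); edf_field(con, 8)            # start date, time
  edf_field(con, 8)                               # header byte count
  edf_field(con, 44)                              # reserved
  n_records <- as.integer(edf_field(con, 8))
  record_duration <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1) stop_invalid("EDF header: bad signal count")
  fields <- function(width, type = "character") {
    v <- vapply(seq_len(ns), function(i) edf_field(con, width), character(1))
    if (type == "numeric") as.numeric(v) else v
  }
  labels <- fields(16)
  fields(80)                                      # transducer
  fields(8)                                       # physical dimension
  phys_min <- fields(8, "numeric")
  phys_max <- fields(8, "numeric")
  dig_min <- fields(8, "numeric")
  dig_max <- fields(8, "numeric")
  fields(80)                                      # prefiltering
  spr <- as.integer(fields(8, "numeric"))         # samples per record
  fields(32)                                      # reserved
  if (length(unique(spr)) != 1) {
    stop_invalid("unsupported EDF: signals have differing per-record sample",
                 " counts (per-channel sampling rates): ",
                 paste(unique(spr), collapse = ", "))
  }
  spr1 <- spr[1]
  sampling_rate <- spr1 / record_duration
  X <- matrix(0, n_records * spr1, ns)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr1, size = 2, endian = "little")
      X[((r - 1) * spr1 + 1):(r * spr1), s] <-
        (dig - dig_min[s]) * (phys_max[s] - phys_min[s]) /
        (dig_max[s] - dig_min[s]) + phys_min[s]
    }
  }
  recording(X, sampling_rate, make.unique(labels))
}

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop_invalid("EDF field too long: ", x)
  formatC(x, width = -width)
}

# shortest decimal representation of x that fits an EDF numeric field
edf_num <- function(x, width = 8) {
  for (d in 7:1) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= width) return(s)
  }
  stop_invalid("cannot format ", x, " in ", width, " characters")
}

#' Write a recording to an EDF file
#'
#' Digital values use the full int16 range scaled to each channel's observed
#' amplitude range. One data record per second.
#'
#' @param rec an [recording()] object; `n_samples` must be a multiple of the
#'   sampling rate and the rate an integer.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "mc_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop_invalid("EDF writer needs an integer rate")
  n <- n_samples(rec); K <- n_channels(rec)
  if (n %% fs != 0) stop_invalid("n_samples must be a multiple of the rate")
  n_records <- n %/% fs
  phys_min <- apply(rec$data, 2, min)
  phys_max <- apply(rec$data, 2, max)
  phys_max <- ifelse(phys_max > phys_min, phys_max, phys_min + 1)
  # store the values exactly as the truncated header fields will say
  phys_min <- vapply(phys_min, function(x) as.numeric(edf_num(x)), 0)
  phys_max <- vapply(phys_max, function(x) as.numeric(edf_num(x)), 0)
  phys_max <- pmax(phys_max, phys_min + 1e-6)
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + 256 * K, 8); wr("", 44)
  wr(n_records, 8); wr("1", 8); wr(K, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(K)) wr("", 80)
  for (i in seq_len(K)) wr("uV", 8)
  for (i in seq_len(K)) wr(edf_num(phys_min[i]), 8)
  for (i in seq_len(K)) wr(edf_num(phys_max[i]), 8)
  for (i in seq_len(K)) wr(dig_min, 8)
  for (i in seq_len(K)) wr(dig_max, 8)
  for (i in seq_len(K)) wr("", 80)
  for (i in seq_len(K)) wr(as.integer(fs), 8)
  for (i in seq_len(K)) wr("", 32)
  for (r in seq_len(n_records)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(K)) {
      dig <- round((rec$data[rows, s] - phys_min[s]) /
                     (phys_max[s] - phys_min[s]) *
                     (dig_max - dig_min) + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
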