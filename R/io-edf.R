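# Minimal EDF (European Data Format) support: continuous recordings,
# identical sampling rate on every signal, 16-bit little-endian samples,
# 1-second data records. Covers what a 10/20 resting-state recording needs;
# EDF+ annotation signals are not parsed.

edf_field <- function(x, width) {
  s <- formatC(substr(as.character(x), 1L, width), width = -width)
  substr(s, 1L, width)
}

read_edf <- function(path, participant_id = NULL, group = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    trimws(rawToChar(readBin(con, "raw", nchars)))
  }
  version <- rd(8L)
  patient <- rd(80L)
  rd(80L)                       # recording id
  rd(8L); rd(8L)                # start date, start time
  header_bytes <- as.integer(rd(8L))
  rd(44L)                       # reserved
  n_records <- as.integer(rd(8L))
  record_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (!isTRUE(ns >= 1L)) stop("format error: EDF header has no signals")
  labels    <- vapply(seq_len(ns), function(i) rd(16L), "")
  for (i in seq_len(ns)) rd(80L)              # transducer
  for (i in seq_len(ns)) rd(8L)               # physical dimension
  phys_min  <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), 0)
  phys_max  <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), 0)
  dig_min   <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), 0)
  dig_max   <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), 0)
  for (i in seq_len(ns)) rd(80L)              # prefiltering
  spr       <- vapply(seq_len(ns), function(i) as.integer(rd(8L)), 0L)
  for (i in seq_len(ns)) rd(32L)              # reserved
  if (!is.finite(record_dur) || record_dur <= 0)
    stop("format error: EDF record duration missing or invalid")
  if (length(unique(spr)) != 1L)
    stop("format error: signals with differing sampling rates are not supported")
  fs <- spr[1L] / record_dur
  if (anyDuplicated(tolower(labels)))
    stop("format error: duplicate channel label in EDF header")

  seek(con, header_bytes)
  total <- n_records * sum(spr)
  raw16 <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                   endian = "little")
  if (length(raw16) != total)
    stop("format error: EDF data shorter than header promises")
  # records are interleaved: per record, spr samples of each signal in turn
  dat <- matrix(0, nrow = n_records * spr[1L], ncol = ns)
  per_rec <- sum(spr)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (s in seq_len(ns)) {
    off <- sum(spr[seq_len(s - 1L)])
    idx <- as.vector(outer(seq_len(spr[1L]) + off, (seq_len(n_records) - 1L) * per_rec, "+"))
    dat[, s] <- (raw16[idx] - dig_min[s]) * scale[s] + phys_min[s]
  }
  if (is.null(participant_id))
    participant_id <- if (nzchar(patient)) patient else
      tools::file_path_sans_ext(basename(path))
  eeg_recording(dat, fs = fs, channels = labels,
                participant_id = participant_id, group = group)
}

write_edf <- function(rec, path) {
  n <- nrow(rec$data)
  ns <- ncol(rec$data)
  if (rec$fs != round(rec$fs))
    stop("EDF writer requires an integer sampling rate")
  spr <- as.integer(rec$fs)              # 1-second records
  n_records <- n %/% spr
  if (n_records < 1L || n_records * spr != n)
    stop("EDF writer requires a whole number of 1-second records; ",
         "trim the recording to full seconds first")
  phys_min <- apply(rec$data, 2L, min)
  phys_max <- apply(rec$data, 2L, max)
  pad <- pmax((phys_max - phys_min) * 1e-3, 1e-3)
  phys_min <- floor((phys_min - pad) * 100) / 100
  phys_max <- ceiling((phys_max + pad) * 100) / 100
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) {   # each element padded to `width` bytes
    writeBin(charToRaw(paste(edf_field(x, width), collapse = "")), con)
  }
  header_bytes <- 256L + 256L * ns
  wr("0", 8L)
  wr(rec$participant_id, 80L)
  wr("eegcomplexity", 80L)
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(header_bytes, 8L)
  wr("", 44L)
  wr(n_records, 8L)
  wr("1", 8L)
  wr(ns, 4L)
  wr(rec$channels, 16L)
  wr(rep("", ns), 80L)
  wr(rep("uV", ns), 8L)
  wr(formatC(phys_min, format = "f", digits = 2), 8L)
  wr(formatC(phys_max, format = "f", digits = 2), 8L)
  wr(rep(dig_min, ns), 8L)
  wr(rep(dig_max, ns), 8L)
  wr(rep("", ns), 80L)
  wr(rep(spr, ns), 8L)
  wr(rep("", ns), 32L)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- matrix(0L, nrow = n, ncol = ns)
  for (s in seq_len(ns)) {
    v <- round((rec$data[, s] - phys_min[s]) * scale[s] + dig_min)
    dig[, s] <- as.integer(pmin(pmax(v, dig_min), dig_max))
  }
  # interleave per record
  out <- integer(n_records * spr * ns)
  per_rec <- spr * ns
  for (s in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr) + (s - 1L) * spr,
                           (seq_len(n_records) - 1L) * per_rec, "+"))
    out[idx] <- dig[, s]
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}
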