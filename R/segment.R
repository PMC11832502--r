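#' Construct an analysis segment
#'
#' A segment is a contiguous window of a recording, addressed with 0-based
#' half-open sample indexing `[start, start + n)`. If the recording carries an
#' artifact mask, the window must be entirely clean.
#'
#' @param rec An [eeg_recording].
#' @param start 0-based first sample of the window.
#' @param n Number of samples in the window.
#' @return An object of class `eeg_segment`.
#' @export
segment <- function(rec, start, n) {
  start <- as.integer(start); n <- as.integer(n)
  if (start < 0L) stop("segment start must be >= 0")
  if (n < 1L) stop("segment length must be >= 1")
  if (start + n > n_samples(rec))
    stop("segment [", start, ", ", start + n, ") exceeds recording length ",
         n_samples(rec))
  if (!all(rec$artifact_mask[(start + 1L):(start + n)]))
    stop("segment overlaps artifact-marked samples")
  structure(list(recording = rec, start = start, n = n),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s: samples [%d, %d) (%.2f s @ %g Hz)\n",
              x$recording$participant_id, x$start, x$start + x$n,
              x$n / x$recording$fs, x$recording$fs))
  invisible(x)
}

#' Amplitude matrix of a segment
#' @param seg An `eeg_segment`.
#' @return Numeric matrix, `seg$n` samples by channels, in microvolts.
#' @export
segment_data <- function(seg) {
  seg$recording$data[(seg$start + 1L):(seg$start + seg$n), , drop = FALSE]
}

#' Longest artifact-free run of a recording
#'
#' Finds the maximal window of consecutive clean samples in the recording's
#' artifact mask (a missing mask counts as all-clean). Ties are broken in
#' favour of the earliest start.
#'
#' @param rec An [eeg_recording].
#' @return An [segment] covering the longest clean run.
#' @export
longest_clean_run <- function(rec) {
  mask <- rec$artifact_mask
  if (!any(mask)) stop("recording has no clean samples")
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths            # 0-based
  clean <- which(r$values)
  best <- clean[which.max(r$lengths[clean])]  # which.max takes the first max
  segment(rec, starts[best], r$lengths[best])
}

#' Trim segments to the cohort-wide common length
#'
#' Cuts every segment to the minimum length over the input list, keeping each
#' segment's first samples, so that all participants contribute windows of
#' identical duration. Idempotent.
#'
#' @param segments Nonempty list of [segment] objects.
#' @return List of segments, all with the same (minimum) length.
#' @export
trim_to_common_length <- function(segments) {
  if (!length(segments)) stop("empty segment list")
  n_min <- min(vapply(segments, function(s) s$n, 0L))
  lapply(segments, function(s) segment(s$recording, s$start, n_min))
}

#' Apply the recording-chain filters
#'
#' Zero-phase Butterworth filtering replicating a typical EEG acquisition
#' chain: 0.53 Hz high-pass, 50 Hz low-pass and a 45–55 Hz band-stop notch.
#' Each channel is mean-removed, reflect-padded by 2 s against edge
#' transients, filtered forward-backward through the three stages, and
#' trimmed back, so signal length is preserved. The low-pass stage uses a
#' steeper (8th-order) roll-off so mains-range components just above the
#' pass-band (e.g. 60 Hz) are attenuated below 5% RMS.
#'
#' @param rec An [eeg_recording]; its sampling rate must exceed 110 Hz so the
#'   55 Hz stop-band edge lies below Nyquist.
#' @param band Pass-band edges in Hz.
#' @param notch Stop-band edges in Hz.
#' @param order Butterworth order of the high-pass and notch stages; the
#'   low-pass stage uses `2 * order`.
#' @return A filtered copy of the recording.
#' @export
apply_recording_filters <- function(rec, band = c(0.53, 50),
                                    notch = c(45, 55), order = 4L) {
  nyq <- rec$fs / 2
  if (max(band, notch) >= nyq)
    stop("sampling rate ", rec$fs, " Hz too low for filter edges up to ",
         max(band, notch), " Hz")
  hp <- signal::butter(order, band[1] / nyq, type = "high")
  lp <- signal::butter(2L * order, band[2] / nyq, type = "low")
  bs <- signal::butter(order, notch / nyq, type = "stop")
  pad <- min(nrow(rec$data) - 1L, round(2 * rec$fs))
  out <- rec
  for (ch in seq_len(ncol(rec$data))) {
    y <- rec$data[, ch] - mean(rec$data[, ch])
    for (flt in list(hp, lp, bs)) y <- filtfilt_padded(flt, y, pad)
    out$data[, ch] <- y
  }
  out
}

# forward-backward filtering with reflective edge padding
filtfilt_padded <- function(flt, x, pad) {
  n <- length(x)
  if (pad < 1L) return(signal::filtfilt(flt, x))
  xp <- c(2 * x[1L] - rev(x[2L:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  signal::filtfilt(flt, xp)[(pad + 1L):(pad + n)]
}
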