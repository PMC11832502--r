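#' The 19 channels of the international 10/20 montage
#'
#' Standard labels of the 19-electrode 10/20 scalp montage, in the
#' conventional anterior-to-posterior order.
#'
#' @format Character vector of length 19.
#' @export
montage_1020 <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz",
                  "C3", "C4", "Cz", "T3", "T4", "T5", "T6",
                  "P3", "P4", "Pz", "O1", "O2")

#' Construct a multichannel EEG recording
#'
#' An `eeg_recording` holds a samples-by-channels amplitude matrix in
#' microvolts, the sampling rate, unique channel labels, an optional
#' per-sample artifact mask (`TRUE` = clean), and participant metadata.
#'
#' @param data Numeric matrix, samples in rows, channels in columns.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channels Character vector of unique channel labels, one per column.
#' @param participant_id Participant identifier string.
#' @param group Group label, one of `"TD"`, `"ASD"`, or `NA`.
#' @param artifact_mask Optional logical vector, one element per sample;
#'   `TRUE` marks a clean sample. Defaults to all-clean.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = colnames(data),
                          participant_id = "unknown", group = NA_character_,
                          artifact_mask = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channels))
    channels <- paste0("ch", seq_len(ncol(data)))
  channels <- as.character(channels)
  if (length(channels) != ncol(data))
    stop("number of channel labels must match number of data columns")
  if (anyDuplicated(tolower(channels)))
    stop("channel labels must be unique")
  if (!is.na(group) && !group %in% c("TD", "ASD"))
    stop("`group` must be \"TD\", \"ASD\" or NA")
  if (is.null(artifact_mask)) {
    artifact_mask <- rep(TRUE, nrow(data))
  } else {
    artifact_mask <- as.logical(artifact_mask)
    if (length(artifact_mask) != nrow(data))
      stop("`artifact_mask` must have one element per sample")
  }
  colnames(data) <- channels
  structure(
    list(participant_id = as.character(participant_id),
         group = group, fs = fs, channels = channels,
         data = data, artifact_mask = artifact_mask),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s%s: %d channels x %d samples @ %g Hz (%.1f s), %d%% clean\n",
              x$participant_id,
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              length(x$channels), nrow(x$data), x$fs, nrow(x$data) / x$fs,
              round(100 * mean(x$artifact_mask))))
  invisible(x)
}

#' Number of samples per channel
#' @param rec An `eeg_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Check a recording against the 19-channel 10/20 montage
#'
#' Compares the recording's channel labels (case-insensitively) with the 19
#' labels of the 10/20 montage and reports discrepancies rather than raising.
#'
#' @param rec An `eeg_recording`.
#' @param montage Reference labels; defaults to [montage_1020].
#' @return Character vector of messages, `"missing: <label>"` for reference
#'   labels absent from the recording and `"extra: <label>"` for recording
#'   labels outside the montage (a duplicated montage label is reported as
#'   extra). Empty when the montage is matched exactly.
#' @export
validate_montage <- function(rec, montage = montage_1020) {
  have <- tolower(rec$channels)
  want <- tolower(montage)
  missing <- montage[!(want %in% have)]
  # beyond the first occurrence, repeats count as extra
  first <- !duplicated(have)
  extra <- rec$channels[!(have %in% want) | !first]
  out <- c(if (length(missing)) paste0("missing: ", missing),
           if (length(extra)) paste0("extra: ", extra))
  if (is.null(out)) character(0) else out
}
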