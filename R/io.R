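#' Read an EEG recording from disk
#'
#' Supports two on-disk formats: EDF (European Data Format, continuous
#' 16-bit records) and a plain delimited-text dialect with two header lines
#' (`fs=<Hz>` and a comma-separated list of channel labels) followed by one
#' comma-separated row of amplitudes per sample.
#'
#' @param path Path to the file.
#' @param format `"edf"`, `"text"`, or `"auto"` (by file extension:
#'   `.edf` is EDF, anything else text).
#' @param participant_id Optional participant id; for EDF the patient header
#'   field is used when not given, for text the file stem.
#' @param group Optional group label (`"TD"`/`"ASD"`).
#' @return An [eeg_recording] with amplitudes in microvolts and channel
#'   order as stored in the file.
#' @export
read_recording <- function(path, format = c("auto", "edf", "text"),
                           participant_id = NULL, group = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: no such file: ", path)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "edf") "edf" else "text"
  switch(format,
         edf = read_edf(path, participant_id = participant_id, group = group),
         text = read_recording_text(path, participant_id = participant_id,
                                    group = group))
}

#' Write an EEG recording to disk
#'
#' @param rec An [eeg_recording].
#' @param path Destination path.
#' @param format `"edf"`, `"text"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @seealso [read_recording] for the formats.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "text")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "edf") "edf" else "text"
  switch(format,
         edf = write_edf(rec, path),
         text = write_recording_text(rec, path))
  invisible(path)
}

read_recording_text <- function(path, participant_id = NULL,
                                group = NA_character_) {
  head2 <- readLines(path, n = 2L)
  if (length(head2) < 2L || !grepl("^fs=", head2[1L]))
    stop("format error: delimited text must start with an 'fs=<Hz>' header line")
  fs <- suppressWarnings(as.numeric(sub("^fs=", "", head2[1L])))
  if (!is.finite(fs) || fs <= 0)
    stop("format error: invalid sampling rate in header: ", head2[1L])
  channels <- trimws(strsplit(head2[2L], ",", fixed = TRUE)[[1L]])
  if (anyDuplicated(tolower(channels)))
    stop("format error: duplicate channel label in header")
  dat <- utils::read.csv(path, header = FALSE, skip = 2L,
                         colClasses = "numeric")
  if (ncol(dat) != length(channels))
    stop("format error: ", ncol(dat), " data columns for ",
         length(channels), " channel labels")
  if (is.null(participant_id))
    participant_id <- tools::file_path_sans_ext(basename(path))
  eeg_recording(as.matrix(dat), fs = fs, channels = channels,
                participant_id = participant_id, group = group)
}

write_recording_text <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("fs=%.10g", rec$fs),
               paste(rec$channels, collapse = ",")), con)
  utils::write.table(rec$data, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
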