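#' Estimator parameter set
#'
#' Bundles every tunable estimator parameter with its standard default:
#' permutation entropy `D = 3`, `tau = 1`; sample entropy `m = 2`,
#' `r = 0.2 * SD`; Rényi order `alpha = 2`; Tsallis index `q = 1.5`;
#' Higuchi `k_max = 10`; a 100-bin amplitude histogram; spectral entropy and
#' band analysis over 0.5–20 Hz; Welch PSD with 2 s Hann windows at 50%
#' overlap.
#'
#' @param D,tau Permutation-entropy embedding dimension and delay.
#' @param m,r_fraction Sample-entropy template length and tolerance as a
#'   fraction of the per-channel segment SD.
#' @param alpha Rényi entropy order.
#' @param q Tsallis entropic index.
#' @param k_max Higuchi interval-size bound.
#' @param n_bins Amplitude-histogram bin count for Tsallis entropy.
#' @param se_band Spectral-entropy frequency range in Hz.
#' @param bands Band definitions for relative power and brain rate.
#' @param psd_window_sec,psd_overlap Welch PSD window and overlap.
#' @return Named list of parameters.
#' @export
feature_params <- function(D = 3L, tau = 1L, m = 2L, r_fraction = 0.2,
                           alpha = 2, q = 1.5, k_max = 10L, n_bins = 100L,
                           se_band = c(0.5, 20), bands = eeg_bands(),
                           psd_window_sec = 2, psd_overlap = 0.5) {
  list(D = D, tau = tau, m = m, r_fraction = r_fraction, alpha = alpha,
       q = q, k_max = k_max, n_bins = n_bins, se_band = se_band,
       bands = bands, psd_window_sec = psd_window_sec,
       psd_overlap = psd_overlap)
}

#' Names of the per-channel features
#' @return Character vector with the eight compared features plus the
#'   normalized LZ76 variant.
#' @export
feature_names <- function() {
  c("brain_rate", "spectral_entropy", "permutation_entropy", "sample_entropy",
    "renyi_entropy", "tsallis_entropy", "higuchi_fd", "lzc", "lzc_normalized")
}

channel_features <- function(x, fs, params) {
  ps <- compute_psd(x, fs, params$psd_window_sec, params$psd_overlap)
  bp <- relative_band_power(ps, params$bands)
  c(brain_rate = brain_rate(bp, params$bands),
    spectral_entropy = spectral_entropy(ps, params$se_band[1], params$se_band[2]),
    permutation_entropy = permutation_entropy(x, params$D, params$tau),
    sample_entropy = sample_entropy(x, params$m, r_fraction = params$r_fraction),
    renyi_entropy = renyi_entropy(estimate_density(x), params$alpha),
    tsallis_entropy = tsallis_entropy(amplitude_histogram(x, params$n_bins),
                                      params$q),
    higuchi_fd = higuchi_fd(x, params$k_max),
    lzc = lz76_complexity(binarize_mean(x)),
    lzc_normalized = lzc_normalized(binarize_mean(x)))
}

#' Extract all per-channel features from a segment
#'
#' Computes, for each channel of the segment, brain rate, spectral entropy,
#' permutation entropy, sample entropy, Rényi entropy, Tsallis entropy,
#' Higuchi fractal dimension and Lempel–Ziv complexity (raw word count plus
#' its length-normalized variant). Deterministic given the segment.
#'
#' @param seg An `eeg_segment` (see [segment], [longest_clean_run]).
#' @param params Estimator parameters, see [feature_params].
#' @return Data frame with one row per channel: `participant_id`, `group`,
#'   `channel`, then one column per feature.
#' @export
extract_all_features <- function(seg, params = feature_params()) {
  dat <- segment_data(seg)
  rec <- seg$recording
  rows <- lapply(seq_len(ncol(dat)), function(ch) {
    vals <- tryCatch(channel_features(dat[, ch], rec$fs, params),
                     error = function(e) {
                       stop("feature extraction failed for participant ",
                            rec$participant_id, ", channel ",
                            rec$channels[ch], ": ", conditionMessage(e),
                            call. = FALSE)
                     })
    cbind(data.frame(participant_id = rec$participant_id,
                     group = rec$group, channel = rec$channels[ch],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  do.call(rbind, rows)
}

#' Cohort feature table
#'
#' Runs segment selection (longest clean run per recording, trimmed to the
#' cohort-wide common length) and feature extraction for every recording,
#' returning the stacked participants-by-channels feature table.
#'
#' @param recordings List of [eeg_recording] objects with group labels set.
#' @param params Estimator parameters, see [feature_params].
#' @param filter Apply the acquisition-chain filters
#'   ([apply_recording_filters]) before segmenting (default `FALSE`).
#' @return Data frame with `length(recordings) * n_channels` rows, columns
#'   `participant_id`, `group`, `channel` and the features of
#'   [feature_names].
#' @export
cohort_features <- function(recordings, params = feature_params(),
                            filter = FALSE) {
  if (!length(recordings)) stop("empty cohort")
  if (filter) recordings <- lapply(recordings, apply_recording_filters)
  segs <- lapply(recordings, longest_clean_run)
  segs <- trim_to_common_length(segs)
  do.call(rbind, lapply(segs, extract_all_features, params = params))
}
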