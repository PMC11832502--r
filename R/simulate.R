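# Deterministic per-participant / per-channel substreams: one global seed is
# hashed arithmetically so cohorts are reproducible and order-independent.
substream_seed <- function(seed, participant, channel = 0L) {
  ((as.numeric(seed) %% 65536) * 30011 + participant * 7919 +
     channel * 104729) %% 2147483647
}

#' Group-level generator parameters
#'
#' @param beta Spectral exponent of the 1/f^beta background.
#' @param alpha_gain RMS of the 10–11 Hz alpha component as a multiple of the
#'   background SD.
#' @param amplitude_scale Overall SD multiplier on the channel signal.
#' @param spike_rate_hz Rate of quasi-periodic spike transients (per second).
#' @param spike_amplitude Spike amplitude as a multiple of the background SD.
#' @return Named list of group parameters.
#' @export
group_params <- function(beta = 1.0, alpha_gain = 3.0, amplitude_scale = 1.0,
                         spike_rate_hz = 0, spike_amplitude = 0) {
  list(beta = beta, alpha_gain = alpha_gain,
       amplitude_scale = amplitude_scale, spike_rate_hz = spike_rate_hz,
       spike_amplitude = spike_amplitude)
}

#' Synthetic cohort configuration
#'
#' Defines a two-group resting-state cohort emulating the study conditions:
#' 39 typically developing (TD) and 49 autism-group (ASD) participants, 19
#' channels of the 10/20 montage at 250 Hz, 43 s of clean signal each. The
#' TD group carries a strong 10–11 Hz alpha component over a flatter (beta =
#' 1) background; the ASD group has a steeper low-frequency-dominated
#' spectrum (beta = 1.6), little alpha, larger amplitude variance and
#' quasi-periodic spike-like transients.
#'
#' @param n_td,n_asd Group sizes.
#' @param n_channels Number of channels (19-label montage by default).
#' @param fs Sampling rate in Hz.
#' @param duration_s Clean-signal duration per participant in seconds.
#' @param seed Global integer seed; drives every substream.
#' @param td,asd Per-group parameters, see [group_params].
#' @param base_amplitude_uv Baseline channel SD in microvolts.
#' @param participant_jitter Relative spread of per-participant variation of
#'   gains and scales (uniform, +/- this fraction).
#' @param channel_jitter Relative spread of per-channel alpha-gain variation.
#' @return Named list (class `cohort_config`).
#' @export
cohort_config <- function(n_td = 39L, n_asd = 49L, n_channels = 19L,
                          fs = 250, duration_s = 43, seed = 0L,
                          td = group_params(beta = 1.0, alpha_gain = 3.0,
                                            amplitude_scale = 1.0,
                                            spike_rate_hz = 0,
                                            spike_amplitude = 0),
                          asd = group_params(beta = 1.6, alpha_gain = 0.3,
                                             amplitude_scale = 1.8,
                                             spike_rate_hz = 2,
                                             spike_amplitude = 4),
                          base_amplitude_uv = 20,
                          participant_jitter = 0.15,
                          channel_jitter = 0.10) {
  stopifnot(n_td > 0L, n_asd > 0L, n_channels > 0L, fs > 0, duration_s > 0)
  structure(list(n_td = n_td, n_asd = n_asd, n_channels = n_channels,
                 fs = fs, duration_s = duration_s, seed = seed,
                 td = td, asd = asd, base_amplitude_uv = base_amplitude_uv,
                 participant_jitter = participant_jitter,
                 channel_jitter = channel_jitter),
            class = "cohort_config")
}

#' Generate broadband EEG-like background noise
#'
#' Gaussian noise spectrally shaped to a power-law PSD proportional to
#' `1/f^beta` inside 0.5–50 Hz; outside that range the shaping gain plateaus
#' (the frequency is clamped to the band), so `beta = 0` reduces to white
#' noise. DC is removed and the output is standardized to zero mean and unit
#' SD.
#'
#' @param n Number of samples (>= 2).
#' @param fs Sampling rate in Hz.
#' @param beta Spectral exponent (>= 0).
#' @param f_band Frequency band over which the power law holds.
#' @return Numeric series of length `n`, mean 0, SD 1.
#' @export
generate_background <- function(n, fs, beta, f_band = c(0.5, 50)) {
  if (n < 2L) stop("need n >= 2")
  if (beta < 0) stop("need beta >= 0")
  z <- stats::rnorm(n)
  if (beta == 0) return((z - mean(z)) / stats::sd(z))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  fc <- pmin(pmax(f, f_band[1]), f_band[2])  # clamp outside the band
  gain <- fc^(-beta / 2)
  gain[1L] <- 0                              # remove DC
  x <- Re(stats::fft(stats::fft(z) * gain, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Superimpose a narrowband alpha oscillation
#'
#' Adds a 10–11 Hz rhythm built as a sinusoidal carrier under slow random
#' amplitude and phase modulation (two independent spline-interpolated
#' Gaussian quadrature envelopes of bandwidth `bw`), i.e. narrowband noise.
#' The `burst` exponent sharpens the waxing-and-waning of the envelope:
#' `burst = 1` gives a Rayleigh envelope, larger values give spindle-like
#' bursts separated by near-silent stretches, as resting alpha shows. The
#' component is scaled so its RMS equals `gain` times the SD of the input
#' series.
#'
#' @param x Background series.
#' @param fs Sampling rate in Hz.
#' @param gain RMS of the component relative to the input SD (0 leaves `x`
#'   untouched).
#' @param f0 Center frequency in Hz (default 10.5, the 10–11 Hz alpha peak).
#' @param bw Modulation bandwidth in Hz.
#' @param burst Envelope burstiness exponent (>= 1).
#' @return Series with the alpha component added.
#' @export
add_alpha_component <- function(x, fs, gain, f0 = 10.5, bw = 1, burst = 2) {
  if (gain < 0) stop("need gain >= 0")
  if (gain == 0) return(x)
  n <- length(x)
  t <- (seq_len(n) - 1L) / fs
  knots <- max(8L, ceiling(n / fs * bw) + 1L)
  kx <- seq(0, n - 1L, length.out = knots)
  re <- stats::spline(kx, stats::rnorm(knots), xout = seq_len(n) - 1L)$y
  im <- stats::spline(kx, stats::rnorm(knots), xout = seq_len(n) - 1L)$y
  osc <- re * sin(2 * pi * f0 * t) + im * cos(2 * pi * f0 * t)
  if (burst != 1) osc <- osc * (re^2 + im^2)^((burst - 1) / 2)
  osc <- osc / sqrt(mean(osc^2)) * gain * stats::sd(x)
  x + osc
}

spike_wave_kernel <- function(fs, spike_s = 0.07, wave_s = 0.40,
                              spike_rel = 0.9) {
  n1 <- max(4L, round(spike_s * fs))
  n2 <- max(4L, round(wave_s * fs))
  t1 <- seq_len(n1) / n1
  t2 <- seq_len(n2) / n2
  spike <- sin(2 * pi * t1) * (0.5 - 0.5 * cos(2 * pi * t1))  # sharp biphasic
  spike <- spike / max(abs(spike)) * spike_rel
  wave <- -sin(pi * t2)^2                                     # rounded after-wave
  k <- c(spike, wave)
  k / max(abs(k))
}

#' Superimpose a quasi-periodic spike-wave train
#'
#' Adds epileptiform spike–slow-wave complexes — a sharp biphasic spike
#' (~70 ms) followed by a rounded slow wave of opposite polarity — at
#' quasi-periodic times: inter-complex intervals are the nominal period
#' `1/rate_hz` jittered uniformly by +/-10%, and each complex's amplitude is
#' jittered by +/-15% around `amp` times the SD of the input series. The
#' regular large-amplitude alternation this produces dominates the signal's
#' mean-threshold crossings, which is what makes the binarized sequence
#' repetitive.
#'
#' @param x Background series.
#' @param fs Sampling rate in Hz.
#' @param rate_hz Complex rate per second (0 leaves `x` untouched).
#' @param amp Peak amplitude relative to the input SD.
#' @param width_s Sharp-spike width in seconds.
#' @param wave_s Slow-wave width in seconds.
#' @return Series with the spike train added; the complex count is attached
#'   as attribute `n_spikes`.
#' @export
add_spike_train <- function(x, fs, rate_hz, amp, width_s = 0.07,
                            wave_s = 0.40) {
  if (rate_hz < 0) stop("need rate_hz >= 0")
  if (rate_hz == 0) return(x)
  n <- length(x)
  period <- fs / rate_hz
  kernel <- spike_wave_kernel(fs, width_s, wave_s) * amp * stats::sd(x)
  klen <- length(kernel)
  pos <- stats::runif(1, 0, period)
  count <- 0L
  while (pos + klen <= n) {
    i0 <- floor(pos)
    x[(i0 + 1L):(i0 + klen)] <- x[(i0 + 1L):(i0 + klen)] +
      kernel * stats::runif(1, 0.85, 1.15)
    count <- count + 1L
    pos <- pos + period * stats::runif(1, 0.9, 1.1)
  }
  attr(x, "n_spikes") <- count
  x
}

synthesize_channel <- function(n, fs, p, alpha_gain_ch, base_uv) {
  x <- generate_background(n, fs, p$beta)
  x <- add_alpha_component(x, fs, alpha_gain_ch)
  x <- add_spike_train(x, fs, p$spike_rate_hz, p$spike_amplitude)
  # amplitude_scale fixes the channel SD in microvolts
  as.numeric((x - mean(x)) / stats::sd(x)) * p$amplitude_scale * base_uv
}

#' Generate a synthetic two-group cohort
#'
#' Builds `n_td + n_asd` recordings from a [cohort_config]: every channel is
#' a 1/f^beta background plus an amplitude-modulated alpha component and
#' (for the ASD parameterization) a quasi-periodic spike train, scaled to
#' microvolts. Per-participant gains and scales vary uniformly by
#' `participant_jitter` and per-channel alpha gain by `channel_jitter`, so
#' groups have within-group and across-channel variance. Fully reproducible
#' and order-independent given `cfg$seed`.
#'
#' @param cfg A [cohort_config].
#' @return List of [eeg_recording] objects with group labels set (TD
#'   participants first).
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) stop("`cfg` must be a cohort_config")
  n <- round(cfg$fs * cfg$duration_s)
  channels <- if (cfg$n_channels == length(montage_1020)) montage_1020
              else paste0("ch", seq_len(cfg$n_channels))
  groups <- c(rep("TD", cfg$n_td), rep("ASD", cfg$n_asd))
  lapply(seq_along(groups), function(p_idx) {
    grp <- groups[p_idx]
    base <- if (grp == "TD") cfg$td else cfg$asd
    pj <- cfg$participant_jitter
    set.seed(substream_seed(cfg$seed, p_idx))
    p <- base
    p$alpha_gain <- base$alpha_gain * stats::runif(1, 1 - pj, 1 + pj)
    p$amplitude_scale <- base$amplitude_scale * stats::runif(1, 1 - pj, 1 + pj)
    dat <- matrix(0, nrow = n, ncol = cfg$n_channels)
    for (ch in seq_len(cfg$n_channels)) {
      set.seed(substream_seed(cfg$seed, p_idx, ch))
      gch <- p$alpha_gain *
        stats::runif(1, 1 - cfg$channel_jitter, 1 + cfg$channel_jitter)
      dat[, ch] <- synthesize_channel(n, cfg$fs, p, gch,
                                      cfg$base_amplitude_uv)
    }
    eeg_recording(dat, fs = cfg$fs, channels = channels,
                  participant_id = sprintf("%s%03d", tolower(grp), p_idx),
                  group = grp)
  })
}

#' Write a cohort to disk with a manifest
#'
#' @param recordings List of recordings (see [generate_cohort]).
#' @param dir Output directory (created if needed).
#' @param format `"text"` or `"edf"`.
#' @return Path of the manifest CSV (columns `participant_id`, `group`,
#'   `file`), invisibly.
#' @export
write_cohort <- function(recordings, dir, format = c("text", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "edf") "edf" else "csv"
  files <- vapply(recordings, function(rec) {
    f <- file.path(dir, paste0(rec$participant_id, ".", ext))
    write_recording(rec, f, format)
    f
  }, "")
  manifest <- data.frame(
    participant_id = vapply(recordings, `[[`, "", "participant_id"),
    group = vapply(recordings, `[[`, "", "group"),
    file = basename(files), stringsAsFactors = FALSE)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}
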