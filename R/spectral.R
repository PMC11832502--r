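#' The five classical EEG frequency bands
#'
#' Delta, theta, alpha, SMR (sensorimotor rhythm) and beta bands used for
#' relative power and the brain-rate weighting. Intervals are half-open
#' `[f_lo, f_hi)` so shared edges are unambiguous; `f_center` is the band
#' midpoint used as the representative frequency in the brain-rate formula.
#'
#' @param names,f_lo,f_hi,f_center Vectors defining the bands; the defaults
#'   are delta 0.5–4, theta 4–8, alpha 8–12, SMR 12–15 and beta 15–20 Hz with
#'   midpoint centers 2.25, 6, 10, 13.5 and 17.5 Hz.
#' @return Data frame with columns `name`, `f_lo`, `f_hi`, `f_center`.
#' @export
eeg_bands <- function(names = c("delta", "theta", "alpha", "smr", "beta"),
                      f_lo = c(0.5, 4, 8, 12, 15),
                      f_hi = c(4, 8, 12, 15, 20),
                      f_center = (f_lo + f_hi) / 2) {
  stopifnot(length(names) == length(f_lo), length(f_lo) == length(f_hi),
            all(f_lo > 0), all(f_hi > f_lo),
            all(f_center >= f_lo), all(f_center < f_hi))
  data.frame(name = names, f_lo = f_lo, f_hi = f_hi, f_center = f_center,
             stringsAsFactors = FALSE)
}

#' Welch power spectral density
#'
#' Welch-averaged one-sided periodogram: the signal is cut into Hann-tapered
#' windows (2 s by default) with 50% overlap, each window is mean-detrended,
#' and squared FFT magnitudes are averaged and density-scaled.
#'
#' @param x Numeric amplitude series (one channel) or an `eeg_segment`, in
#'   which case a list with one `power_spectrum` per channel is returned.
#' @param fs Sampling rate in Hz (ignored when `x` is a segment).
#' @param window_sec Window length in seconds; must give at least one full
#'   window, so the input must span at least `window_sec` (2 s default).
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @return A `power_spectrum`: list with `freqs` (Hz, 0 to Nyquist) and
#'   `psd` (power density, nonnegative).
#' @export
compute_psd <- function(x, fs = NULL, window_sec = 2, overlap = 0.5) {
  if (inherits(x, "eeg_segment")) {
    dat <- segment_data(x)
    fs <- x$recording$fs
    out <- lapply(seq_len(ncol(dat)),
                  function(ch) compute_psd(dat[, ch], fs, window_sec, overlap))
    names(out) <- x$recording$channels
    return(out)
  }
  if (is.null(fs)) stop("`fs` is required for a bare numeric series")
  nper <- round(window_sec * fs)
  if (length(x) < nper)
    stop("series too short for a ", window_sec, " s analysis window")
  hop <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))  # Hann
  segs <- vapply(starts, function(s) x[s:(s + nper - 1L)], numeric(nper))
  segs <- sweep(segs, 2L, colMeans(segs))
  segs <- segs * w
  ft <- stats::mvfft(segs)
  nf <- nper %/% 2L + 1L
  pw <- rowMeans(abs(ft[seq_len(nf), , drop = FALSE])^2) / (fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- seq(2L, if (nper %% 2L == 0L) nf - 1L else nf)
  pw[dbl] <- 2 * pw[dbl]
  structure(list(freqs = (seq_len(nf) - 1L) * fs / nper, psd = pw),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, 0-%g Hz (df = %g Hz)\n",
              length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1]))
  invisible(x)
}

band_bins <- function(ps, f_lo, f_hi) which(ps$freqs >= f_lo & ps$freqs < f_hi)

#' Relative power per frequency band
#'
#' Fraction of spectral power falling in each band, normalized by the total
#' power over all supplied (non-overlapping) bands, so fractions sum to 1.
#'
#' @param ps A `power_spectrum` from [compute_psd].
#' @param bands Band definitions, see [eeg_bands].
#' @return Named numeric vector of fractions, one per band.
#' @export
relative_band_power <- function(ps, bands = eeg_bands()) {
  o <- order(bands$f_lo)
  if (any(bands$f_hi[o][-nrow(bands)] > bands$f_lo[o][-1L]))
    stop("bands must not overlap")
  p <- vapply(seq_len(nrow(bands)),
              function(b) sum(ps$psd[band_bins(ps, bands$f_lo[b], bands$f_hi[b])]),
              0)
  tot <- sum(p)
  if (tot <= 0) stop("no spectral power inside the analysis bands")
  stats::setNames(p / tot, bands$name)
}

#' Hz-by-hz relative power spectrum
#'
#' Spectral power aggregated into 1-Hz bins `[k, k+1)` from 0 Hz up to
#' `f_max`, normalized to sum to 1. Used to depict the spectrum hertz by
#' hertz without averaging over whole bands.
#'
#' @param ps A `power_spectrum`.
#' @param f_max Upper edge in Hz (at most the Nyquist frequency).
#' @return Numeric vector of fractions named by bin lower edge.
#' @export
relative_power_per_hz <- function(ps, f_max = 20) {
  if (f_max > max(ps$freqs) + 1e-9) stop("`f_max` exceeds the spectral range")
  lo <- 0:(ceiling(f_max) - 1L)
  p <- vapply(lo, function(k) sum(ps$psd[band_bins(ps, k, k + 1)]), 0)
  tot <- sum(p)
  if (tot <= 0) stop("no spectral power below f_max")
  stats::setNames(p / tot, lo)
}

#' Brain rate: power-weighted mean EEG frequency
#'
#' The arousal index defined as the weighted mean of the band representative
#' frequencies, `BR = sum(f_i P_i) / sum(P_i)`, with `P_i` the power in band
#' i and `f_i` its center frequency. Invariant to uniform power scaling and
#' bounded by the smallest and largest band center.
#'
#' @param band_powers Nonnegative powers (or power fractions), one per band.
#' @param bands Band definitions supplying `f_center`.
#' @return Brain rate in Hz.
#' @export
brain_rate <- function(band_powers, bands = eeg_bands()) {
  if (length(band_powers) != nrow(bands))
    stop("need one power per band")
  if (any(band_powers < 0) || all(band_powers == 0))
    stop("band powers must be nonnegative and not all zero")
  sum(bands$f_center * band_powers) / sum(band_powers)
}

#' Spectral entropy of a power spectrum
#'
#' Shannon entropy (natural log) of the power spectral density normalized to
#' a probability distribution over the frequency bins in `[f_lo, f_hi)`.
#' Ranges from 0 (all power in one bin) to `log(n)` for a flat spectrum over
#' n bins; reported un-normalized, in nats.
#'
#' @param ps A `power_spectrum`.
#' @param f_lo,f_hi Frequency range in Hz; defaults to the analyzed 0.5–20 Hz
#'   band range.
#' @return Spectral entropy in nats.
#' @export
spectral_entropy <- function(ps, f_lo = 0.5, f_hi = 20) {
  bins <- band_bins(ps, f_lo, f_hi)
  if (!length(bins)) stop("no frequency bins in [", f_lo, ", ", f_hi, ")")
  p <- ps$psd[bins]
  tot <- sum(p)
  if (tot <= 0) stop("no spectral power in [", f_lo, ", ", f_hi, ")")
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p))
}
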