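#' Higuchi fractal dimension
#'
#' Canonical Higuchi curve-length estimator: for every interval size
#' `k = 1..k_max` and offset `m = 1..k`, the normalized length of the
#' decimated sub-series is
#' `L_m(k) = sum |x(m + i k) - x(m + (i-1) k)| * (N - 1) / (floor((N - m)/k) k) / k`,
#' lengths are averaged over offsets, and the dimension is the least-squares
#' slope of `log L(k)` against `log(1/k)`. Values range from 1 (smooth
#' curves) to 2 (noise-like series).
#'
#' @param x Numeric series of length at least `10 * k_max`.
#' @param k_max Largest interval size (default 10).
#' @return Estimated fractal dimension.
#' @export
higuchi_fd <- function(x, k_max = 10L) {
  k_max <- as.integer(k_max)
  n <- length(x)
  if (n < 10L * k_max)
    stop("series too short: need at least 10 * k_max = ", 10L * k_max,
         " samples")
  Lk <- vapply(seq_len(k_max), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      sub <- x[seq.int(m, n, by = k)]
      nk <- length(sub) - 1L
      sum(abs(diff(sub))) * (n - 1) / (nk * k) / k
    }, 0)
    mean(Lm)
  }, 0)
  lx <- log(1 / seq_len(k_max))
  ly <- log(Lk)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Binarize a signal at its mean amplitude
#'
#' Maps each sample to 1 when strictly above the signal mean and 0 otherwise
#' (samples exactly at the mean map to 0). This is the symbolization step
#' ahead of Lempel–Ziv complexity.
#'
#' @param x Numeric amplitude series.
#' @return A `binary_sequence`: list with integer `bits` (0/1) and the
#'   `threshold` used.
#' @export
binarize_mean <- function(x) {
  if (!length(x)) stop("empty series")
  thr <- mean(x)
  structure(list(bits = as.integer(x > thr), threshold = thr),
            class = "binary_sequence")
}

#' Lempel–Ziv 1976 complexity of a binary sequence
#'
#' Number of distinct words in the exhaustive-history parse: scanning left to
#' right, the current candidate word closes as soon as it is no longer a
#' substring of everything seen before it (the parsed prefix plus the
#' candidate minus its last symbol); a trailing incomplete word counts as one
#' word. Low counts indicate repetitive, predictable sequences.
#'
#' @param b A `binary_sequence` from [binarize_mean], or a vector of 0/1
#'   integers, or a character string like `"0110"`.
#' @return Positive integer word count.
#' @export
lz76_complexity <- function(b) {
  bits <- as_bits(b)
  if (!length(bits)) stop("empty sequence")
  .lz76_count(bits)
}

as_bits <- function(b) {
  if (inherits(b, "binary_sequence")) return(b$bits)
  if (is.character(b) && length(b) == 1L)
    return(as.integer(strsplit(b, "", fixed = TRUE)[[1L]]))
  bits <- as.integer(b)
  if (any(is.na(bits)) || any(!bits %in% c(0L, 1L)))
    stop("sequence must be binary (0/1)")
  bits
}

#' Length-normalized Lempel–Ziv complexity
#'
#' `c(n) log2(n) / n`, where `c(n)` is the LZ76 word count: divides out the
#' `n / log2(n)` growth of the count for random sequences so values are
#' comparable across sequence lengths.
#'
#' @inheritParams lz76_complexity
#' @return Positive scalar.
#' @export
lzc_normalized <- function(b) {
  bits <- as_bits(b)
  n <- length(bits)
  if (n < 2L) stop("need at least 2 symbols")
  .lz76_count(bits) * log2(n) / n
}
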