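#' Permutation entropy of a time series
#'
#' Shannon entropy (natural log) of the distribution of ordinal patterns:
#' each window of `D` samples at delay `tau` is reduced to the permutation
#' that sorts it, ties broken by order of appearance (stable sort), and the
#' entropy of the pattern frequencies is returned. Lies in `[0, log(D!)]` and
#' is invariant to monotone amplitude transformations.
#'
#' @param x Numeric amplitude series of length at least `D * tau + 1`.
#' @param D Embedding dimension (default 3).
#' @param tau Embedding delay in samples (default 1).
#' @return Permutation entropy in nats.
#' @export
permutation_entropy <- function(x, D = 3L, tau = 1L) {
  D <- as.integer(D); tau <- as.integer(tau)
  if (D < 2L || tau < 1L) stop("need D >= 2 and tau >= 1")
  n_win <- length(x) - (D - 1L) * tau
  if (length(x) < D * tau + 1L)
    stop("series too short: need at least D*tau + 1 = ", D * tau + 1L,
         " samples")
  cols <- lapply(0:(D - 1L),
                 function(j) x[seq.int(1L + j * tau, length.out = n_win)])
  # stable rank of each window element: earlier positions win ties
  ranks <- matrix(0, n_win, D)
  for (j in seq_len(D)) for (k in seq_len(D)) {
    if (k < j) ranks[, j] <- ranks[, j] + (cols[[k]] <= cols[[j]])
    else if (k > j) ranks[, j] <- ranks[, j] + (cols[[k]] < cols[[j]])
  }
  code <- as.vector(ranks %*% D^(seq_len(D) - 1L))
  p <- tabulate(match(code, unique(code))) / n_win
  -sum(p * log(p))
}

#' Sample entropy of a time series
#'
#' `SampEn(m, r) = -log(A / B)` where `B` counts pairs of length-`m`
#' templates and `A` pairs of length-`m+1` templates lying within Chebyshev
#' distance `r` (strict), self-matches excluded (Richman–Moorman counting:
#' template starts are restricted so every template has an extension). Low
#' values indicate self-similar, regular signals.
#'
#' @param x Numeric amplitude series of length at least `m + 2`.
#' @param m Template length (default 2).
#' @param r Match tolerance in signal units; when `NULL` it is resolved as
#'   `r_fraction` times the sample standard deviation of `x`.
#' @param r_fraction Fraction of the signal SD used when `r` is `NULL`
#'   (default 0.2).
#' @return Nonnegative scalar; 0 for a constant series, `Inf` (with a
#'   warning) when length-`m` templates match but none of their extensions
#'   do. An error is raised when no templates match at all.
#' @export
sample_entropy <- function(x, m = 2L, r = NULL, r_fraction = 0.2) {
  m <- as.integer(m)
  if (m < 1L) stop("need m >= 1")
  if (length(x) < m + 2L) stop("series too short: need at least m + 2 samples")
  if (is.null(r)) {
    s <- stats::sd(x)
    if (s == 0) return(0)            # constant series: perfectly regular
    r <- r_fraction * s
  }
  if (r <= 0) {
    if (stats::sd(x) == 0) return(0)
    stop("tolerance r must be positive")
  }
  cnt <- .sampen_counts(as.numeric(x), m, r)
  A <- cnt[1L]; B <- cnt[2L]
  if (B == 0) stop("sample entropy undefined: no template matches at r = ", r)
  if (A == 0) {
    warning("no (m+1)-template matches; sample entropy is infinite")
    return(Inf)
  }
  -log(A / B)
}

#' Kernel density estimate of the amplitude distribution
#'
#' Gaussian-kernel density estimate with Silverman's rule-of-thumb bandwidth,
#' evaluated on a 1,024-point grid extending three bandwidths beyond the data
#' range. Feeds the Rényi entropy of the amplitude distribution.
#'
#' @param x Numeric amplitude series, length at least 10, nonzero variance.
#' @param n_grid Number of grid points.
#' @return A `density_estimate`: list with `grid`, `f` (density values) and
#'   `bandwidth`.
#' @export
estimate_density <- function(x, n_grid = 1024L) {
  if (length(x) < 10L) stop("need at least 10 samples for a density estimate")
  if (stats::sd(x) == 0) stop("zero-variance series has no density estimate")
  d <- stats::density(x, bw = "nrd0", n = n_grid, cut = 3)
  structure(list(grid = d$x, f = d$y, bandwidth = d$bw),
            class = "density_estimate")
}

trapezoid <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)

#' Rényi entropy of an amplitude density
#'
#' Differential Rényi entropy of order `alpha`,
#' `H_alpha = log(integral f(x)^alpha dx) / (1 - alpha)`, evaluated by
#' trapezoidal integration over the density grid. With `alpha = 2` this is
#' the collision entropy of the amplitude distribution; being differential it
#' can be negative for sharply concentrated densities, and it shifts by
#' `log(c)` when amplitudes are scaled by `c`.
#'
#' @param dens A `density_estimate` from [estimate_density], or a numeric
#'   series (then the density is estimated first).
#' @param alpha Entropy order, positive and different from 1 (default 2).
#' @return Rényi entropy in nats.
#' @export
renyi_entropy <- function(dens, alpha = 2) {
  if (is.numeric(dens)) dens <- estimate_density(dens)
  if (alpha <= 0 || alpha == 1) stop("need alpha > 0, alpha != 1")
  I <- trapezoid(dens$grid, dens$f^alpha)
  if (!is.finite(I) || I <= 0) stop("non-finite density integral")
  log(I) / (1 - alpha)
}

#' Equal-width amplitude histogram as a discrete distribution
#'
#' Discretizes amplitudes into `n_bins` equal-width bins spanning the data
#' range and normalizes counts to probabilities; feeds the Tsallis entropy.
#' A constant series puts all mass in the first bin.
#'
#' @param x Numeric amplitude series.
#' @param n_bins Number of bins (default 100).
#' @return A `discrete_distribution`: list with `probs` (sums to 1) and
#'   `breaks`.
#' @export
amplitude_histogram <- function(x, n_bins = 100L) {
  n_bins <- as.integer(n_bins)
  if (!length(x)) stop("empty series")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    probs <- c(1, rep(0, n_bins - 1L))
    breaks <- seq(rng[1] - 0.5, rng[1] + 0.5, length.out = n_bins + 1L)
  } else {
    idx <- pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins))
    probs <- tabulate(idx, nbins = n_bins) / length(x)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  structure(list(probs = probs, breaks = breaks),
            class = "discrete_distribution")
}

#' Tsallis entropy of a discrete distribution
#'
#' Non-extensive entropy `S_q = (1 - sum(p_i^q)) / (q - 1)`. For `q > 1` it
#' saturates at `1/(q - 1)` as the distribution flattens over many outcomes
#' (2 for the default `q = 1.5`), which is what a broadband noisy amplitude
#' histogram approaches.
#'
#' @param p A `discrete_distribution` (see [amplitude_histogram]), or a bare
#'   probability vector summing to 1.
#' @param q Entropic index, positive and different from 1 (default 1.5).
#' @return Nonnegative scalar, less than `1/(q-1)` for `q > 1`.
#' @export
tsallis_entropy <- function(p, q = 1.5) {
  if (inherits(p, "discrete_distribution")) p <- p$probs
  if (q <= 0 || q == 1) stop("need q > 0, q != 1")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("`p` must be a probability distribution")
  (1 - sum(p^q)) / (q - 1)
}
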