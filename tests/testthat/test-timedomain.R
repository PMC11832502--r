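test_that("permutation entropy handles degenerate and hand-counted series", {
  expect_equal(permutation_entropy(1:100), 0)
  # x = (4, 7, 9, 10, 6, 11, 3): patterns (123)x2, (312)x2, (213)x1
  x <- c(4, 7, 9, 10, 6, 11, 3)
  expected <- -(0.4 * log(0.4) * 2 + 0.2 * log(0.2))
  expect_equal(permutation_entropy(x), expected, tolerance = 1e-12)
  expect_equal(permutation_entropy(x), oracle_pe(x), tolerance = 1e-12)
  set.seed(1)
  expect_equal(permutation_entropy(rnorm(20000)), log(6), tolerance = 0.01)
  expect_lte(permutation_entropy(rnorm(500)), log(6))
  expect_error(permutation_entropy(c(1, 2, 3), D = 3), "too short")
})

test_that("permutation entropy is translation invariant and tie-stable", {
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(200)
    expect_equal(permutation_entropy(x + 100), permutation_entropy(x))
  }
  # heavy ties: agreement with the stable-sort oracle
  xt <- sample(1:3, 300, replace = TRUE)
  expect_equal(permutation_entropy(xt), oracle_pe(xt), tolerance = 1e-12)
})

test_that("sample entropy matches hand-counting and handles edge cases", {
  expect_equal(sample_entropy(rep(5, 100)), 0)
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  # exhaustive count: A = B = 7 identical template pairs, so -log(1) = 0
  expect_equal(sample_entropy(x, m = 2, r = 0.5), 0)
  expect_equal(sample_entropy(x, m = 2, r = 0.5),
               oracle_sampen(x, 2, 0.5))
  set.seed(4)
  w <- rnorm(2000)
  r <- 0.2 * sd(w)
  expect_equal(sample_entropy(w, 2, r), oracle_sampen(w, 2, r),
               tolerance = 1e-12)
  expect_error(sample_entropy(c(1, 2, 3)), "too short")
  # strongly separated alternation: no m-template matches at tiny r
  expect_error(sample_entropy(seq(1, 100, by = 1) * 100, r = 0.1),
               "no template matches")
})

test_that("density estimate is a proper density and scales correctly", {
  set.seed(10)
  x <- rnorm(10000)
  d <- estimate_density(x)
  expect_lt(max(abs(d$f - dnorm(d$grid))), 0.02)
  expect_equal(oracle_integrate(d$grid, d$f), 1, tolerance = 1e-3)
  d10 <- estimate_density(10 * x)
  expect_equal(max(d10$f), max(d$f) / 10, tolerance = 0.05 * max(d$f) / 10)
  expect_equal(diff(range(d10$grid)), 10 * diff(range(d$grid)),
               tolerance = 0.05 * 10 * diff(range(d$grid)))
  expect_error(estimate_density(rep(1, 100)), "zero-variance")
  expect_error(estimate_density(rnorm(5)), "at least 10")
})

test_that("Renyi entropy matches closed forms and shift/scale laws", {
  set.seed(6)
  for (sigma in c(1, 2)) {
    x <- rnorm(10000, sd = sigma)
    expect_equal(renyi_entropy(x, alpha = 2), log(2 * sigma * sqrt(pi)),
                 tolerance = 0.03 * log(2 * sigma * sqrt(pi)))
  }
  u <- runif(20000, 0, 4)     # uniform width w: H2 = log(w)
  expect_equal(renyi_entropy(u, alpha = 2), log(4), tolerance = 0.05)
  x <- rnorm(2000)
  d <- estimate_density(x)
  dshift <- estimate_density(x + 57.3)
  expect_equal(renyi_entropy(dshift), renyi_entropy(d), tolerance = 1e-6)
  dscale <- estimate_density(3 * x)
  expect_equal(renyi_entropy(dscale), renyi_entropy(d) + log(3),
               tolerance = 0.02)
  expect_error(renyi_entropy(d, alpha = 1), "alpha")
})

test_that("Tsallis entropy has its closed-form values and ceiling", {
  expect_identical(tsallis_entropy(rep(0.25, 4), q = 1.5), 1)
  expect_equal(tsallis_entropy(c(1, rep(0, 9)), q = 1.5), 0)
  # uniform over n bins approaches 1/(q-1) = 2 from below
  v <- vapply(c(100, 1000, 10000),
              function(n) tsallis_entropy(rep(1 / n, n), q = 1.5), 0)
  expect_true(all(diff(v) > 0))
  expect_equal(v[3], 1.98, tolerance = 1e-12)
  expect_lt(v[3], 2)
  expect_error(tsallis_entropy(c(0.7, 0.7), q = 1.5), "probability")
  expect_error(tsallis_entropy(rep(0.25, 4), q = 1), "q")
})

test_that("amplitude histogram is a distribution over equal-width bins", {
  h <- amplitude_histogram(rep(3.2, 50))
  expect_equal(sum(h$probs), 1)
  expect_identical(max(h$probs), 1)
  set.seed(7)
  h2 <- amplitude_histogram(runif(1000), n_bins = 10)
  expect_true(all(abs(h2$probs - 0.1) < 0.05))
  expect_equal(sum(h2$probs), 1, tolerance = 1e-12)
})

test_that("Higuchi dimension separates smooth curves from noise", {
  expect_equal(higuchi_fd(as.numeric(1:1000)), 1, tolerance = 0.05)
  set.seed(8)
  expect_equal(higuchi_fd(rnorm(10000)), 2, tolerance = 0.1)
  t <- seq(0, 4, length.out = 2000)
  expect_equal(higuchi_fd(sin(2 * pi * t)), 1, tolerance = 0.1)
  expect_error(higuchi_fd(rnorm(50), k_max = 10), "too short")
})

test_that("mean binarization thresholds strictly above the mean", {
  expect_identical(binarize_mean(c(1, 3, 1, 3))$bits, c(0L, 1L, 0L, 1L))
  expect_identical(binarize_mean(rep(2, 5))$bits, rep(0L, 5))
  expect_identical(binarize_mean(c(0, 10, 0, 0))$bits, c(0L, 1L, 0L, 0L))
  expect_equal(binarize_mean(c(0, 10, 0, 0))$threshold, 2.5)
})

test_that("LZ76 reproduces the worked parses", {
  expect_identical(lz76_complexity("011001011110"), 6L)
  expect_identical(lz76_complexity("0"), 1L)
  expect_identical(lz76_complexity("01"), 2L)
  expect_identical(lz76_complexity("010101010101"), 3L)
  expect_identical(lz76_complexity(rep(0L, 50)), 2L)
})

test_that("LZ76 count is monotone under sequence extension", {
  set.seed(9)
  bits <- sample(0:1, 400, replace = TRUE)
  counts <- vapply(seq(10, 400, by = 10),
                   function(k) lz76_complexity(bits[1:k]), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("normalized LZC rescales the raw count", {
  expect_equal(lzc_normalized("011001011110"), 6 * log2(12) / 12)
  v <- vapply(c(10, 100, 1000),
              function(n) lzc_normalized(rep(1L, n)), 0)
  expect_equal(v, 2 * log2(c(10, 100, 1000)) / c(10, 100, 1000))
  expect_true(all(v > 0))
})

test_that("estimators are deterministic on identical input", {
  set.seed(10)
  x <- rnorm(600)
  for (f in list(function(z) permutation_entropy(z),
                 function(z) sample_entropy(z),
                 function(z) renyi_entropy(z),
                 function(z) higuchi_fd(z),
                 function(z) lz76_complexity(binarize_mean(z))))
    expect_identical(f(x), f(x))
})

test_that("feature extraction returns finite per-channel rows", {
  set.seed(11)
  fs <- 250
  n <- 1500
  noise <- matrix(rnorm(3 * n), ncol = 3)
  noise[, 2] <- noise[, 1]                       # duplicated channel
  noise[, 3] <- noise[, 3] + 5 * sin(2 * pi * 10 * seq_len(n) / fs)
  rec <- eeg_recording(noise, fs = fs, channels = c("C3", "C4", "O1"),
                       participant_id = "p1", group = "TD")
  ft <- extract_all_features(segment(rec, 0, n))
  expect_identical(nrow(ft), 3L)
  expect_true(all(is.finite(as.matrix(ft[, feature_names()]))))
  # duplicated channel gives identical feature rows
  expect_equal(unname(unlist(ft[1, feature_names()])),
               unname(unlist(ft[2, feature_names()])))
  # strong 10 Hz component: more alpha weight, lower spectral entropy
  ps1 <- compute_psd(noise[, 1], fs)
  ps3 <- compute_psd(noise[, 3], fs)
  expect_gt(relative_band_power(ps3)[["alpha"]],
            relative_band_power(ps1)[["alpha"]])
  expect_lt(ft$spectral_entropy[3], ft$spectral_entropy[1])
})
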