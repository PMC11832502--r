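test_that("normality screen accepts normal and rejects exponential samples", {
  ok <- 0L
  for (s in 1:20) {
    set.seed(s)
    p <- normality_screen(rnorm(5000))
    ok <- ok + all(p > 0.01)
  }
  expect_gte(ok, 18L)
  for (s in 1:5) {
    set.seed(s)
    p <- normality_screen(rexp(5000))
    expect_true(all(p < 0.01))
  }
  expect_error(normality_screen(c(1, 2)), "at least 4")
  expect_error(normality_screen(rep(1, 50)), "constant")
})

test_that("two-sample tests reach their degenerate extremes", {
  a <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  r <- two_sample_tests(a, a)
  expect_equal(r[["stat_ks"]], 0)
  expect_equal(r[["p_ks"]], 1)
  disjoint <- two_sample_tests(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disjoint[["stat_ks"]], 1)
  expect_error(two_sample_tests(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("exact Mann-Whitney p equals full enumeration over rank assignments", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- two_sample_tests(a, b)
  expect_equal(r[["stat_mwu"]], 0)
  expect_equal(r[["p_mwu"]], oracle_mwu_exact_p(a, b))  # 2/20
  expect_equal(r[["p_mwu"]], 0.1)
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(6) + 1
    expect_equal(two_sample_tests(x, y)[["p_mwu"]], oracle_mwu_exact_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("MWU normal approximation tracks the exact test at n = 15", {
  set.seed(22)
  for (i in 1:15) {
    x <- rnorm(15); y <- rnorm(15) + runif(1, 0, 1)
    p_approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(p_approx - p_exact), 0.02)
  }
})

test_that("Bonferroni division displays the corrected threshold", {
  a <- bonferroni_alpha(0.05, 19)
  expect_equal(attr(a, "display"), 0.0026)
  expect_equal(as.numeric(a), 0.05 / 19)
  expect_equal(as.numeric(bonferroni_alpha(0.05, 1)), 0.05)
  expect_equal(as.numeric(bonferroni_alpha(0.10, 5)), 0.02)
  expect_error(bonferroni_alpha(1.2, 3), "alpha")
})

test_that("mean CI is exact for degenerate input and linear in the data", {
  expect_equal(unname(mean_ci(rep(3, 10))), c(3, 3))
  set.seed(23)
  x <- rnorm(50)
  ci <- mean_ci(x)
  expect_equal(unname(mean_ci(2 * x)), unname(2 * ci))
  expect_lt(ci[["lo"]], mean(x))
  expect_gt(ci[["hi"]], mean(x))
  # coverage: interval covers the true mean about 95% of the time
  cover <- 0L
  for (s in 1:40) {
    set.seed(s)
    ci_s <- mean_ci(rnorm(200))
    cover <- cover + (ci_s[["lo"]] < 0 && ci_s[["hi"]] > 0)
  }
  expect_gte(cover, 34L)
  expect_error(mean_ci(3), "at least 2")
})

fake_feature_table <- function(n_td = 12, n_asd = 15, channels = c("C3", "C4"),
                               shift = list(), seed = 1) {
  set.seed(seed)
  grid <- expand.grid(participant_id = c(sprintf("td%02d", seq_len(n_td)),
                                         sprintf("as%02d", seq_len(n_asd))),
                      channel = channels, stringsAsFactors = FALSE)
  grid$group <- ifelse(grepl("^td", grid$participant_id), "TD", "ASD")
  for (f in setdiff(feature_names(), "lzc_normalized")) {
    v <- rnorm(nrow(grid))
    if (!is.null(shift[[f]])) v <- v + shift[[f]] * (grid$group == "ASD")
    grid[[f]] <- v
  }
  grid$lzc_normalized <- rnorm(nrow(grid))
  grid
}

test_that("comparison table has one row per feature and channel", {
  ft <- fake_feature_table(channels = sprintf("ch%02d", 1:19))
  ct <- build_comparison_table(ft)
  expect_identical(nrow(ct), 8L * 19L)
  expect_true(all(ct$p_ks >= 0 & ct$p_ks <= 1))
  expect_true(all(ct$p_mwu >= 0 & ct$p_mwu <= 1))
  expect_equal(attr(ct, "alpha_corrected"), 0.05 / 19)
})

test_that("an injected group shift is flagged in almost every channel", {
  ft <- fake_feature_table(n_td = 39, n_asd = 49,
                           channels = sprintf("ch%02d", 1:19),
                           shift = list(renyi_entropy = 3))
  ct <- build_comparison_table(ft)
  sig <- ct[ct$feature == "renyi_entropy", ]
  expect_gte(sum(sig$significant_both), 18L)
  expect_true(all(sig$direction[sig$significant_both] > 0))
  other <- ct[ct$feature != "renyi_entropy", ]
  expect_lte(sum(other$significant_both), 2L)
})

test_that("significance flags are monotone in the corrected level", {
  ft <- fake_feature_table(n_td = 20, n_asd = 20,
                           shift = list(lzc = 1.5, brain_rate = -1))
  loose <- build_comparison_table(ft, alpha = 0.05, m_tests = 1)
  strict <- build_comparison_table(ft, alpha = 0.0005, m_tests = 19)
  expect_true(all(!strict$significant_both | loose$significant_both))
})

test_that("direction reflects the median difference regardless of row order", {
  ft <- fake_feature_table(shift = list(brain_rate = -2))
  ct1 <- build_comparison_table(ft)
  ct2 <- build_comparison_table(ft[rev(seq_len(nrow(ft))), ])
  br1 <- ct1[ct1$feature == "brain_rate", ]
  br2 <- ct2[ct2$feature == "brain_rate", ]
  br2 <- br2[match(br1$channel, br2$channel), ]
  expect_identical(br1$direction, br2$direction)
  expect_true(all(br1$direction < 0))
})

test_that("the per-feature summary counts starred channels by direction", {
  ft <- fake_feature_table(n_td = 30, n_asd = 30,
                           channels = sprintf("ch%02d", 1:5),
                           shift = list(tsallis_entropy = 4))
  sm <- summarize_comparisons(build_comparison_table(ft, m_tests = 19))
  row <- sm[sm$feature == "tsallis_entropy", ]
  expect_identical(row$n_significant, 5L)
  expect_identical(row$n_asd_higher, 5L)
  expect_lte(sum(sm$n_significant[sm$feature != "tsallis_entropy"]), 1L)
})
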