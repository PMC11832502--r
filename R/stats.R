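#' Normality screen for a feature sample
#'
#' Shapiro–Wilk test plus a one-sample Kolmogorov–Smirnov test against a
#' normal distribution with parameters estimated from the sample (Lilliefors
#' correction). Used to justify the switch to nonparametric group tests.
#'
#' @param values Numeric sample, at least 4 and at most 5000 values, not
#'   constant.
#' @return Named numeric vector `c(p_shapiro, p_ks1)`.
#' @export
normality_screen <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("need at least 4 finite values")
  if (length(values) > 5000L) stop("Shapiro-Wilk supports at most 5000 values")
  if (stats::sd(values) == 0) stop("constant sample has no normality test")
  c(p_shapiro = stats::shapiro.test(values)$p.value,
    p_ks1 = nortest::lillie.test(values)$p.value)
}

#' Two-sample nonparametric tests
#'
#' Two-sided p-values of the two-sample Kolmogorov–Smirnov test and the
#' Mann–Whitney U test. The MWU p-value is exact (network enumeration) when
#' both groups have at most 20 observations and no ties, and otherwise uses
#' the normal approximation with continuity and tie correction.
#'
#' @param a,b Numeric samples, at least 3 values each.
#' @return Named numeric vector `c(stat_ks, p_ks, stat_mwu, p_mwu)`;
#'   `stat_ks` is the KS D statistic and `stat_mwu` the Mann–Whitney U of
#'   the first sample.
#' @export
two_sample_tests <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L) stop("need at least 3 values per group")
  exact <- max(length(a), length(b)) <= 20L && !any(duplicated(c(a, b)))
  ks <- suppressWarnings(stats::ks.test(a, b))
  mwu <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  c(stat_ks = unname(ks$statistic), p_ks = ks$p.value,
    stat_mwu = unname(mwu$statistic), p_mwu = mwu$p.value)
}

#' Bonferroni-corrected significance level
#'
#' Family-wise correction by division: `alpha / m_tests`. The full-precision
#' threshold is returned with a display value rounded to 4 decimals attached
#' as an attribute (0.05 over 19 channels displays as 0.0026).
#'
#' @param alpha Uncorrected significance level in (0, 1).
#' @param m_tests Number of hypotheses (here, channels per feature).
#' @return Corrected threshold (numeric scalar) with attribute `display`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m_tests = 19L) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (m_tests < 1L) stop("`m_tests` must be >= 1")
  out <- alpha / m_tests
  attr(out, "display") <- round(out, 4)
  out
}

#' t-based confidence interval of a group mean
#'
#' `mean +/- t_{n-1, (1+level)/2} * SD / sqrt(n)`; the interval drawn as an
#' error bar for each group and channel.
#'
#' @param values Numeric sample with at least 2 values and finite SD.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
mean_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a confidence interval")
  s <- stats::sd(values)
  if (!is.finite(s)) stop("non-finite standard deviation")
  half <- stats::qt((1 + level) / 2, df = n - 1L) * s / sqrt(n)
  c(lo = mean(values) - half, hi = mean(values) + half)
}

#' Channel-wise group comparison table
#'
#' For every (feature, channel) cell of a cohort feature table, runs the
#' two-sample KS and Mann–Whitney U tests between the ASD and TD groups and
#' flags the cell significant when *both* p-values fall below the
#' Bonferroni-corrected level (`alpha / m_tests`, correcting over channels).
#' Group-mean 95% confidence intervals and the direction of the median
#' difference are attached for error-bar reporting.
#'
#' @param ft Feature table from [cohort_features]: columns `participant_id`,
#'   `group` (`"TD"`/`"ASD"`), `channel`, and one column per feature.
#' @param features Feature columns to compare; defaults to the eight compared
#'   features (the normalized LZ76 variant is reported separately).
#' @param alpha Uncorrected significance level.
#' @param m_tests Number of hypotheses for the Bonferroni division; defaults
#'   to the number of channels in `ft`.
#' @param ci_level Confidence level for the group-mean intervals.
#' @return Data frame with one row per feature x channel: `feature`,
#'   `channel`, `p_ks`, `p_mwu`, `significant_both`, `direction` (sign of
#'   median(ASD) - median(TD)), and per-group mean/CI columns. The corrected
#'   threshold is attached as attribute `alpha_corrected`.
#' @export
build_comparison_table <- function(ft, features = setdiff(feature_names(),
                                                          "lzc_normalized"),
                                   alpha = 0.05, m_tests = NULL,
                                   ci_level = 0.95) {
  if (!all(c("group", "channel") %in% names(ft)))
    stop("feature table must have `group` and `channel` columns")
  missing_feat <- setdiff(features, names(ft))
  if (length(missing_feat))
    stop("feature table lacks columns: ", paste(missing_feat, collapse = ", "))
  channels <- unique(ft$channel)
  if (is.null(m_tests)) m_tests <- length(channels)
  a_corr <- bonferroni_alpha(alpha, m_tests)
  rows <- list()
  for (feat in features) {
    for (ch in channels) {
      sub <- ft[ft$channel == ch, c("group", feat)]
      td <- sub[sub$group == "TD", feat]
      asd <- sub[sub$group == "ASD", feat]
      if (!length(td) || !length(asd))
        stop("missing group for feature ", feat, ", channel ", ch)
      p <- two_sample_tests(td, asd)
      ci_td <- mean_ci(td, ci_level)
      ci_asd <- mean_ci(asd, ci_level)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, channel = ch,
        p_ks = p[["p_ks"]], p_mwu = p[["p_mwu"]],
        significant_both = p[["p_ks"]] < a_corr && p[["p_mwu"]] < a_corr,
        direction = sign(stats::median(asd) - stats::median(td)),
        mean_td = mean(td), ci_lo_td = ci_td[["lo"]], ci_hi_td = ci_td[["hi"]],
        mean_asd = mean(asd), ci_lo_asd = ci_asd[["lo"]],
        ci_hi_asd = ci_asd[["hi"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha_corrected") <- as.numeric(a_corr)
  out
}

#' Per-feature summary of significant channels
#'
#' Counts, for each feature, the channels flagged significant by both tests
#' at the corrected level, split by the direction of the group difference.
#'
#' @param ct Comparison table from [build_comparison_table].
#' @return Data frame with columns `feature`, `n_significant`, `n_asd_higher`,
#'   `n_asd_lower`.
#' @export
summarize_comparisons <- function(ct) {
  feats <- unique(ct$feature)
  do.call(rbind, lapply(feats, function(f) {
    sub <- ct[ct$feature == f & ct$significant_both, ]
    data.frame(feature = f,
               n_significant = nrow(sub),
               n_asd_higher = sum(sub$direction > 0),
               n_asd_lower = sum(sub$direction < 0),
               stringsAsFactors = FALSE)
  }))
}
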