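# Independent brute-force oracles. These deliberately share no code with the
# package: different algorithms, different encodings, plain loops.

# Exhaustive-history LZ76 parse by literal substring search: the candidate
# word s[l..l+k-1] closes when it is not a substring of s[1..l+k-2].
oracle_lz76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  c <- 0L
  l <- 1L
  while (l <= n) {
    k <- 1L
    while (l + k - 1L <= n &&
           grepl(substr(s, l, l + k - 1L), substr(s, 1L, l + k - 2L),
                 fixed = TRUE)) {
      k <- k + 1L
    }
    c <- c + 1L
    l <- l + k
  }
  c
}

# Ordinal-pattern entropy by explicit window sorting (order() is stable, so
# ties break by order of appearance).
oracle_pe <- function(x, D = 3L, tau = 1L) {
  n_win <- length(x) - (D - 1L) * tau
  pats <- vapply(seq_len(n_win), function(i) {
    w <- x[seq.int(i, by = tau, length.out = D)]
    paste(order(w), collapse = "-")
  }, "")
  p <- as.numeric(table(pats)) / n_win
  -sum(p * log(p))
}

# Naive O(n^2) template-pair counting for sample entropy, Chebyshev
# distance, strict matches, template starts 1..n-m.
oracle_sampen_counts <- function(x, m = 2L, r) {
  n <- length(x)
  N <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      dmax <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dmax < r) {
        B <- B + 1L
        if (max(dmax, abs(x[i + m] - x[j + m])) < r) A <- A + 1L
      }
    }
  }
  c(A = A, B = B)
}

oracle_sampen <- function(x, m = 2L, r) {
  cnt <- oracle_sampen_counts(x, m, r)
  -log(cnt[["A"]] / cnt[["B"]])
}

# Plain-loop trapezoidal integration (independent of the package's helper).
oracle_integrate <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L))
    s <- s + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  s
}

# Literal Higuchi algorithm with the slope from the covariance formula.
oracle_higuchi <- function(x, k_max = 10L) {
  n <- length(x)
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lm_ <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      total <- 0
      for (i in seq_len(length(idx) - 1L))
        total <- total + abs(x[idx[i + 1L]] - x[idx[i]])
      nk <- length(idx) - 1L
      lm_[m] <- total * (n - 1) / (nk * k) / k
    }
    lk[k] <- mean(lm_)
  }
  u <- log(1 / seq_len(k_max))
  v <- log(lk)
  stats::cov(u, v) / stats::var(u)
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
oracle_mwu_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(idx) {
    g1 <- pooled[idx]; g2 <- pooled[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2L, u_stat)
  mu <- length(a) * length(b) / 2
  # two-sided: double the smaller tail, capped at 1
  min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
}

# Longest clean run by scanning every window.
oracle_longest_run <- function(mask) {
  n <- length(mask)
  best_start <- -1L; best_len <- 0L
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(mask[s:e]) && (e - s + 1L) > best_len) {
        best_len <- e - s + 1L
        best_start <- s - 1L   # 0-based
      }
    }
  }
  c(start = best_start, len = best_len)
}
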