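test_that("background noise is standardized and spectrally shaped", {
  set.seed(31)
  w <- generate_background(5000, 250, 0)
  expect_equal(mean(w), 0, tolerance = 0.02)
  expect_equal(sd(w), 1, tolerance = 0.02)
  expect_lt(abs(cor(w[-1], w[-length(w)])), 0.05)

  p <- generate_background(10750, 250, 2)
  ps <- compute_psd(p, 250)
  sel <- ps$freqs >= 1 & ps$freqs <= 30
  slope <- unname(coef(lm(log(ps$psd[sel]) ~ log(ps$freqs[sel])))[2])
  expect_equal(slope, -2, tolerance = 0.3 / 2)
  expect_equal(mean(p), 0, tolerance = 0.02)
  expect_equal(sd(p), 1, tolerance = 0.02)
  expect_error(generate_background(1, 250, 1), "n >= 2")
})

test_that("the alpha component concentrates power at 10-11 Hz", {
  set.seed(32)
  bg <- generate_background(10750, 250, 1)
  expect_identical(add_alpha_component(bg, 250, 0), bg)
  withalpha <- add_alpha_component(bg, 250, 3)
  f0 <- relative_power_per_hz(compute_psd(bg, 250))
  f1 <- relative_power_per_hz(compute_psd(withalpha, 250))
  expect_gt(f1[["10"]], f0[["10"]])
  # component RMS honours the gain
  expect_equal(sqrt(mean((withalpha - bg)^2)), 3 * sd(bg), tolerance = 1e-6)
  set.seed(99); a1 <- add_alpha_component(bg, 250, 2)
  set.seed(99); a2 <- add_alpha_component(bg, 250, 2)
  expect_identical(a1, a2)
})

test_that("spike trains arrive at the requested quasi-periodic rate", {
  set.seed(33)
  bg <- generate_background(10750, 250, 1.6)
  expect_identical(add_spike_train(bg, 250, 0, 4), bg)
  sp <- add_spike_train(bg, 250, 2, 4)
  expect_lte(abs(attr(sp, "n_spikes") - 2 * 43), 2)
  expect_identical(length(sp), length(bg))
})

test_that("spike-wave trains regularize the binarized sequence", {
  lower <- 0L
  for (s in 1:50) {
    set.seed(s)
    bg <- generate_background(2500, 250, 1.6)
    with_sp <- lz76_complexity(binarize_mean(add_spike_train(bg, 250, 2, 4)))
    without <- lz76_complexity(binarize_mean(bg))
    lower <- lower + (with_sp < without)
  }
  expect_gte(lower, 40L)
})

test_that("cohorts are reproducible, labelled, and participant-varied", {
  cfg <- tiny_cohort_cfg()
  recs1 <- generate_cohort(cfg)
  recs2 <- generate_cohort(cfg)
  expect_identical(recs1, recs2)
  expect_identical(length(recs1), 8L)
  expect_identical(vapply(recs1, `[[`, "", "group"),
                   rep(c("TD", "ASD"), each = 4))
  expect_identical(recs1[[1]]$channels, montage_1020)
  expect_identical(nrow(recs1[[1]]$data), 1500L)
  # different participants differ, as do different seeds
  expect_false(identical(recs1[[1]]$data, recs1[[2]]$data))
  cfg2 <- tiny_cohort_cfg(); cfg2$seed <- 8L
  expect_false(identical(generate_cohort(cfg2)[[1]]$data, recs1[[1]]$data))
  # amplitude scaling separates groups
  sd_td <- mean(apply(recs1[[1]]$data, 2, sd))
  sd_asd <- mean(apply(recs1[[5]]$data, 2, sd))
  expect_gt(sd_asd / sd_td, 1.3)
})

test_that("group-mean alpha fraction is higher for TD than ASD", {
  recs <- generate_cohort(tiny_cohort_cfg())
  segs <- trim_to_common_length(lapply(recs, longest_clean_run))
  frac10 <- vapply(segs, function(seg) {
    mean(vapply(compute_psd(seg), function(ps)
      relative_power_per_hz(ps)[["10"]], 0))
  }, 0)
  grp <- vapply(segs, function(s) s$recording$group, "")
  expect_gt(mean(frac10[grp == "TD"]), mean(frac10[grp == "ASD"]))
})

test_that("cohort writing produces a readable manifest and files", {
  dir <- withr::local_tempdir()
  recs <- generate_cohort(cohort_config(n_td = 1, n_asd = 1, duration_s = 4,
                                        seed = 2))
  write_cohort(recs, dir, format = "text")
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(manifest), 2L)
  back <- read_recording(file.path(dir, manifest$file[1]))
  expect_equal(unname(back$data), unname(recs[[1]]$data), tolerance = 1e-8)
})
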