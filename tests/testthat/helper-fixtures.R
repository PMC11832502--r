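# Small in-code fixtures shared across test files.

make_recording <- function(n = 500, n_ch = 2, fs = 250, seed = 1,
                           channels = paste0("ch", seq_len(n_ch)), ...) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n * n_ch), ncol = n_ch), fs = fs,
                channels = channels, ...)
}

montage_recording <- function(n = 1000, fs = 250, seed = 1, ...) {
  make_recording(n = n, n_ch = 19, fs = fs, seed = seed,
                 channels = montage_1020, ...)
}

tiny_cohort_cfg <- function(...) {
  cohort_config(n_td = 4L, n_asd = 4L, duration_s = 6, seed = 7L, ...)
}
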