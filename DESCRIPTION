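Package: eegcomplexity
Title: Entropy, Complexity and Spectral Features for Quantitative EEG Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Channel-wise quantitative analysis of resting-state EEG. Computes
    relative band power, brain rate, spectral entropy, permutation entropy,
    sample entropy, Renyi and Tsallis entropy, Higuchi fractal dimension and
    Lempel-Ziv (LZ76) complexity for every channel of a multichannel recording,
    and compares two groups channel by channel with two-sample
    Kolmogorov-Smirnov and Mann-Whitney U tests under a Bonferroni-corrected
    significance level. Includes EDF and delimited-text I/O for 10/20-montage
    recordings, artifact-mask based segment selection, and a calibrated
    synthetic two-group cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    nortest,
    signal,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
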