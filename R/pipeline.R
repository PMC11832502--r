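#' Pipeline configuration
#'
#' Bundles everything a full run needs: the input source (a directory of
#' recordings with a `manifest.csv`, or a synthetic [cohort_config]),
#' estimator parameters, the significance level and hypothesis count for the
#' Bonferroni division, and the output directory.
#'
#' @param input A [cohort_config] for synthetic mode, or a directory path
#'   containing recordings plus a `manifest.csv` with columns
#'   `participant_id`, `group`, `file`.
#' @param params Estimator parameters, see [feature_params].
#' @param alpha Uncorrected significance level.
#' @param m_tests Hypotheses for the Bonferroni division (defaults to the
#'   channel count).
#' @param out_dir Directory for the CSV/JSON artifacts.
#' @param filter Apply the acquisition-chain filters before segmenting.
#' @param seed Seed recorded in the manifest; for synthetic input it
#'   overrides `input$seed` when non-`NULL`.
#' @return Named list (class `pipeline_config`).
#' @export
pipeline_config <- function(input = cohort_config(), params = feature_params(),
                            alpha = 0.05, m_tests = NULL, out_dir = "qeeg_run",
                            filter = FALSE, seed = NULL) {
  structure(list(input = input, params = params, alpha = alpha,
                 m_tests = m_tests, out_dir = out_dir, filter = filter,
                 seed = seed),
            class = "pipeline_config")
}

read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    stop("input directory needs a manifest.csv (participant_id, group, file)")
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i)
    read_recording(file.path(dir, manifest$file[i]),
                   participant_id = manifest$participant_id[i],
                   group = manifest$group[i]))
}

group_hz_spectra <- function(segs, f_max = 20) {
  rows <- lapply(segs, function(seg) {
    frac <- vapply(compute_psd(seg), relative_power_per_hz, f_max = f_max,
                   numeric(ceiling(f_max)))
    data.frame(group = seg$recording$group, f_lo = 0:(ceiling(f_max) - 1L),
               fraction = rowMeans(frac), stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  stats::aggregate(fraction ~ group + f_lo, data = all, FUN = mean)
}

#' Run the full analysis pipeline
#'
#' Generates or reads the cohort, validates the montage, selects the longest
#' clean segment per participant and trims to the common length, extracts
#' all per-channel features, runs the channel-wise group comparison and
#' writes the run artifacts: `features.csv`, `comparison.csv`,
#' `error_bars.csv`, `hz_spectra.csv` and `manifest.json`.
#'
#' @param cfg A [pipeline_config].
#' @return Invisibly, a list with the in-memory `features`, `comparison`,
#'   `error_bars` and `hz_spectra` tables plus the artifact `paths`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) stop("`cfg` must be a pipeline_config")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[%5.1fs] %s",
                                         as.numeric(Sys.time() - t0, "secs"),
                                         msg))
  if (inherits(cfg$input, "cohort_config")) {
    input <- cfg$input
    if (!is.null(cfg$seed)) input$seed <- cfg$seed
    stage(sprintf("generating synthetic cohort (%d TD + %d ASD, seed %d)",
                  input$n_td, input$n_asd, input$seed))
    recordings <- generate_cohort(input)
    seed_used <- input$seed
  } else {
    stage(paste("reading cohort from", cfg$input))
    recordings <- read_cohort(cfg$input)
    for (rec in recordings) {
      issues <- validate_montage(rec)
      if (length(issues))
        warning("montage issues for ", rec$participant_id, ": ",
                paste(issues, collapse = "; "))
    }
    seed_used <- cfg$seed
  }
  if (cfg$filter) {
    stage("applying recording-chain filters")
    recordings <- lapply(recordings, apply_recording_filters)
  }
  stage("selecting and trimming clean segments")
  segs <- trim_to_common_length(lapply(recordings, longest_clean_run))
  stage(sprintf("extracting features (%d participants x %d channels, %d samples)",
                length(segs), ncol(segs[[1]]$recording$data), segs[[1]]$n))
  ft <- do.call(rbind, lapply(segs, extract_all_features, params = cfg$params))
  stage("comparing groups channel-wise")
  ct <- build_comparison_table(ft, alpha = cfg$alpha, m_tests = cfg$m_tests)
  hz <- group_hz_spectra(segs)
  eb <- comparison_error_bars(ct)

  paths <- list(features = file.path(cfg$out_dir, "features.csv"),
                comparison = file.path(cfg$out_dir, "comparison.csv"),
                error_bars = file.path(cfg$out_dir, "error_bars.csv"),
                hz_spectra = file.path(cfg$out_dir, "hz_spectra.csv"),
                manifest = file.path(cfg$out_dir, "manifest.json"))
  write_csv_artifact(ft, paths$features)
  ct_out <- ct
  ct_out$p_ks_display <- round(ct$p_ks, 3)
  ct_out$p_mwu_display <- round(ct$p_mwu, 3)
  write_csv_artifact(ct_out, paths$comparison)
  write_csv_artifact(eb, paths$error_bars)
  write_csv_artifact(hz, paths$hz_spectra)
  manifest <- list(
    package = "eegcomplexity",
    version = as.character(utils::packageVersion("eegcomplexity")),
    seed = seed_used,
    alpha = cfg$alpha,
    alpha_corrected = attr(ct, "alpha_corrected"),
    n_participants = length(recordings),
    n_channels = ncol(segs[[1]]$recording$data),
    segment_samples = segs[[1]]$n,
    n_feature_rows = nrow(ft),
    n_comparison_rows = nrow(ct))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stage("done")
  invisible(list(features = ft, comparison = ct, error_bars = eb,
                 hz_spectra = hz, paths = paths))
}

write_csv_artifact <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
}

comparison_error_bars <- function(ct) {
  long <- rbind(
    data.frame(feature = ct$feature, channel = ct$channel, group = "TD",
               mean = ct$mean_td, ci_lo = ct$ci_lo_td, ci_hi = ct$ci_hi_td,
               stringsAsFactors = FALSE),
    data.frame(feature = ct$feature, channel = ct$channel, group = "ASD",
               mean = ct$mean_asd, ci_lo = ct$ci_lo_asd,
               ci_hi = ct$ci_hi_asd, stringsAsFactors = FALSE))
  long[order(long$feature, long$channel, long$group), ]
}

#' Summarize a finished run
#'
#' Reads the comparison CSV of a run directory (or takes the in-memory
#' result of [run_pipeline]) and prints, per feature, how many channels were
#' flagged significant by both tests and in which direction.
#'
#' @param run A run directory path or the list returned by [run_pipeline].
#' @return The per-feature summary data frame, invisibly.
#' @export
summarize_run <- function(run) {
  ct <- if (is.character(run)) {
    f <- file.path(run, "comparison.csv")
    if (!file.exists(f)) stop("no comparison.csv in ", run)
    utils::read.csv(f, stringsAsFactors = FALSE)
  } else run$comparison
  sm <- summarize_comparisons(ct)
  n_ch <- length(unique(ct$channel))
  for (i in seq_len(nrow(sm))) {
    dir <- if (sm$n_significant[i] == 0) "" else if
      (sm$n_asd_higher[i] >= sm$n_asd_lower[i]) " (ASD > TD)" else " (ASD < TD)"
    cat(sprintf("%-20s %2d / %d significant channels%s\n",
                sm$feature[i], sm$n_significant[i], n_ch, dir))
  }
  invisible(sm)
}
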