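# End-to-end orchestration: simulate -> preprocess -> sensorstats -> nvc ->
# network -> classify.  Each stage reads its inputs from disk and writes
# its outputs to <out>/<stage>/, so any stage can be re-run or resumed from
# the on-disk artifacts of the previous one.

.stage_done <- function(dir) file.exists(file.path(dir, ".complete"))

.mark_done <- function(dir) {
  files <- setdiff(list.files(dir, recursive = TRUE), ".complete")
  sums <- tools::md5sum(file.path(dir, files))
  writeLines(paste(unname(sums), files, sep = "  "),
             file.path(dir, ".complete"))
}

.verify_stage <- function(dir) {
  manifest <- readLines(file.path(dir, ".complete"))
  for (line in manifest) {
    parts <- strsplit(line, "  ", fixed = TRUE)[[1]]
    f <- file.path(dir, parts[2])
    if (!file.exists(f) || !identical(unname(tools::md5sum(f)), parts[1]))
      stop("resumable-run error: intermediate file corrupted or missing: ",
           f)
  }
}

.pipeline_args <- function(overrides) {
  lapply(overrides, function(v) v)
}

#' Run the full analysis pipeline
#'
#' Executes all six stages under `config$out`, writing plain-text artifacts
#' per stage plus a provenance record (`provenance.json`: config hash,
#' seed, package version, per-stage checksums, timestamps).  Completed
#' stages (marked by a checksum manifest) are verified and skipped on
#' re-run; a corrupted intermediate file raises an error naming the file.
#'
#' @param config A [run_config()].
#' @param force Re-run stages even if marked complete (default FALSE).
#' @return Invisibly, a list with the key stage results (`accuracy_table`,
#'   `nvc_peak`, `provenance`).
#' @export
run_pipeline <- function(config = run_config(), force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  stage_times <- list()

  stage <- function(name, fun) {
    dir <- file.path(out, name)
    if (!force && .stage_done(dir)) {
      .verify_stage(dir)
      message("stage ", name, ": complete, skipping")
      return(invisible(NULL))
    }
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    t0 <- Sys.time()
    tryCatch(fun(dir), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    .mark_done(dir)
    stage_times[[name]] <<- c(start = format(t0), end = format(Sys.time()))
    invisible(NULL)
  }

  stage("simulate", function(dir) {
    pcfg <- do.call(paradigm_config,
                    c(.pipeline_args(config$paradigm),
                      if (!"seed" %in% names(config$paradigm))
                        list(seed = config$seed)))
    truth <- do.call(ground_truth, .pipeline_args(config$truth))
    rec <- generate_subject(pcfg, truth, seed = config$seed)
    write_recording(rec, dir)
  })

  stage("preprocess", function(dir) {
    rec <- read_recording(file.path(out, "simulate"))
    eps <- do.call(preprocess_subject,
                   c(list(rec), .pipeline_args(config$preprocessing)))
    for (m in names(eps)) write_epochs(eps[[m]], file.path(dir, m))
    # unfiltered (full-bandwidth) HbO epochs for the lag analysis
    hb <- mbll_convert(rec$fnirs$intensity)
    wide <- epoch_extract(hb$hbo, 1 / rec$fnirs$dt_s, rec$schedule,
                          c(-6.5, 5.5), modality = "HbO",
                          baseline_window_s = c(-6.5, -0.5),
                          channel_names = rec$fnirs$channel_names)
    write_epochs(baseline_correct(wide), file.path(dir, "hbo_wide"))
  })

  stage("sensorstats", function(dir) {
    eeg <- read_epochs(file.path(out, "preprocess", "eeg"))
    hbo <- read_epochs(file.path(out, "preprocess", "hbo"))
    an <- channel_anova(eeg, window_s = c(0.35, 0.40), alpha = 0.001)
    data.table::fwrite(as.data.frame(an),
                       file.path(dir, "eeg_anova.tsv"), sep = "\t")
    an_f <- channel_anova(hbo, window_s = c(0, 3.5), alpha = 0.05)
    data.table::fwrite(as.data.frame(an_f),
                       file.path(dir, "hbo_anova.tsv"), sep = "\t")
    tt <- hbo_block_ttest(hbo)
    data.table::fwrite(as.data.frame(tt),
                       file.path(dir, "hbo_block_ttest.tsv"), sep = "\t")
    t3 <- tt[tt$time_s == 3, ]
    map <- topo_interpolate(t3$t, fnirs_layout_48())
    .write_matrix_tsv(map$grid, file.path(dir, "hbo_t3_topomap.tsv"))
    plot_topo_png(map, file.path(dir, "hbo_t3_topomap.png"),
                  main = "HbO t statistic, 3 s")
  })

  stage("nvc", function(dir) {
    eeg <- read_epochs(file.path(out, "preprocess", "eeg"))
    hbo <- read_epochs(file.path(out, "preprocess", "hbo_wide"))
    erp <- summary_waveform(grand_average(eeg))
    hbw <- summary_waveform(grand_average(hbo))
    xr <- config$nvc$X_ms_range
    surf <- lag_surface(erp, hbw,
                        erp_t0_s = eeg$t0_offset_s, hbo_t0_s = hbo$t0_offset_s,
                        erp_rate_hz = eeg$rate_hz,
                        hbo_dt_s = 1 / hbo$rate_hz,
                        X_ms = xr[1]:xr[2],
                        Y_ms = seq(0, config$nvc$Y_ms_max, by = 27))
    reg <- high_corr_region(surf, threshold = config$nvc$threshold)
    .write_matrix_tsv(surf$r_min, file.path(dir, "r_min_surface.tsv"))
    jsonlite::write_json(
      list(peak_X_ms = reg$peak_X_ms, peak_Y_ms = reg$peak_Y_ms,
           peak_r = reg$peak_r, n_region = reg$n_region,
           threshold = config$nvc$threshold),
      file.path(dir, "nvc_report.json"), auto_unbox = TRUE, digits = NA)
  })

  stage("network", function(dir) {
    eeg <- read_epochs(file.path(out, "preprocess", "eeg"))
    hbo <- read_epochs(file.path(out, "preprocess", "hbo"))
    den <- config$network$density
    win <- config$network$window_s
    write_feature_table(trial_feature_table(eeg, win, den),
                        file.path(dir, "features_eeg"))
    write_feature_table(trial_feature_table(hbo, win, den),
                        file.path(dir, "features_fnirs"))
    gan <- grand_average_networks(eeg, win, den)
    for (cond in names(gan))
      write_network(gan[[cond]], file.path(dir, paste0("ga_eeg_", cond)))
  })

  stage("classify", function(dir) {
    cc <- config$classification
    eeg <- read_feature_table(file.path(out, "network", "features_eeg"))
    fni <- read_feature_table(file.path(out, "network", "features_fnirs"))
    tables <- list(eeg = eeg, fnirs = fni,
                   fused = fuse_features(eeg, fni))
    rows <- list()
    for (m in intersect(cc$modalities, names(tables))) {
      cv <- repeated_cv(tables[[m]], n_reps = cc$n_reps,
                        n_folds = cc$n_folds, n_keep = cc$n_keep,
                        k_neighbors = cc$k_neighbors, C_grid = cc$C_grid,
                        gamma_grid = cc$gamma_grid,
                        inner_folds = cc$inner_folds, tuning = cc$tuning,
                        seed = config$seed)
      rows[[m]] <- data.frame(modality = m, accuracy = cv$accuracy,
                              sd_folds = stats::sd(cv$fold_accuracy))
      data.table::fwrite(as.data.frame(cv$confusion),
                         file.path(dir, paste0("confusion_", m, ".tsv")),
                         sep = "\t")
      top <- sort(cv$selected_count, decreasing = TRUE)
      jsonlite::write_json(as.list(top[top > 0][seq_len(min(50, sum(top > 0)))]),
                           file.path(dir, paste0("selected_", m, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    data.table::fwrite(do.call(rbind, rows),
                       file.path(dir, "accuracy_table.tsv"), sep = "\t")
  })

  stages <- c("simulate", "preprocess", "sensorstats", "nvc", "network",
              "classify")
  checks <- lapply(stages, function(s) {
    d <- file.path(out, s)
    files <- setdiff(list.files(d, recursive = TRUE), ".complete")
    as.list(tools::md5sum(file.path(d, files)))
  })
  names(checks) <- stages
  prov <- list(
    config_hash = .config_hash(unclass(config)[setdiff(names(config), "out")]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("neurointent")),
    started = format(t_start), finished = format(Sys.time()),
    stage_checksums = checks
  )
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  acc <- utils::read.delim(file.path(out, "classify", "accuracy_table.tsv"))
  nvc_rep <- jsonlite::read_json(file.path(out, "nvc", "nvc_report.json"),
                                 simplifyVector = TRUE)
  invisible(list(accuracy_table = acc, nvc_peak = nvc_rep,
                 provenance = prov))
}
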