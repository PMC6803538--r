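# Native plain-text interchange format: TSV matrices + JSON metadata.
# Every stage of the pipeline reads and writes these files, so stages are
# resumable and inspectable with ordinary text tools.

.write_matrix_tsv <- function(m, path) {
  data.table::fwrite(data.table::as.data.table(m), path, sep = "\t")
  invisible(path)
}

.read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("missing data file: ", path)
  as.matrix(data.table::fread(path, sep = "\t"))
}

# named atomic vectors must become JSON objects (jsonlite drops the names
# of atomic vectors); lists are converted recursively
.jsonify <- function(x) {
  if (is.list(x)) lapply(x, .jsonify)
  else if (!is.null(names(x)) && length(x) > 1L) as.list(x)
  else x
}

.write_meta <- function(meta, path, format) {
  meta$format <- format
  meta$format_version <- 1L
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.read_meta <- function(path, format) {
  if (!file.exists(path)) stop("missing metadata file: ", path)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(meta$format, format))
    stop("schema error in ", path, ": expected format '", format,
         "', found '", meta$format %||% "<none>", "'")
  if (!identical(as.integer(meta$format_version), 1L))
    stop("schema error in ", path, ": unsupported format_version")
  meta
}

#' Write a trial schedule to TSV
#' @param schedule A `trial_schedule`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  df <- as.data.frame(schedule)
  df$condition <- as.character(df$condition)
  attr(df, "total_duration_s") <- NULL
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a trial schedule written by [write_schedule()]
#' @param path TSV path.
#' @param config The `paradigm_config` the schedule was built from.
#' @return A `trial_schedule`.
#' @export
read_schedule <- function(path, config = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("trial", "condition", "color", "session", "trial_start_s",
            "observation_onset_s")
  if (!all(need %in% names(df)))
    stop("schema error in ", path, ": missing schedule columns")
  n_cond <- length(unique(df$condition))
  df$condition <- factor(df$condition, levels = condition_labels(n_cond))
  if (!is.null(config)) {
    attr(df, "config") <- config
    attr(df, "total_duration_s") <- nrow(df) *
      (config$pre_rest_s + config$cue_s + config$observation_s +
         config$post_rest_s) +
      (config$n_sessions - 1L) * config$inter_session_rest_s
  }
  class(df) <- c("trial_schedule", "data.frame")
  df
}

#' Write a raw recording to a native-format directory
#'
#' TSV matrices (EEG, EOG, one intensity matrix per wavelength), a schedule
#' TSV, and JSON metadata/ground truth.
#'
#' @param rec A `raw_recording`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "raw_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_schedule(rec$schedule, file.path(dir, "schedule.tsv"))
  .write_matrix_tsv(rec$eeg, file.path(dir, "eeg.tsv"))
  .write_matrix_tsv(rec$eog, file.path(dir, "eog.tsv"))
  for (w in seq_along(rec$fnirs$wavelengths))
    .write_matrix_tsv(rec$fnirs$intensity[, w, ],
                      file.path(dir, sprintf("fnirs_wl%d.tsv",
                                             rec$fnirs$wavelengths[w])))
  cfg <- .jsonify(unclass(rec$config))
  truth <- .jsonify(unclass(rec$truth))
  .write_meta(list(
    eeg_rate_hz = rec$eeg_rate_hz, eeg_channel_names = rec$eeg_channel_names,
    fnirs_dt_s = rec$fnirs$dt_s, wavelengths = rec$fnirs$wavelengths,
    fnirs_channel_names = rec$fnirs$channel_names,
    seed = rec$seed, config = cfg, truth = truth
  ), file.path(dir, "recording.json"), format = "raw_recording")
  invisible(dir)
}

#' Read a native-format raw recording directory
#' @param dir Directory written by [write_recording()].
#' @return A `raw_recording`.
#' @export
read_recording <- function(dir) {
  meta <- .read_meta(file.path(dir, "recording.json"), "raw_recording")
  cfg <- do.call(paradigm_config, meta$config[setdiff(names(meta$config),
                                                      character(0))])
  tr <- meta$truth
  truth <- ground_truth(
    effect_size = tr$effect_size,
    erp_amplitudes_uV = unlist(tr$erp_amplitudes_uV),
    erp_window_ms = unlist(tr$erp_window_ms),
    hbo_peak_amp = unlist(tr$hbo_peak_amp),
    hbo_peak_time_s = tr$hbo_peak_time_s, nvc_lag_ms = tr$nvc_lag_ms,
    lateralization_index = unlist(tr$lateralization_index),
    coupling_amp = tr$coupling_amp, r_hb = tr$r_hb,
    responsive_eeg = unlist(tr$responsive_eeg),
    n_communities = tr$n_communities,
    network_gain_eeg = tr$network_gain_eeg,
    network_gain_fnirs = tr$network_gain_fnirs,
    noise = tr$noise)
  schedule <- read_schedule(file.path(dir, "schedule.tsv"), cfg)
  eeg <- .read_matrix_tsv(file.path(dir, "eeg.tsv"))
  eog <- .read_matrix_tsv(file.path(dir, "eog.tsv"))
  wl <- meta$wavelengths
  nt <- ncol(eeg)
  first <- .read_matrix_tsv(file.path(dir, sprintf("fnirs_wl%d.tsv", wl[1])))
  intensity <- array(NA_real_, c(nrow(first), length(wl), ncol(first)))
  intensity[, 1, ] <- first
  for (w in seq_along(wl)[-1])
    intensity[, w, ] <- .read_matrix_tsv(file.path(dir,
                                          sprintf("fnirs_wl%d.tsv", wl[w])))
  structure(list(
    schedule = schedule, eeg = unname(eeg), eog = unname(eog),
    eeg_rate_hz = meta$eeg_rate_hz, eeg_channel_names = meta$eeg_channel_names,
    fnirs = list(intensity = intensity, wavelengths = wl,
                 dt_s = meta$fnirs_dt_s,
                 channel_names = meta$fnirs_channel_names),
    truth = truth, config = cfg, seed = meta$seed
  ), class = "raw_recording")
}

#' Write an epoch set to a native-format file pair
#'
#' Data as a (trials x channels) x time TSV plus JSON metadata at
#' `<prefix>.json`.
#'
#' @param epochs An `epoch_set`.
#' @param prefix Path prefix (writes `<prefix>.tsv` and `<prefix>.json`).
#' @return `prefix`, invisibly.
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  .write_matrix_tsv(flat, paste0(prefix, ".tsv"))
  .write_meta(list(
    n_trials = d[1], n_channels = d[2], n_samples = d[3],
    rate_hz = epochs$rate_hz, t0_offset_s = epochs$t0_offset_s,
    labels = as.character(epochs$labels), modality = epochs$modality,
    baseline_window_s = epochs$baseline_window_s,
    channel_names = epochs$channel_names
  ), paste0(prefix, ".json"), format = "epoch_set")
  invisible(prefix)
}

#' Read an epoch set written by [write_epochs()]
#' @param prefix Path prefix used at write time.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(prefix) {
  meta <- .read_meta(paste0(prefix, ".json"), "epoch_set")
  flat <- .read_matrix_tsv(paste0(prefix, ".tsv"))
  d <- c(meta$n_trials, meta$n_channels, meta$n_samples)
  if (nrow(flat) != d[1] * d[2] || ncol(flat) != d[3])
    stop("schema error: epoch data shape does not match metadata in ",
         prefix, ".json")
  arr <- aperm(array(t(flat), c(d[3], d[2], d[1])), c(3, 2, 1))
  epoch_set(arr, meta$rate_hz, meta$t0_offset_s, meta$labels,
            meta$modality, unlist(meta$baseline_window_s),
            meta$channel_names)
}

#' Write a connectivity network (TSV matrices + edge list + JSON)
#' @param net A `connectivity_network`.
#' @param prefix Path prefix.
#' @return `prefix`, invisibly.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "connectivity_network"))
  .write_matrix_tsv(net$weights, paste0(prefix, "_weights.tsv"))
  .write_matrix_tsv(net$binary, paste0(prefix, "_binary.tsv"))
  e <- which(upper.tri(net$binary) & net$binary > 0, arr.ind = TRUE)
  edges <- data.frame(from = net$node_ids[e[, 1]], to = net$node_ids[e[, 2]],
                      z = net$weights[e])
  data.table::fwrite(edges, paste0(prefix, "_edges.tsv"), sep = "\t")
  .write_meta(list(density = net$density, node_ids = net$node_ids,
                   modality = net$modality),
              paste0(prefix, ".json"), format = "connectivity_network")
  invisible(prefix)
}

#' Read a connectivity network written by [write_network()]
#' @param prefix Path prefix.
#' @return A `connectivity_network`.
#' @export
read_network <- function(prefix) {
  meta <- .read_meta(paste0(prefix, ".json"), "connectivity_network")
  structure(list(
    weights = unname(.read_matrix_tsv(paste0(prefix, "_weights.tsv"))),
    binary = unname(.read_matrix_tsv(paste0(prefix, "_binary.tsv"))),
    density = meta$density, node_ids = meta$node_ids,
    modality = meta$modality
  ), class = "connectivity_network")
}

#' Write a nodal feature table (TSV + JSON)
#' @param ft A `feature_table`.
#' @param prefix Path prefix.
#' @return `prefix`, invisibly.
#' @export
write_feature_table <- function(ft, prefix) {
  stopifnot(inherits(ft, "feature_table"))
  data.table::fwrite(data.table::as.data.table(ft$features),
                     paste0(prefix, ".tsv"), sep = "\t")
  .write_meta(list(labels = as.character(ft$labels), modality = ft$modality,
                   density = ft$density, window_s = ft$window_s,
                   columns = colnames(ft$features)),
              paste0(prefix, ".json"), format = "feature_table")
  invisible(prefix)
}

#' Read a nodal feature table written by [write_feature_table()]
#' @param prefix Path prefix.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(prefix) {
  meta <- .read_meta(paste0(prefix, ".json"), "feature_table")
  feats <- .read_matrix_tsv(paste0(prefix, ".tsv"))
  colnames(feats) <- meta$columns
  if (nrow(feats) != length(meta$labels))
    stop("schema error: feature rows do not match labels in ", prefix,
         ".json")
  structure(list(features = feats, labels = factor(meta$labels),
                 modality = meta$modality, density = meta$density,
                 window_s = unlist(meta$window_s)),
            class = "feature_table")
}
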