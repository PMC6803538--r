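#' Construct an epoch set
#'
#' Container for per-trial, per-channel time series of one modality, time
#' locked to observation onset (time 0).
#'
#' @param data trials x channels x time array.
#' @param rate_hz Sampling rate (Hz).
#' @param t0_offset_s Time (s) of the first sample relative to observation
#'   onset (negative: epoch starts before onset).
#' @param labels Per-trial condition labels (factor or character).
#' @param modality One of `"EEG"`, `"HbO"`, `"HbR"`, `"HbT"`.
#' @param baseline_window_s Two-element baseline interval (s).
#' @param channel_names Optional channel names.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, rate_hz, t0_offset_s, labels,
                      modality = c("EEG", "HbO", "HbR", "HbT"),
                      baseline_window_s = NULL, channel_names = NULL) {
  modality <- match.arg(modality)
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == length(labels),
            rate_hz > 0)
  if (!is.null(channel_names))
    stopifnot(length(channel_names) == dim(data)[2])
  structure(list(
    data = data, rate_hz = rate_hz, t0_offset_s = t0_offset_s,
    labels = if (is.factor(labels)) labels else factor(labels),
    modality = modality,
    baseline_window_s = baseline_window_s,
    channel_names = channel_names
  ), class = "epoch_set")
}

#' Sample times of an epoch set
#' @param epochs An `epoch_set`.
#' @return Numeric vector of times (s) relative to observation onset.
#' @export
epoch_times <- function(epochs) {
  epochs$t0_offset_s + (seq_len(dim(epochs$data)[3]) - 1L) / epochs$rate_hz
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s: %d trials x %d channels x %d samples @ %.4g Hz\n",
              x$modality, d[1], d[2], d[3], x$rate_hz))
  cat(sprintf("  window [%.3f, %.3f] s; conditions: %s\n",
              x$t0_offset_s, max(epoch_times(x)),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

#' Cut continuous data into trials aligned to observation onset
#'
#' Extracts one epoch per scheduled trial from a continuous channels x time
#' matrix.  The epoch spans `window_s` relative to each trial's observation
#' onset and contains `floor((window_s[2] - window_s[1]) * rate_hz) + 1`
#' samples (endpoint-inclusive on the sampling grid).
#'
#' @param continuous channels x time matrix.
#' @param rate_hz Sampling rate of `continuous`.
#' @param schedule A [build_schedule()] trial schedule (or any data.frame
#'   with `condition` and `observation_onset_s`).
#' @param window_s Two-element epoch window (s) relative to onset.
#' @param modality,baseline_window_s,channel_names Passed to [epoch_set()].
#' @return An `epoch_set`.
#' @export
epoch_extract <- function(continuous, rate_hz, schedule, window_s,
                          modality = "EEG", baseline_window_s = NULL,
                          channel_names = NULL) {
  stopifnot(is.matrix(continuous), window_s[1] < window_s[2])
  n_trials <- nrow(schedule)
  nt <- ncol(continuous)
  n_samp <- floor((window_s[2] - window_s[1]) * rate_hz + 1e-9) + 1L
  if (n_trials == 0L) {
    return(epoch_set(array(0, c(0L, nrow(continuous), n_samp)), rate_hz,
                     window_s[1], character(0), modality, baseline_window_s,
                     channel_names))
  }
  onset_idx <- round(schedule$observation_onset_s * rate_hz) + 1L
  start <- onset_idx + round(window_s[1] * rate_hz)
  end <- start + n_samp - 1L
  oob <- which(start < 1L | end > nt)
  if (length(oob))
    stop("epoch window out of recording bounds for trial(s) ",
         paste(oob, collapse = ", "))
  out <- array(0, c(n_trials, nrow(continuous), n_samp))
  for (i in seq_len(n_trials))
    out[i, , ] <- continuous[, start[i]:end[i]]
  epoch_set(out, rate_hz, t0_offset_s = (start[1] - onset_idx[1]) / rate_hz,
            labels = schedule$condition, modality = modality,
            baseline_window_s = baseline_window_s,
            channel_names = channel_names)
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean over the baseline window, so
#' that the baseline mean becomes exactly zero.  Default windows follow the
#' analysis convention: (-0.7, -0.5) s for EEG and (-6.5, -0.5) s for the
#' hemoglobin modalities.
#'
#' @param epochs An `epoch_set`.
#' @param baseline_window_s Two-element window (s); default: the epoch set's
#'   own `baseline_window_s`, else the modality convention above.
#' @return Baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline_window_s = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  bw <- baseline_window_s %||% epochs$baseline_window_s %||%
    (if (epochs$modality == "EEG") c(-0.7, -0.5) else c(-6.5, -0.5))
  t <- epoch_times(epochs)
  idx <- which(t >= bw[1] - 1e-9 & t <= bw[2] + 1e-9)
  if (!length(idx) || bw[1] < min(t) - 1e-9 || bw[2] > max(t) + 1e-9)
    stop("baseline window [", bw[1], ", ", bw[2], "] s outside epoch [",
         min(t), ", ", max(t), "] s")
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over 3rd dim
  epochs$baseline_window_s <- bw
  epochs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Window mean per trial and channel
#'
#' Mean amplitude over a time window, the per-trial summary used by the
#' channelwise statistics.
#'
#' @param epochs An `epoch_set`.
#' @param window_s Two-element window (s) relative to onset.
#' @return trials x channels matrix.
#' @export
window_mean <- function(epochs, window_s) {
  t <- epoch_times(epochs)
  idx <- which(t >= window_s[1] - 1e-9 & t <= window_s[2] + 1e-9)
  if (!length(idx)) stop("window contains no samples")
  apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
}
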