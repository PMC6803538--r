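#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, applied per row when
#' given a channels x time matrix.  Zero phase is used throughout the
#' pipeline so that filtering does not shift the latency of the 350-400 ms
#' evoked window.  The effective magnitude response is the squared
#' Butterworth response: monotone (no ripple) in the passband, and for the
#' default 4th-order design at least 20 dB down one octave outside the band.
#'
#' @param x Numeric vector or channels x time matrix.
#' @param rate_hz Sampling rate.
#' @param low_hz,high_hz Band edges; `0 < low < high < rate/2`.
#' @param order Filter order (default 4; use 2 for very low fNIRS bands,
#'   where high-order polynomial coefficients become ill-conditioned).
#' @return Filtered data, same shape as `x`.
#' @export
bandpass_filter <- function(x, rate_hz, low_hz, high_hz, order = 4L) {
  nyq <- rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("invalid band: need 0 < low_hz < high_hz < rate_hz/2 (Nyquist ",
         nyq, " Hz)")
  flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  .apply_filtfilt(x, flt)
}

#' Zero-phase notch filter
#'
#' Second-order Butterworth band-stop around `notch_hz` (default width
#' 2 Hz), applied forward-backward.  Attenuates the notch frequency by well
#' over 20 dB while leaving frequencies a few Hz away essentially untouched.
#'
#' @param x Numeric vector or channels x time matrix.
#' @param rate_hz Sampling rate.
#' @param notch_hz Frequency to suppress (powerline; default 50 Hz).
#' @param width_hz Stop-band width (default 2 Hz).
#' @param order Filter order (default 2).
#' @return Filtered data, same shape as `x`.
#' @export
notch_filter <- function(x, rate_hz, notch_hz = 50, width_hz = 2, order = 2L) {
  nyq <- rate_hz / 2
  if (notch_hz >= nyq) stop("notch_hz must be below the Nyquist frequency")
  if (notch_hz - width_hz / 2 <= 0) stop("notch band extends below 0 Hz")
  flt <- signal::butter(order,
                        c(notch_hz - width_hz / 2, notch_hz + width_hz / 2) / nyq,
                        type = "stop")
  .apply_filtfilt(x, flt)
}

.apply_filtfilt <- function(x, flt) {
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- signal::filtfilt(flt, x[i, ])
    out
  } else {
    signal::filtfilt(flt, as.numeric(x))
  }
}

#' Regression-based ocular artifact removal
#'
#' Removes eye-movement and blink artifacts by subtracting, from every EEG
#' channel, its least-squares projection onto the (mean-centered) EOG
#' channels.  With an exactly linear contamination `eeg = clean + B %*% eog`
#' and EOG orthogonal to the clean signal, the mixing `B` is identified
#' exactly and the clean data recovered.  Near-constant EOG channels carry
#' no artifact information and are skipped with a diagnostic.
#'
#' @param eeg channels x time matrix.
#' @param eog eog-channels x time matrix (same number of columns).
#' @param tol Variance below which an EOG channel is considered constant.
#' @return EEG matrix with the EOG projection removed; the fitted mixing
#'   matrix is attached as attribute `"mixing"`.
#' @export
remove_eog <- function(eeg, eog, tol = 1e-12) {
  if (is.null(dim(eog))) eog <- matrix(eog, nrow = 1L)
  stopifnot(ncol(eeg) == ncol(eog))
  v <- apply(eog, 1L, stats::var)
  keep <- which(v > tol)
  if (!length(keep)) {
    message("remove_eog: all EOG channels are constant; EEG returned unchanged")
    attr(eeg, "mixing") <- matrix(0, nrow(eeg), nrow(eog))
    return(eeg)
  }
  if (length(keep) < nrow(eog))
    message("remove_eog: skipping constant EOG channel(s) ",
            paste(setdiff(seq_len(nrow(eog)), keep), collapse = ", "))
  E <- eog[keep, , drop = FALSE]
  E <- E - rowMeans(E)
  B <- eeg %*% t(E) %*% solve(E %*% t(E))
  out <- eeg - B %*% E
  mix <- matrix(0, nrow(eeg), nrow(eog))
  mix[, keep] <- B
  attr(out, "mixing") <- mix
  out
}
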