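#' Preprocess a raw bimodal recording into analysis-ready epochs
#'
#' The standard chain for both modalities:
#' EEG — notch at the powerline frequency, 1-30 Hz zero-phase band-pass,
#' regression-based EOG removal, epoching to `eeg_window_s` around each
#' observation onset, baseline correction over (-0.7, -0.5) s.
#' fNIRS — modified Beer-Lambert conversion of the raw three-wavelength
#' intensities to HbO/HbR/HbT concentration changes, 0.01-0.1 Hz zero-phase
#' band-pass (2nd order), epoching to `fnirs_window_s`, baseline correction
#' over (-6.5, -0.5) s.
#'
#' @param rec A `raw_recording` from [generate_subject()] (or the native
#'   reader).
#' @param eeg_band_hz EEG analysis band (default `c(1, 30)`).
#' @param notch_hz Powerline frequency (default 50; `NA` disables).
#' @param fnirs_band_hz fNIRS band (default `c(0.01, 0.1)`).
#' @param eeg_window_s,fnirs_window_s Epoch windows (defaults
#'   `c(-0.7, 3.5)` and `c(-6.5, 5.5)`).
#' @param eeg_baseline_s,fnirs_baseline_s Baseline windows (defaults
#'   `c(-0.7, -0.5)` and `c(-6.5, -0.5)`).
#' @param remove_ocular Apply [remove_eog()] (default TRUE).
#' @param hb_modalities Hemoglobin modalities to epoch (default all three;
#'   restrict to `"hbo"` when only oxyhemoglobin is analyzed).
#' @return Named list of baseline-corrected `epoch_set`s:
#'   `eeg` plus the requested hemoglobin modalities.
#' @export
preprocess_subject <- function(rec,
                               eeg_band_hz = c(1, 30), notch_hz = 50,
                               fnirs_band_hz = c(0.01, 0.1),
                               eeg_window_s = c(-0.7, 3.5),
                               fnirs_window_s = c(-6.5, 5.5),
                               eeg_baseline_s = c(-0.7, -0.5),
                               fnirs_baseline_s = c(-6.5, -0.5),
                               remove_ocular = TRUE,
                               hb_modalities = c("hbo", "hbr", "hbt")) {
  stopifnot(inherits(rec, "raw_recording"))
  rate <- rec$eeg_rate_hz
  eeg <- rec$eeg
  if (!is.na(notch_hz) && notch_hz < rate / 2)
    eeg <- notch_filter(eeg, rate, notch_hz)
  eeg <- bandpass_filter(eeg, rate, eeg_band_hz[1], eeg_band_hz[2])
  if (remove_ocular) {
    eog <- bandpass_filter(rec$eog, rate, eeg_band_hz[1], eeg_band_hz[2])
    eeg <- remove_eog(eeg, eog)
  }
  eeg_ep <- epoch_extract(eeg, rate, rec$schedule, eeg_window_s,
                          modality = "EEG",
                          baseline_window_s = eeg_baseline_s,
                          channel_names = rec$eeg_channel_names)
  eeg_ep <- baseline_correct(eeg_ep)

  hb <- mbll_convert(rec$fnirs$intensity)
  f_rate <- 1 / rec$fnirs$dt_s
  out <- list(eeg = eeg_ep)
  for (mod in match.arg(hb_modalities, several.ok = TRUE)) {
    x <- bandpass_filter(hb[[mod]], f_rate, fnirs_band_hz[1],
                         fnirs_band_hz[2], order = 2L)
    ep <- epoch_extract(x, f_rate, rec$schedule, fnirs_window_s,
                        modality = c(hbo = "HbO", hbr = "HbR",
                                     hbt = "HbT")[[mod]],
                        baseline_window_s = fnirs_baseline_s,
                        channel_names = rec$fnirs$channel_names)
    out[[mod]] <- baseline_correct(ep)
  }
  out
}
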