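#' Ground truth for synthetic bimodal recordings
#'
#' Collects every planted quantity the generator embeds in a synthetic
#' subject, so downstream analyses can be validated against known answers:
#' condition-ordered evoked amplitudes in the 350-400 ms window, an
#' oxyhemoglobin response peaking near 3 s with condition-ordered amplitude
#' and left-hemisphere lateralization, a neurovascular coupling lag between
#' the electrical and hemodynamic signatures, and condition-specific
#' community structure in the inter-channel correlations of each modality.
#'
#' The two modalities carry *complementary* network structure: the EEG
#' community assignment and per-channel participation weights separate
#' grasp-to-drink (Sd) from the other two conditions, while the fNIRS
#' assignment (with weaker coupling gain) separates the ambiguous-touch
#' condition (Su).  Condition differences modulate both which channels form
#' communities and how strongly each channel participates (nodal metrics
#' only see the latter: isomorphic relabelings leave per-node statistics
#' unchanged).  Neither modality alone can resolve all three intentions
#' from network topology; their fusion can.
#'
#' @param effect_size Nonnegative scalar scaling all condition differences;
#'   0 plants identical conditions (null data).
#' @param erp_amplitudes_uV Named per-condition amplitude (uV) of the
#'   350-400 ms evoked component on responsive channels.  Default
#'   `Su = 2`, `Sm = 2 + 3*effect_size`, `Sd = 2 + 6*effect_size`.
#' @param erp_window_ms Window of the intention component (default c(350, 400)).
#' @param hbo_peak_amp Named per-condition peak HbO amplitude in mM*mm.
#'   Default `Su = 0.02`, `Sm = 0.02 + 0.015*effect_size`,
#'   `Sd = 0.02 + 0.03*effect_size`.
#' @param hbo_peak_time_s Post-onset time of the HbO response peak (default 3).
#' @param nvc_lag_ms Neurovascular lag: the hemodynamic copy of the evoked
#'   waveform trails the EEG by this many ms (default 1700).
#' @param lateralization_index Named per-condition signed scalar; left
#'   channels are scaled by `1 + LI`, right by `1 - LI`.
#' @param coupling_amp HbO amplitude (mM*mm) of the lag-shifted copy of the
#'   evoked waveform that carries the neurovascular coupling (default 0.02).
#' @param r_hb HbR/HbO ratio (default -1/3).
#' @param responsive_eeg Indices of EEG channels carrying the intention
#'   component (default [responsive_eeg_channels()], 43 channels).
#' @param n_communities Number of latent blocks in the planted connectivity
#'   structure (default 4).
#' @param network_gain_eeg,network_gain_fnirs Amplitude of the shared
#'   within-community latent signal (uV for EEG; mM*mm for fNIRS).
#' @param noise Named list of noise amplitudes; see Details.
#' @details Noise defaults (overridable element-wise through `noise`):
#'   `eeg_background_uV = 5` (1/f background, alpha = 1),
#'   `eeg_alpha_uV = 2` (10 Hz rhythm), `eeg_white_uV = 1`,
#'   `eeg_spatial_mix = 0.3` (shared-noise fraction),
#'   `cue_vep_uV = -5` (posterior cue-locked deflection at -500 ms),
#'   `blink_rate_hz = 0.1`, `blink_amp_uV = 200`,
#'   `fnirs_mayer = 0.008`, `fnirs_cardiac = 0.005`, `fnirs_drift = 0.004`,
#'   `fnirs_white = 0.003` (all mM*mm).  Setting all noise terms to 0 yields
#'   deterministic clean signals used by the recovery oracles.
#' @return A `ground_truth` object (list).
#' @export
ground_truth <- function(effect_size = 1,
                         erp_amplitudes_uV = NULL,
                         erp_window_ms = c(350, 400),
                         hbo_peak_amp = NULL,
                         hbo_peak_time_s = 3,
                         nvc_lag_ms = 1700,
                         lateralization_index = c(Sd = 0.3, Sm = 0.2, Su = 0.1),
                         coupling_amp = 0.02,
                         r_hb = -1 / 3,
                         responsive_eeg = responsive_eeg_channels(),
                         n_communities = 4L,
                         network_gain_eeg = 3,
                         network_gain_fnirs = 0.02,
                         noise = list()) {
  stopifnot(effect_size >= 0, nvc_lag_ms >= 0, hbo_peak_time_s > 0)
  if (is.null(erp_amplitudes_uV))
    erp_amplitudes_uV <- c(Sd = 2 + 6 * effect_size, Sm = 2 + 3 * effect_size,
                           Su = 2)
  if (is.null(hbo_peak_amp))
    hbo_peak_amp <- c(Sd = 0.02 + 0.03 * effect_size,
                      Sm = 0.02 + 0.015 * effect_size, Su = 0.02)
  if (effect_size > 0) {
    stopifnot(erp_amplitudes_uV["Sd"] > erp_amplitudes_uV["Sm"],
              erp_amplitudes_uV["Sm"] > erp_amplitudes_uV["Su"],
              hbo_peak_amp["Sd"] > hbo_peak_amp["Sm"],
              hbo_peak_amp["Sm"] > hbo_peak_amp["Su"])
  }
  defaults <- list(
    eeg_background_uV = 5, eeg_alpha_uV = 2, eeg_white_uV = 1,
    eeg_spatial_mix = 0.3, cue_vep_uV = -5,
    blink_rate_hz = 0.1, blink_amp_uV = 200,
    fnirs_mayer = 0.008, fnirs_cardiac = 0.005, fnirs_drift = 0.004,
    fnirs_white = 0.003
  )
  unknown <- setdiff(names(noise), names(defaults))
  if (length(unknown)) stop("unknown noise terms: ", paste(unknown, collapse = ", "))
  defaults[names(noise)] <- noise

  structure(list(
    effect_size = effect_size,
    conditions = c("Sd", "Sm", "Su"),
    erp_amplitudes_uV = erp_amplitudes_uV,
    erp_window_ms = erp_window_ms,
    hbo_peak_amp = hbo_peak_amp,
    hbo_peak_time_s = hbo_peak_time_s,
    nvc_lag_ms = nvc_lag_ms,
    lateralization_index = lateralization_index,
    coupling_amp = coupling_amp,
    r_hb = r_hb,
    responsive_eeg = responsive_eeg,
    n_communities = as.integer(n_communities),
    network_gain_eeg = network_gain_eeg,
    network_gain_fnirs = network_gain_fnirs,
    network_communities = if (effect_size > 0) list(
      eeg = .community_maps(64L, n_communities, shared = c("Sm", "Su")),
      fnirs = .community_maps(48L, n_communities, shared = c("Sd", "Sm"))
    ) else list(  # null data: identical latent structure in every condition
      eeg = .community_maps(64L, n_communities, shared = c("Sd", "Sm", "Su")),
      fnirs = .community_maps(48L, n_communities, shared = c("Sd", "Sm", "Su"))
    ),
    network_participation = if (effect_size > 0) list(
      eeg = .participation_weights(64L, distinct = "Sd"),
      fnirs = .participation_weights(48L, distinct = "Su")
    ) else list(
      eeg = .participation_weights(64L, distinct = NULL),
      fnirs = .participation_weights(48L, distinct = NULL)
    ),
    noise = defaults
  ), class = "ground_truth")
}

# Condition -> per-channel participation weights in the latent connectivity
# signal.  A relabeled partition alone is invisible to nodal graph metrics
# (isomorphic graphs have identical per-node statistics), so the planted
# condition difference also modulates HOW STRONGLY each channel couples to
# its community: in the `distinct` condition one half of the channels is
# strongly coupled (weight 1) and the other weakly (0.25); in the remaining
# conditions the roles are swapped.  That changes each node's degree,
# clustering and centrality between conditions.
.participation_weights <- function(n_channels, distinct) {
  conds <- c("Sd", "Sm", "Su")
  half_a <- ifelse(seq_len(n_channels) <= n_channels / 2, 1, 0.25)
  half_b <- ifelse(seq_len(n_channels) <= n_channels / 2, 0.25, 1)
  w <- lapply(conds, function(cond) {
    if (is.null(distinct)) half_a
    else if (cond == distinct) half_a else half_b
  })
  names(w) <- conds
  w
}

# Condition -> channel-block maps.  Conditions listed in `shared` receive the
# same (interleaved) partition; the remaining condition gets a contiguous
# partition, so its correlation structure is maximally distinct.
.community_maps <- function(n_channels, n_comm, shared) {
  conds <- c("Sd", "Sm", "Su")
  interleaved <- ((seq_len(n_channels) - 1L) %% n_comm) + 1L
  contiguous <- ((seq_len(n_channels) - 1L) %/% ceiling(n_channels / n_comm)) + 1L
  maps <- lapply(conds, function(cond) {
    if (cond %in% shared) interleaved else contiguous
  })
  names(maps) <- conds
  maps
}

#' Deterministic evoked-response template of one trial
#'
#' The noise-free EEG waveform planted on a responsive channel, sampled at
#' `rate_hz`, over `window_s` relative to observation onset: a cue-locked
#' negative deflection at -500 ms (visual evoked response to the cue,
#' amplitude `cue_amp_uV`, posterior channels only in the generator), a small
#' negative component near 200 ms, and the condition-scaled positive
#' intention component centered in the 350-400 ms window.
#'
#' @param amp_uV Amplitude of the intention component.
#' @param window_s Time window (s) relative to observation onset.
#' @param rate_hz Sampling rate.
#' @param cue_amp_uV Amplitude of the cue-locked deflection (default 0:
#'   the generator adds the cue response separately, on posterior channels).
#' @param erp_window_ms Center window of the intention component.
#' @return list(time_s, values) of the template.
#' @export
erp_template <- function(amp_uV, window_s = c(-0.7, 3.5), rate_hz = 1000,
                         cue_amp_uV = 0, erp_window_ms = c(350, 400)) {
  t <- seq(window_s[1], window_s[2], by = 1 / rate_hz)
  center <- mean(erp_window_ms) / 1000
  g <- function(mu, sd) exp(-((t - mu)^2) / (2 * sd^2))
  # visual evoked complex (C1/P1-N1-P2-N2 lobes at irregular latencies,
  # then the condition-scaled late positive component centered in
  # erp_window_ms); the alternating multi-lobe shape gives the template a
  # sharp autocorrelation, as real evoked complexes have
  v <- amp_uV * (0.35 * g(0.075, 0.012) - 0.45 * g(0.145, 0.015) +
                 0.40 * g(0.210, 0.015) - 0.35 * g(0.300, 0.014) +
                 g(center, 0.020))
  if (cue_amp_uV != 0)
    v <- v + cue_amp_uV * exp(-((t + 0.5)^2) / (2 * 0.03^2))
  list(time_s = t, values = v)
}
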