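# Synthetic bimodal recording generator.
#
# All randomness is driven by an explicit seed; .Random.seed is saved and
# restored so generation never perturbs the caller's RNG stream.

# 1/f^alpha noise via spectral shaping, unit variance
.pink_noise <- function(n, alpha = 1) {
  if (n < 2L) return(stats::rnorm(n))
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  sc <- 1 / f^(alpha / 2)
  x <- Re(stats::fft(X * sc, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# moving-average smoothed white noise, unit variance, length n
.smooth_noise <- function(n, width = 25L) {
  z <- stats::filter(stats::rnorm(n + 2L * width), rep(1 / width, width),
                     sides = 2L)
  z <- z[(width + 1L):(width + n)]
  z[is.na(z)] <- 0
  s <- stats::sd(z)
  if (s > 0) z / s else z
}

#' Generate synthetic EEG and EOG for one subject run
#'
#' Produces a continuous 64-channel EEG recording (uV) at the configured
#' rate plus two bipolar EOG channels, following the planted ground truth:
#' spatially mixed 1/f background with a 10 Hz rhythm and white sensor
#' noise; per trial, a cue-locked negative deflection 500 ms before
#' observation onset on posterior channels, the condition-scaled intention
#' component spanning the 350-400 ms window on the responsive channels, and
#' condition-specific shared latent signals over the 0-3.5 s observation
#' window that induce the planted community structure in inter-channel
#' correlations.  EOG blinks leak into frontal channels through a fixed
#' linear mixing (attached as attribute `"eog_mixing"`), so that
#' regression-based removal is exactly identifiable.
#'
#' @param schedule A [build_schedule()] schedule.
#' @param truth A [ground_truth()].
#' @param seed Integer seed.
#' @return list(eeg = 64 x time matrix, eog = 2 x time matrix,
#'   rate_hz, channel_names); `eeg` carries the `"eog_mixing"` attribute.
#' @export
generate_eeg <- function(schedule, truth, seed = 1L) {
  cfg <- attr(schedule, "config")
  stopifnot(!is.null(cfg), inherits(truth, "ground_truth"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  rate <- cfg$eeg_rate_hz
  total <- attr(schedule, "total_duration_s")
  n <- round(total * rate)
  layout <- eeg_layout_64()
  nch <- nrow(layout)
  nz <- truth$noise

  eeg <- matrix(0, nch, n)
  if (nz$eeg_background_uV > 0) {
    common <- .pink_noise(n)
    m <- nz$eeg_spatial_mix
    for (ch in seq_len(nch))
      eeg[ch, ] <- nz$eeg_background_uV *
        (sqrt(1 - m) * .pink_noise(n) + sqrt(m) * common)
  }
  tim <- (seq_len(n) - 1L) / rate
  if (nz$eeg_alpha_uV > 0) {
    # posterior-dominant ~10 Hz rhythm; the phase diffuses (coherence time
    # on the order of a second), as real alpha does, so the rhythm does not
    # impose a fixed inter-channel correlation pattern
    gain <- nz$eeg_alpha_uV * (0.6 + 0.4 * pmax(0, -layout$y))
    for (ch in seq_len(nch)) {
      drift <- cumsum(stats::rnorm(n, sd = sqrt(2 * pi / rate)))
      eeg[ch, ] <- eeg[ch, ] + gain[ch] *
        sin(2 * pi * 10 * tim + stats::runif(1, 0, 2 * pi) + drift)
    }
  }
  if (nz$eeg_white_uV > 0)
    eeg <- eeg + nz$eeg_white_uV * matrix(stats::rnorm(nch * n), nch, n)

  # trial-locked components
  posterior <- which(layout$y < -0.2)
  resp <- truth$responsive_eeg
  amps <- truth$erp_amplitudes_uV
  comm <- truth$network_communities$eeg
  obs_len <- round(cfg$observation_s * rate)
  tmpl <- erp_template(1, window_s = c(-0.7, 3.5), rate_hz = rate,
                       erp_window_ms = truth$erp_window_ms)
  cue_shape <- exp(-((tmpl$time_s + 0.5)^2) / (2 * 0.03^2))
  onset_idx <- round(schedule$observation_onset_s * rate) + 1L
  rel0 <- round(-0.7 * rate)
  for (i in seq_len(nrow(schedule))) {
    cond <- as.character(schedule$condition[i])
    idx <- onset_idx[i] + rel0 + seq_along(tmpl$time_s) - 1L
    ok <- idx >= 1L & idx <= n
    eeg[posterior, idx[ok]] <- eeg[posterior, idx[ok]] +
      rep(nz$cue_vep_uV * cue_shape[ok], each = length(posterior))
    eeg[resp, idx[ok]] <- eeg[resp, idx[ok]] +
      rep(amps[[cond]] * tmpl$values[ok], each = length(resp))
    # shared latent signals inducing condition-specific connectivity
    if (truth$network_gain_eeg > 0 && truth$effect_size >= 0) {
      oidx <- onset_idx[i]:min(n, onset_idx[i] + obs_len - 1L)
      map <- comm[[cond]]
      Z <- t(vapply(seq_len(truth$n_communities),
                    function(b) .smooth_noise(length(oidx), width = 40L),
                    numeric(length(oidx))))
      w <- truth$network_participation$eeg[[cond]]
      eeg[, oidx] <- eeg[, oidx] +
        truth$network_gain_eeg * (w * Z[map, , drop = FALSE])
    }
  }

  # ocular source (blink transients); only the source leaks into EEG, the
  # recorded EOG additionally carries its own sensor noise
  eog_src <- matrix(0, 2L, n)
  n_blinks <- stats::rpois(1L, nz$blink_rate_hz * total)
  if (n_blinks > 0 && nz$blink_amp_uV > 0) {
    bt <- sort(stats::runif(n_blinks, 0, total))
    bw <- round(0.05 * rate)  # 50 ms gaussian sd
    for (b in bt) {
      c0 <- round(b * rate) + 1L
      idx <- max(1L, c0 - 4L * bw):min(n, c0 + 4L * bw)
      shape <- exp(-((idx - c0)^2) / (2 * bw^2))
      a <- nz$blink_amp_uV * stats::runif(1, 0.8, 1.2)
      eog_src[1L, idx] <- eog_src[1L, idx] + a * shape
      eog_src[2L, idx] <- eog_src[2L, idx] +
        0.25 * a * shape * sample(c(-1, 1), 1L)
    }
  }
  # fixed, deterministic leakage coefficients (strongest frontally)
  B <- cbind(0.15 * pmax(0, layout$y - 0.1) / 0.85,
             0.06 * layout$x * pmax(0, layout$y))
  eeg <- eeg + B %*% eog_src
  eog <- eog_src
  if (nz$blink_amp_uV > 0)
    eog <- eog + matrix(stats::rnorm(2L * n, sd = 2), 2L, n)
  attr(eeg, "eog_mixing") <- B
  list(eeg = eeg, eog = eog, rate_hz = rate, channel_names = layout$name)
}

#' Generate synthetic fNIRS light intensities for one subject run
#'
#' Builds planted oxy/deoxyhemoglobin concentration time courses (mM*mm) on
#' the 48-channel parietal montage and converts them to strictly positive
#' three-wavelength (780/805/830 nm) light intensities through the forward
#' Beer-Lambert model, the exact inverse of [mbll_convert()].  Per trial,
#' the HbO course is the condition-scaled hemodynamic response
#' ([hbo_response()]: observation boxcar convolved with a double-gamma
#' kernel shifted by the neurovascular lag, peaking at the configured
#' post-onset time), a lag-shifted copy of the evoked waveform carrying the
#' neurovascular coupling, hemisphere scaling by the lateralization index,
#' and shared latent signals inducing the fNIRS community structure.
#' Physiological noise: a ~0.1 Hz Mayer wave, ~1 Hz cardiac pulsation, slow
#' drift and white noise.  HbR is the planted ratio `r_hb` times HbO.
#'
#' @param schedule A [build_schedule()] schedule.
#' @param truth A [ground_truth()].
#' @param seed Integer seed.
#' @return list(intensity = 48 x 3 x time array, wavelengths, dt_s,
#'   channel_names, planted = list(hbo, hbr) of the concentration courses).
#' @export
generate_fnirs <- function(schedule, truth, seed = 1L) {
  cfg <- attr(schedule, "config")
  stopifnot(!is.null(cfg), inherits(truth, "ground_truth"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  dt <- cfg$fnirs_dt_s
  total <- attr(schedule, "total_duration_s")
  n <- floor(total / dt) + 1L
  layout <- fnirs_layout_48()
  nch <- nrow(layout)
  nz <- truth$noise
  lag_s <- truth$nvc_lag_ms / 1000
  tim <- (seq_len(n) - 1L) * dt

  # per-channel spatial gain: gaussian profile around each patch center
  cx <- ifelse(layout$hemisphere == "left", -0.5, 0.5)
  gain_sp <- 0.6 + 0.4 * exp(-(((layout$x - cx)^2 + (layout$y + 0.2)^2) / 0.5))

  # unit-peak response template, evaluated by interpolation per trial
  tail_s <- lag_s + cfg$observation_s + 6 * truth$hbo_peak_time_s
  fine <- seq(0, tail_s, by = 0.005)
  rtmpl <- stats::approxfun(fine,
    hbo_response(fine, peak_time_s = truth$hbo_peak_time_s, lag_s = lag_s,
                 duration_s = cfg$observation_s),
    yleft = 0, yright = 0)
  # lag-shifted copy of the evoked shape (neurovascular coupling carrier)
  etm <- erp_template(1, window_s = c(0, 0.7), rate_hz = 1000,
                      erp_window_ms = truth$erp_window_ms)
  ctmpl <- stats::approxfun(etm$time_s + lag_s, etm$values,
                            yleft = 0, yright = 0)

  hbo <- matrix(0, nch, n)
  amps <- truth$hbo_peak_amp
  li <- truth$lateralization_index
  comm <- truth$network_communities$fnirs
  obs_len <- max(1L, round(cfg$observation_s / dt))
  for (i in seq_len(nrow(schedule))) {
    cond <- as.character(schedule$condition[i])
    onset <- schedule$observation_onset_s[i]
    i0 <- round(onset / dt) + 1L
    idx <- i0:min(n, i0 + ceiling(tail_s / dt))
    rel <- tim[idx] - onset
    # coupling carrier has the same amplitude in every condition: the
    # condition ordering lives in the hemodynamic response amplitude, while
    # the lag-locked copy of the evoked shape is equally strong throughout
    wave <- amps[[cond]] * rtmpl(rel) + truth$coupling_amp * ctmpl(rel)
    hemi <- ifelse(layout$hemisphere == "left",
                   1 + li[[cond]], 1 - li[[cond]])
    hbo[, idx] <- hbo[, idx] + (gain_sp * hemi) %o% wave
    if (truth$network_gain_fnirs > 0) {
      oidx <- i0:min(n, i0 + obs_len - 1L)
      map <- comm[[cond]]
      # slow (vasomotion-band) trial-varying components: hemodynamic
      # connectivity fluctuations live below ~0.1 Hz, so the planted
      # signal survives the narrow-band analysis filter
      u <- seq(0, 1, length.out = length(oidx))
      basis <- rbind(sin(pi * u), u - 0.5)
      Z <- matrix(stats::rnorm(truth$n_communities * 2L),
                  truth$n_communities, 2L) %*% basis
      Z <- Z / max(1e-12, stats::sd(as.vector(Z)))
      w <- truth$network_participation$fnirs[[cond]]
      hbo[, oidx] <- hbo[, oidx] +
        truth$network_gain_fnirs * (w * Z[map, , drop = FALSE])
    }
  }

  if (nz$fnirs_mayer > 0 || nz$fnirs_cardiac > 0 || nz$fnirs_drift > 0 ||
      nz$fnirs_white > 0) {
    for (ch in seq_len(nch)) {
      ph <- stats::runif(4L, 0, 2 * pi)
      fm <- stats::runif(1, 0.08, 0.12); fc <- stats::runif(1, 0.9, 1.2)
      x <- nz$fnirs_mayer * sin(2 * pi * fm * tim + ph[1]) +
        nz$fnirs_cardiac * sin(2 * pi * fc * tim + ph[2])
      if (nz$fnirs_drift > 0) {
        d <- cumsum(stats::rnorm(n))
        x <- x + nz$fnirs_drift * d / max(1e-12, stats::sd(d))
      }
      if (nz$fnirs_white > 0) x <- x + nz$fnirs_white * stats::rnorm(n)
      hbo[ch, ] <- hbo[ch, ] + x
    }
  }

  hbr <- truth$r_hb * hbo
  i0mat <- matrix(stats::runif(nch * 3L, 0.8, 1.2), nch, 3L)
  intensity <- forward_mbll(hbo, hbr, i0 = i0mat)
  n_bad <- sum(intensity <= 0)
  if (n_bad > 0) {
    message("generate_fnirs: ", n_bad,
            " non-positive intensity sample(s) clipped")
    intensity[intensity <= 0] <- 1e-9
  }
  list(intensity = intensity, wavelengths = c(780, 805, 830), dt_s = dt,
       channel_names = layout$name, planted = list(hbo = hbo, hbr = hbr))
}

#' Generate a complete synthetic subject
#'
#' Composes [build_schedule()], [generate_eeg()] and [generate_fnirs()] and
#' attaches the ground truth, yielding one subject's raw bimodal recording.
#'
#' @param config A [paradigm_config()]; its `seed` randomizes the trial
#'   sequence.
#' @param truth A [ground_truth()].
#' @param seed Integer seed for the signal noise (EEG uses `seed`, fNIRS
#'   `seed + 1`).
#' @return A `raw_recording` list: `schedule`, `eeg`, `eog`, `eeg_rate_hz`,
#'   `fnirs` (intensity array plus sampling metadata), `truth`, `config`,
#'   `seed`.
#' @export
generate_subject <- function(config = paradigm_config(),
                             truth = ground_truth(), seed = 1L) {
  schedule <- build_schedule(config)
  e <- generate_eeg(schedule, truth, seed = seed)
  f <- generate_fnirs(schedule, truth, seed = seed + 1L)
  structure(list(
    schedule = schedule, eeg = e$eeg, eog = e$eog,
    eeg_rate_hz = e$rate_hz, eeg_channel_names = e$channel_names,
    fnirs = f, truth = truth, config = config, seed = as.integer(seed)
  ), class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d trials; EEG %d ch x %d samples @ %g Hz; fNIRS %d ch x 3 wl x %d samples @ %.3f s\n",
    nrow(x$schedule), nrow(x$eeg), ncol(x$eeg), x$eeg_rate_hz,
    dim(x$fnirs$intensity)[1], dim(x$fnirs$intensity)[3], x$fnirs$dt_s))
  invisible(x)
}
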