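#' Reduce a grand average to one summary waveform per condition
#'
#' Cross-channel mean, the default channel reduction used before the
#' neurovascular lag analysis.
#'
#' @param grand_avg conditions x channels x time array ([grand_average()]).
#' @param channels Optional channel subset (indices).
#' @return conditions x time matrix; keeps the `times_s` attribute.
#' @export
summary_waveform <- function(grand_avg, channels = NULL) {
  stopifnot(length(dim(grand_avg)) == 3L, all(dim(grand_avg) > 0))
  sel <- channels %||% seq_len(dim(grand_avg)[2])
  out <- apply(grand_avg[, sel, , drop = FALSE], c(1, 3), mean)
  attr(out, "times_s") <- attr(grand_avg, "times_s")
  out
}

#' Lagged cross-correlation surface between ERP and HbO waveforms
#'
#' For every window length `X` (ms) and hemodynamic lag `Y` (ms), the
#' Pearson correlation between the ERP segment `[0, X]` ms and the HbO
#' segment `[Y, Y + X]` ms is computed per condition.  The HbO waveform is
#' linearly interpolated onto the 1 ms ERP grid first.  The default grids
#' follow the analysis convention: `X` from 100 to 600 ms in 1 ms steps,
#' `Y` from 0 to 3000 ms in 27 ms (one fNIRS sample) steps.
#'
#' @param erp conditions x time matrix of ERP summary waveforms.
#' @param hbo conditions x time matrix of HbO summary waveforms
#'   (same condition order).
#' @param erp_t0_s,hbo_t0_s Time (s) of the first column relative to
#'   observation onset.
#' @param erp_rate_hz ERP sampling rate (default 1000).
#' @param hbo_dt_s HbO sampling interval (default 0.027 s).
#' @param X_ms,Y_ms Window-length and lag grids (ms).
#' @return A `corr_surface` list: `X_ms`, `Y_ms`, `r` (conditions x X x Y
#'   array), `r_min` (X x Y elementwise minimum over conditions),
#'   `n_undefined` (zero-variance segments recorded as NA).
#' @export
lag_surface <- function(erp, hbo, erp_t0_s = 0, hbo_t0_s = 0,
                        erp_rate_hz = 1000, hbo_dt_s = 0.027,
                        X_ms = 100:600, Y_ms = seq(0, 3000, by = 27)) {
  stopifnot(nrow(erp) == nrow(hbo))
  n_cond <- nrow(erp)
  maxX <- max(X_ms); maxY <- max(Y_ms)
  need_ms <- maxY + maxX
  hbo_t_ms <- (hbo_t0_s + (seq_len(ncol(hbo)) - 1L) * hbo_dt_s) * 1000
  erp_t_ms <- (erp_t0_s + (seq_len(ncol(erp)) - 1L) / erp_rate_hz) * 1000
  if (max(hbo_t_ms) < need_ms - 1e-6)
    stop("HbO waveform must cover max(Y) + max(X) = ", need_ms, " ms after onset")
  if (max(erp_t_ms) < maxX - 1e-6 || min(erp_t_ms) > 1e-6)
    stop("ERP waveform must cover [0, ", maxX, "] ms")

  grid_ms <- 0:need_ms
  r <- array(NA_real_, c(n_cond, length(X_ms), length(Y_ms)),
             dimnames = list(rownames(erp), NULL, NULL))
  n_undef <- 0L
  for (ci in seq_len(n_cond)) {
    e <- stats::approx(erp_t_ms, erp[ci, ], xout = 0:maxX)$y
    h <- stats::approx(hbo_t_ms, hbo[ci, ], xout = grid_ms)$y
    ce <- cumsum(e); ce2 <- cumsum(e^2)
    for (yi in seq_along(Y_ms)) {
      hs <- h[(Y_ms[yi] + 1L):(Y_ms[yi] + maxX + 1L)]
      ch <- cumsum(hs); ch2 <- cumsum(hs^2); ceh <- cumsum(e * hs)
      nw <- X_ms + 1L
      se <- ce[nw]; se2 <- ce2[nw]; sh <- ch[nw]; sh2 <- ch2[nw]
      seh <- ceh[nw]
      ve <- se2 - se^2 / nw; vh <- sh2 - sh^2 / nw
      cov <- seh - se * sh / nw
      # guard against cancellation: a segment is constant if its variance is
      # negligible relative to its sum of squares
      ok <- ve > 1e-12 * pmax(se2, 1e-300) & vh > 1e-12 * pmax(sh2, 1e-300)
      rr <- rep(NA_real_, length(nw))
      rr[ok] <- pmin(1, pmax(-1, cov[ok] / sqrt(ve[ok] * vh[ok])))
      n_undef <- n_undef + sum(is.na(rr))
      r[ci, , yi] <- rr
    }
  }
  if (n_undef > 0)
    message("lag_surface: ", n_undef,
            " zero-variance segment(s) recorded as NA")
  r_min <- apply(r, c(2, 3), min)
  structure(list(X_ms = X_ms, Y_ms = Y_ms, r = r, r_min = r_min,
                 n_undefined = n_undef),
            class = "corr_surface")
}

#' High-correlation region and peak of a lag surface
#'
#' The region where the minimum-over-conditions correlation exceeds
#' `threshold` (the contour criterion), and the peak `(X*, Y*)` of the
#' minimum surface.  Ties at the peak break toward the smallest lag `Y`,
#' then the smallest window `X`.
#'
#' @param surface A `corr_surface`.
#' @param threshold Correlation threshold (default 0.8).
#' @return list: `mask` (X x Y logical), `n_region`, `peak_X_ms`,
#'   `peak_Y_ms`, `peak_r`.
#' @export
high_corr_region <- function(surface, threshold = 0.8) {
  stopifnot(inherits(surface, "corr_surface"))
  rm <- surface$r_min
  mask <- !is.na(rm) & rm > threshold
  if (!any(mask))
    message("high_corr_region: no cell exceeds threshold ", threshold,
            "; returning empty region")
  if (all(is.na(rm))) {
    return(list(mask = mask, n_region = 0L, peak_X_ms = NA_real_,
                peak_Y_ms = NA_real_, peak_r = NA_real_))
  }
  best <- max(rm, na.rm = TRUE)
  cand <- which(!is.na(rm) & rm >= best - 1e-12, arr.ind = TRUE)
  # smallest Y first, then smallest X
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
  xi <- cand[1, 1]; yi <- cand[1, 2]
  list(mask = mask, n_region = sum(mask),
       peak_X_ms = surface$X_ms[xi], peak_Y_ms = surface$Y_ms[yi],
       peak_r = rm[xi, yi])
}
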