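#' Double-gamma hemodynamic impulse response
#'
#' Canonical two-gamma impulse response (positive lobe minus a 1/6-weighted
#' undershoot lobe, shapes 6 and 16), time-compressed so that its
#' positive-to-undershoot zero crossing falls at `zero_cross_s`.  When a
#' boxcar of neural activity longer than `zero_cross_s` is convolved with
#' this kernel, the resulting response peaks exactly where the kernel
#' crosses zero — which is how the generator places the oxyhemoglobin peak
#' at a requested post-onset time.
#'
#' @param t Time points (s), may include negatives (response is 0 there).
#' @param zero_cross_s Target zero-crossing time (s).
#' @return Kernel values, unit peak.
#' @export
hrf_double_gamma <- function(t, zero_cross_s) {
  stopifnot(zero_cross_s > 0)
  z0 <- .hrf_zero_cross()
  k <- z0 / zero_cross_s
  u <- pmax(t, 0) * k
  h <- stats::dgamma(u, shape = 6, rate = 1) -
    stats::dgamma(u, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(h)
}

# zero crossing of the canonical shape, solved once and cached
.hrf_cache <- new.env(parent = emptyenv())
.hrf_zero_cross <- function() {
  if (is.null(.hrf_cache$z0)) {
    f <- function(u) stats::dgamma(u, 6, 1) - stats::dgamma(u, 16, 1) / 6
    .hrf_cache$z0 <- stats::uniroot(f, c(6, 14), tol = 1e-12)$root
  }
  .hrf_cache$z0
}

#' Noise-free HbO response of one trial
#'
#' Boxcar neural activity over the observation period, shifted by the
#' neurovascular lag and convolved with [hrf_double_gamma()], normalized to
#' unit peak.  With `peak_time_s` larger than the lag and smaller than
#' `lag + duration`, the response peaks at `peak_time_s` exactly (up to the
#' sampling grid).
#'
#' @param t Time points (s) relative to observation onset.
#' @param peak_time_s Requested post-onset peak time (default 3).
#' @param lag_s Neurovascular lag (s; default 1.7).
#' @param duration_s Observation (neural activity) duration (default 3.5).
#' @param dt Internal integration step (default 0.005 s).
#' @return Response values at `t`, unit peak.
#' @export
hbo_response <- function(t, peak_time_s = 3, lag_s = 1.7, duration_s = 3.5,
                         dt = 0.005) {
  stopifnot(peak_time_s > lag_s)
  zc <- peak_time_s - lag_s
  tmax <- max(max(t), lag_s + duration_s + 6 * zc) + dt
  grid <- seq(0, tmax, by = dt)
  h <- hrf_double_gamma(grid, zero_cross_s = zc)
  H <- cumsum(h) * dt
  Hfun <- stats::approxfun(grid, H, yleft = 0, yright = H[length(H)])
  r <- Hfun(t - lag_s) - Hfun(t - lag_s - duration_s)
  # while the boxcar is still on, the response peaks where the kernel
  # crosses zero, i.e. at H(zc); otherwise normalize numerically
  peak <- if (zc < duration_s) Hfun(zc) else {
    g <- seq(lag_s, lag_s + duration_s + 6 * zc, by = dt)
    max(Hfun(g - lag_s) - Hfun(g - lag_s - duration_s))
  }
  r / peak
}
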