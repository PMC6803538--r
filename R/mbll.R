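#' Hemoglobin extinction coefficients at the instrument wavelengths
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the three
#' continuous-wave wavelengths (780, 805 and 830 nm), in mM^-1 cm^-1,
#' compiled from the standard literature tables (805 nm is near the
#' isosbestic point).  These constants parameterize both the forward
#' light-attenuation model and [mbll_convert()].
#'
#' @return data.frame with columns `wavelength_nm`, `eps_hbo`, `eps_hbr`.
#' @export
hb_extinction <- function() {
  data.frame(
    wavelength_nm = c(780, 805, 830),
    eps_hbo = c(0.710, 0.830, 0.974),
    eps_hbr = c(1.075, 0.780, 0.693)
  )
}

#' Default differential pathlength factors
#'
#' Adult-head DPF values for the three wavelengths; dimensionless.
#' @return Named numeric vector.
#' @export
default_dpf <- function() c(`780` = 5.1, `805` = 4.9, `830` = 4.7)

# A-matrix of the MBLL linear system: dOD = A %*% c(dHbO, dHbR),
# concentrations expressed as concentration x pathlength in mM*mm
# (the source-detector separation cancels in this convention).
.mbll_A <- function(dpf) {
  E <- as.matrix(hb_extinction()[, c("eps_hbo", "eps_hbr")])
  A <- E * dpf * 0.1  # 0.1: mM*mm -> mM*cm
  dimnames(A) <- list(c("780", "805", "830"), c("hbo", "hbr"))
  A
}

#' Forward Beer-Lambert model: concentrations to light intensities
#'
#' Synthesizes raw three-wavelength intensities from planted hemoglobin
#' concentration changes, the exact inverse of [mbll_convert()]:
#' `I(lambda, t) = I0(lambda) * 10^-dOD(lambda, t)` with
#' `dOD = eps_HbO * dHbO + eps_HbR * dHbR` scaled by the DPF
#' (concentrations in mM*mm).
#'
#' @param hbo,hbr channels x time matrices of concentration changes (mM*mm).
#' @param i0 channels x 3 matrix of baseline intensities (arbitrary units),
#'   or a scalar.
#' @param dpf Per-wavelength differential pathlength factors.
#' @return channels x 3 x time array of intensities.
#' @export
forward_mbll <- function(hbo, hbr, i0 = 1, dpf = default_dpf()) {
  stopifnot(all(dim(hbo) == dim(hbr)))
  nch <- nrow(hbo); nt <- ncol(hbo)
  if (length(i0) == 1L) i0 <- matrix(i0, nch, 3L)
  A <- .mbll_A(dpf)
  out <- array(NA_real_, c(nch, 3L, nt))
  for (w in 1:3) {
    od <- A[w, "hbo"] * hbo + A[w, "hbr"] * hbr
    out[, w, ] <- i0[, w] * 10^(-od)
  }
  out
}

#' Modified Beer-Lambert conversion of intensities to hemoglobin changes
#'
#' Converts raw continuous-wave intensities at 780/805/830 nm into
#' concentration changes of oxy-, deoxy- and total hemoglobin.  Optical
#' density changes `dOD(lambda, t) = -log10(I(t) / I_ref)` are computed
#' against a reference intensity, then the overdetermined 3 x 2 linear
#' system `dOD = [eps_HbO, eps_HbR] * DPF/10 * [dHbO; dHbR]` is solved by
#' least squares at every time point.  `dHbT = dHbO + dHbR`.
#'
#' @param intensity channels x 3 x time array (wavelength order 780/805/830),
#'   strictly positive.
#' @param dpf Per-wavelength DPF (default [default_dpf()]).
#' @param separation_cm Source-detector separation, used only when
#'   `output = "molar"` (default 3 cm).
#' @param ref Reference for `I_ref`: `"mean"` (per-channel mean over time,
#'   default), `"first"` (first sample), or an integer vector of sample
#'   indices to average over.
#' @param output `"mM_mm"` (concentration x pathlength, default) or
#'   `"molar"` (mM, dividing by 10 x separation).
#' @return list with channels x time matrices `hbo`, `hbr`, `hbt` and the
#'   `dpf`/`ref` used.
#' @export
mbll_convert <- function(intensity, dpf = default_dpf(), separation_cm = 3,
                         ref = "mean", output = c("mM_mm", "molar")) {
  output <- match.arg(output)
  stopifnot(length(dim(intensity)) == 3L, dim(intensity)[2] == 3L)
  bad <- which(intensity <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-positive intensity at channel %d, wavelength %d, sample %d (%d total)",
      bad[1, 1], bad[1, 2], bad[1, 3], nrow(bad)))
  }
  nch <- dim(intensity)[1]; nt <- dim(intensity)[3]
  A <- .mbll_A(dpf)
  pinv <- solve(crossprod(A), t(A))  # 2 x 3 least-squares operator
  # vectorized over channels: per-wavelength optical-density matrices
  iref <- if (identical(ref, "mean")) apply(intensity, c(1, 2), mean)
          else if (identical(ref, "first")) intensity[, , 1L]
          else apply(intensity[, , ref, drop = FALSE], c(1, 2), mean)
  iref <- matrix(iref, nch, 3L)  # guard the single-channel drop
  hbo <- matrix(0, nch, nt); hbr <- matrix(0, nch, nt)
  for (w in 1:3) {
    od <- -log10(intensity[, w, ] / iref[, w])   # nch x nt
    if (is.null(dim(od))) od <- matrix(od, nch, nt)
    hbo <- hbo + pinv[1, w] * od
    hbr <- hbr + pinv[2, w] * od
  }
  if (output == "molar") {
    sc <- 10 * separation_cm
    hbo <- hbo / sc; hbr <- hbr / sc
  }
  list(hbo = hbo, hbr = hbr, hbt = hbo + hbr, dpf = dpf, ref = ref,
       output = output)
}
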