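#' Projected 2-D layout of the 64-channel EEG montage
#'
#' A schematic top-view projection of an extended 10-20 64-electrode cap
#' (nose up, unit head radius).  Rows run from frontopolar to occipital;
#' x spreads channels within each row, shrinking toward the head rim.
#' Coordinates are used for topographic interpolation and for selecting
#' posterior/frontal channel sets; they are schematic, not digitized
#' positions.
#'
#' @return data.frame with columns `channel`, `name`, `x`, `y`.
#' @export
eeg_layout_64 <- function() {
  rows <- list(
    list(y = 0.95, names = c("FP1", "FPZ", "FP2")),
    list(y = 0.80, names = c("AF7", "AF3", "AF4", "AF8")),
    list(y = 0.60, names = c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8")),
    list(y = 0.32, names = c("FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8")),
    list(y = 0.00, names = c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8")),
    list(y = -0.32, names = c("TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8")),
    list(y = -0.60, names = c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8")),
    list(y = -0.80, names = c("PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8")),
    list(y = -0.95, names = c("CB1", "O1", "OZ", "O2", "CB2"))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    k <- length(r$names)
    w <- 0.92 * sqrt(max(0, 1 - r$y^2))
    x <- if (k == 1L) 0 else seq(-w, w, length.out = k)
    data.frame(name = r$names, x = x, y = r$y)
  }))
  out$channel <- seq_len(nrow(out))
  out[, c("channel", "name", "x", "y")]
}

#' Parametric layout of the 48-channel fNIRS montage
#'
#' Channel positions are the emitter-detector midpoints of two 4 x 6
#' optode patches placed over the left and right parietal areas
#' (24 channels per hemisphere), on the same schematic head coordinates as
#' [eeg_layout_64()].  Channels 1-24 are left-hemisphere, 25-48 right.
#'
#' @return data.frame with columns `channel`, `name`, `x`, `y`, `hemisphere`.
#' @export
fnirs_layout_48 <- function() {
  gx <- seq(0.15, 0.85, length.out = 4)   # medial -> lateral
  gy <- seq(0.25, -0.65, length.out = 6)  # anterior-parietal -> occipito-parietal
  grid <- expand.grid(x = gx, y = gy)
  left <- data.frame(x = -grid$x, y = grid$y, hemisphere = "left")
  right <- data.frame(x = grid$x, y = grid$y, hemisphere = "right")
  out <- rbind(left, right)
  out$channel <- seq_len(nrow(out))
  out$name <- sprintf("CH%02d", out$channel)
  out[, c("channel", "name", "x", "y", "hemisphere")]
}

#' Default responsive EEG channel set
#'
#' The synthetic evoked intention component is planted on 43 of the 64
#' channels: all channels except the 21 most frontal/temporal in layout
#' order (the montage count of condition-sensitive channels; the identity
#' of the set is a generator choice and is configurable).
#'
#' @param n_drop Number of leading (frontal) channels excluded (default 21).
#' @return Integer vector of channel indices.
#' @export
responsive_eeg_channels <- function(n_drop = 21L) {
  layout <- eeg_layout_64()
  setdiff(layout$channel, seq_len(n_drop))
}
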