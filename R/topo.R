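#' Topographic interpolation of per-channel statistics
#'
#' Interpolates scattered per-channel values onto a regular 2-D grid with an
#' exact thin-plate spline (radial basis `r^2 log r` plus an affine part)
#' and masks the grid outside the convex hull of the channel positions.
#' The interpolant passes exactly through every channel value and
#' reproduces affine fields `a*x + b*y + c` exactly, the two fidelity
#' properties a statistic map must satisfy.
#'
#' @param values Per-channel scalar statistic.
#' @param layout data.frame with channel coordinates `x`, `y` (e.g.
#'   [eeg_layout_64()] or [fnirs_layout_48()]), same length as `values`.
#' @param grid_n Grid resolution per axis (default 64).
#' @return A `topo_map` list: `grid` (grid_n x grid_n matrix, NA outside the
#'   hull), `gx`, `gy` (grid axes), `channel_xy`, `values`.
#' @export
topo_interpolate <- function(values, layout, grid_n = 64L) {
  x <- layout$x; y <- layout$y
  n <- length(values)
  stopifnot(length(x) == n, length(y) == n)
  if (n < 3L || qr(cbind(1, x, y))$rank < 3L)
    stop("channel layout is collinear (or has < 3 channels); cannot interpolate")

  U <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))  # r^2 log r
  D2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  K <- U(D2)
  P <- cbind(1, x, y)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  coef <- solve(M, c(values, 0, 0, 0))
  w <- coef[seq_len(n)]; a <- coef[n + 1:3]

  gx <- seq(min(x), max(x), length.out = grid_n)
  gy <- seq(min(y), max(y), length.out = grid_n)
  gpts <- as.matrix(expand.grid(x = gx, y = gy))
  G2 <- outer(gpts[, 1], x, "-")^2 + outer(gpts[, 2], y, "-")^2
  z <- as.vector(U(G2) %*% w) + a[1] + a[2] * gpts[, 1] + a[3] * gpts[, 2]

  hull <- grDevices::chull(x, y)
  bnd <- cbind(x[c(hull, hull[1])], y[c(hull, hull[1])])
  inside <- mgcv::in.out(bnd, gpts)
  # keep grid points on (or numerically at) the hull boundary as well
  z[!inside] <- NA_real_
  grid <- matrix(z, grid_n, grid_n)  # rows follow gx, columns gy
  structure(list(grid = grid, gx = gx, gy = gy,
                 channel_xy = cbind(x = x, y = y), values = values),
            class = "topo_map")
}

#' Evaluate a topographic map at arbitrary points (exact spline evaluation)
#'
#' @param map A `topo_map`.
#' @param px,py Coordinates.
#' @return Interpolated values (no hull masking).
#' @export
topo_eval <- function(map, px, py) {
  x <- map$channel_xy[, "x"]; y <- map$channel_xy[, "y"]
  n <- length(map$values)
  U <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))
  D2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  K <- U(D2)
  P <- cbind(1, x, y)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  coef <- solve(M, c(map$values, 0, 0, 0))
  w <- coef[seq_len(n)]; a <- coef[n + 1:3]
  G2 <- outer(px, x, "-")^2 + outer(py, y, "-")^2
  as.vector(U(G2) %*% w) + a[1] + a[2] * px + a[3] * py
}

#' Write a topographic map as a PNG image
#'
#' @param map A `topo_map`.
#' @param path Output PNG path.
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
plot_topo_png <- function(map, path, main = "") {
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(map$gx, map$gy, map$grid, asp = 1, xlab = "x", ylab = "y",
                  main = main, col = grDevices::hcl.colors(64, "RdBu",
                                                           rev = TRUE))
  graphics::points(map$channel_xy, pch = 20, cex = 0.6)
  invisible(path)
}
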