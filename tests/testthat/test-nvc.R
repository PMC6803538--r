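test_that("summary waveform is the cross-channel mean", {
  set.seed(41)
  ga <- array(rnorm(2 * 3 * 50), c(2, 3, 50),
              dimnames = list(c("Sd", "Sm"), NULL, NULL))
  sw <- summary_waveform(ga)
  for (ci in 1:2) for (ti in c(1, 25, 50))
    expect_equal(unname(sw[ci, ti]), mean(ga[ci, , ti]))
  # single channel -> identity; opposite channels -> zero
  ga1 <- ga[, 1, , drop = FALSE]
  expect_equal(unname(summary_waveform(ga1)), unname(ga[, 1, ]))
  ga2 <- array(c(ga[, 1, ], -ga[, 1, ]), c(2, 1, 50))
  ga2 <- array(NA_real_, c(2, 2, 50)); ga2[, 1, ] <- ga[, 1, ]
  ga2[, 2, ] <- -ga[, 1, ]
  expect_equal(max(abs(summary_waveform(ga2))), 0)
})

test_that("lag surface equals the two-pass Pearson oracle", {
  set.seed(42)
  erp <- matrix(rnorm(2 * 700), 2, 700)
  hbo <- matrix(rnorm(2 * 150), 2, 150)
  surf <- lag_surface(erp, hbo, X_ms = c(120, 350, 600),
                      Y_ms = seq(0, 2997, by = 27))
  e1 <- approx((0:699) / 1000, erp[1, ], xout = (0:600) / 1000)$y
  h1 <- approx((0:149) * 0.027, hbo[1, ], xout = (0:3600) / 1000)$y
  for (X in c(120, 350, 600)) for (Y in c(0, 270, 1512)) {
    xi <- match(X, surf$X_ms); yi <- match(Y, surf$Y_ms)
    expect_equal(surf$r[1, xi, yi],
                 oracle_pearson(e1[1:(X + 1)], h1[(Y + 1):(Y + X + 1)]),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(surf$r) <= 1, na.rm = TRUE))
})

test_that("identical signals give unit correlation at zero lag", {
  t <- (0:4000) / 1000
  w <- sin(2 * pi * 1.3 * t) + 0.3 * sin(2 * pi * 3.7 * t)
  erp <- rbind(w[1:700], w[1:700])
  # hbo on its own 27 ms grid, same underlying function
  th <- seq(0, 4, by = 0.027)
  hb <- sin(2 * pi * 1.3 * th) + 0.3 * sin(2 * pi * 3.7 * th)
  hbo <- rbind(hb, hb)
  surf <- lag_surface(erp, hbo, X_ms = seq(100, 600, 50),
                      Y_ms = seq(0, 2997, 27))
  expect_true(all(surf$r[, , 1] > 0.999))
  reg <- high_corr_region(surf)
  # tie-break: smallest Y then smallest X
  expect_equal(reg$peak_Y_ms, 0)
})

test_that("surface is invariant to affine rescaling of either waveform", {
  set.seed(43)
  erp <- matrix(rnorm(700), 1, 700)
  hbo <- matrix(rnorm(150), 1, 150)
  s1 <- lag_surface(erp, hbo, X_ms = seq(100, 600, 100),
                    Y_ms = seq(0, 2997, 27))
  s2 <- lag_surface(3.2 * erp + 5, 0.1 * hbo - 2,
                    X_ms = seq(100, 600, 100), Y_ms = seq(0, 2997, 27))
  expect_equal(s1$r, s2$r, tolerance = 1e-10)
})

test_that("a constructed delay is recovered on the lag grid", {
  set.seed(44)
  # smooth band-limited signal, delayed copy on the fNIRS grid
  base <- as.numeric(stats::filter(rnorm(9000), rep(1 / 40, 40),
                                   sides = 2))
  base[is.na(base)] <- 0
  L <- 1188  # planted delay (44 fNIRS samples)
  # hbo(t) = erp(t - L): the hemodynamic copy trails the ERP by L ms
  erp <- matrix(base[3001:3700], 1, 700)
  th_idx <- 3001 - L + round(seq(0, 4000, by = 27))
  hbo <- matrix(base[th_idx], 1, length(th_idx))
  surf <- lag_surface(erp, hbo, X_ms = 100:600, Y_ms = seq(0, 2997, 27))
  reg <- high_corr_region(surf)
  expect_lt(abs(reg$peak_Y_ms - L), 55)  # within 2 grid steps
})

test_that("uncorrelated noise stays below a permutation-style bound", {
  set.seed(45)
  peaks <- replicate(10, {
    erp <- matrix(rnorm(700), 1, 700)
    hbo <- matrix(rnorm(150), 1, 150)
    s <- lag_surface(erp, hbo, X_ms = seq(300, 600, 10),
                     Y_ms = seq(0, 2997, 27))
    max(s$r_min, na.rm = TRUE)
  })
  # interpolated white noise, windows >= 300 samples: max |r| stays modest
  expect_lt(max(peaks), 0.75)
  expect_lt(median(peaks), 0.5)
})

test_that("thresholding and empty regions behave as documented", {
  set.seed(46)
  erp <- matrix(rnorm(700), 1, 700)
  hbo <- matrix(rnorm(150), 1, 150)
  surf <- lag_surface(erp, hbo, X_ms = seq(100, 600, 100),
                      Y_ms = seq(0, 2997, 27))
  expect_message(reg <- high_corr_region(surf, threshold = 1),
                 "empty region")
  expect_equal(reg$n_region, 0)
  expect_false(any(reg$mask))
  # peak still reported
  expect_true(is.finite(reg$peak_r))
})
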