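test_that("grand average reduces to trivial cases correctly", {
  set.seed(31)
  dat <- array(rnorm(3 * 2 * 40), c(3, 2, 40))
  ep <- epoch_set(dat, 10, 0, c("Sd", "Sm", "Su"), "EEG")
  ga <- grand_average(ep)
  expect_equal(ga["Sm", , ], dat[2, , ])  # single trial per condition
  epc <- epoch_set(array(4, c(6, 2, 10)), 10, 0,
                   rep(c("Sd", "Sm", "Su"), 2), "EEG")
  expect_true(all(grand_average(epc) == 4))
  ep2 <- epoch_set(dat[1:2, , , drop = FALSE], 10, 0,
                   factor(c("Sd", "Sm"), levels = c("Sd", "Sm", "Su")),
                   "EEG")
  expect_error(grand_average(ep2), "Su")
})

test_that("grand average converges to the planted waveform", {
  set.seed(32)
  wave <- sin(seq(0, 2 * pi, length.out = 50))
  dat <- array(rnorm(300 * 1 * 50, sd = 1), c(300, 1, 50))
  dat[, 1, ] <- dat[, 1, ] + rep(wave, each = 300)
  ep <- epoch_set(dat, 10, 0, rep(c("Sd", "Sm", "Su"), 100), "EEG")
  ga <- grand_average(ep)
  # CLT: per-condition mean of 100 trials, sd 0.1 -> within 4 sigma
  expect_lt(max(abs(ga[1, 1, ] - wave)), 0.4)
})

test_that("channelwise ANOVA matches the sums-of-squares oracle", {
  set.seed(33)
  for (i in 1:20) {
    y <- rnorm(30)
    g <- factor(rep(c("Sd", "Sm", "Su"), 10))
    ep <- epoch_set(array(y, c(30, 1, 1)), 1, 0, g, "EEG")
    res <- channel_anova(ep, c(0, 0.5), alpha = 0.05)
    expect_equal(res$F[1], oracle_anova_F(y, g), tolerance = 1e-10)
    expect_equal(res$df1[1], 2)
    expect_equal(res$df2[1], 27)
  }
})

test_that("ANOVA flags strong separation and bonferroni-corrects pairwise tests", {
  set.seed(34)
  y <- rep(c(1, 2, 3), each = 4) + rnorm(12, sd = 1e-3)
  ep <- epoch_set(array(y, c(12, 1, 1)), 1, 0,
                  rep(c("Sd", "Sm", "Su"), each = 4), "EEG")
  res <- channel_anova(ep, c(0, 1), alpha = 0.001)
  expect_gt(res$F[1], 1e4)
  expect_true(res$significant[1])
  post <- attr(res, "posthoc")
  expect_true(all(post[1, ] < 0.001))
  # bonferroni arithmetic: corrected = min(1, 3 * raw)
  pt <- pairwise.t.test(y, rep(c("Sd", "Sm", "Su"), each = 4),
                        p.adjust.method = "none", pool.sd = TRUE)$p.value
  raw <- c(pt["Sm", "Sd"], pt["Su", "Sd"], pt["Su", "Sm"])
  expect_equal(unname(post[1, ]), pmin(1, 3 * raw), tolerance = 1e-12)
  # identical group means: F should be near zero
  y0 <- rep(c(5, 6), 6)
  ep0 <- epoch_set(array(y0, c(12, 1, 1)), 1, 0,
                   rep(c("Sd", "Sm", "Su"), 4), "EEG")
  expect_lt(channel_anova(ep0, c(0, 1), 0.05)$F[1], 1e-20)
  # degenerate: zero variance everywhere
  epz <- epoch_set(array(rep(c(1, 2, 3), each = 4), c(12, 1, 1)), 1, 0,
                   rep(c("Sd", "Sm", "Su"), each = 4), "EEG")
  expect_error(channel_anova(epz, c(0, 1), 0.05), "degenerate")
})

test_that("HbO block t-test localizes a planted response in time", {
  rate <- 1 / 0.027
  n <- floor(12 / 0.027) + 1
  t <- -6.5 + (seq_len(n) - 1) * 0.027
  resp <- hbo_response(t, peak_time_s = 3, lag_s = 1, duration_s = 3.5)
  # derived expectation: among the probe times, the planted response has its
  # largest windowed mean at 3 s (checked directly on the clean template)
  wm_clean <- sapply(1:5, function(tt) mean(resp[t >= tt - 0.5 & t <= tt + 0.5]))
  expect_equal(which.max(wm_clean), 3L)
  set.seed(35)
  nch <- 13  # 12 channels with the response, channel 13 pure noise
  dat <- array(rnorm(40 * nch * n, sd = 0.05), c(40, nch, n))
  for (ch in 1:12) dat[, ch, ] <- dat[, ch, ] + rep(resp, each = 40)
  ep <- epoch_set(dat, rate, -6.5, rep(c("Sd", "Sm"), 20), "HbO")
  res <- hbo_block_ttest(ep)
  # per channel the 3 s vs 4 s ordering is noisy (the standard-error
  # estimate itself fluctuates), but the typical peak time is 3 s
  peak_t <- sapply(1:12, function(ch) {
    r <- res[res$channel == ch, ]
    r$time_s[which.max(abs(r$t))]
  })
  expect_equal(median(peak_t), 3)
  r1 <- res[res$channel == 1, ]
  expect_true(all(r1$significant[r1$time_s %in% 2:4]))
  # channel without response: |t| stays modest
  r2 <- res[res$channel == nch, ]
  expect_lt(max(abs(r2$t)), 4.5)
  # paired t equals t.test oracle
  obs <- window_mean(ep, c(2.5, 3.5)); base <- window_mean(ep, c(-6.5, -0.5))
  tt <- t.test(obs[, 1], base[, 1], paired = TRUE)
  expect_equal(r1$t[r1$time_s == 3], unname(tt$statistic), tolerance = 1e-12)
})

test_that("topographic interpolation is exact at channels and on affine fields", {
  layout <- fnirs_layout_48()
  vals <- 2 * layout$x - 3 * layout$y + 0.5
  map <- topo_interpolate(vals, layout, grid_n = 32)
  # exact at channel sites
  expect_equal(topo_eval(map, layout$x, layout$y), vals, tolerance = 1e-8)
  # reproduces the affine field on interior grid points
  gx <- map$gx[8:24]; gy <- map$gy[8:24]
  gg <- expand.grid(x = gx, y = gy)
  expect_equal(topo_eval(map, gg$x, gg$y), 2 * gg$x - 3 * gg$y + 0.5,
               tolerance = 1e-6)
  # constant field -> constant map inside the mask
  mapc <- topo_interpolate(rep(7, nrow(layout)), layout, grid_n = 16)
  expect_equal(range(mapc$grid, na.rm = TRUE), c(7, 7), tolerance = 1e-8)
  # grid is masked outside the hull
  expect_true(anyNA(mapc$grid))
  # collinear layouts are rejected
  bad <- data.frame(x = 1:5, y = 2 * (1:5))
  expect_error(topo_interpolate(rnorm(5), bad), "collinear")
})

test_that("ANOVA-significant channels recover exactly the planted responsive set", {
  # pooled across simulated runs to ~165 error df, the scale at which
  # channelwise F statistics of this paradigm are computed (a single
  # 42-trial run is underpowered at alpha = 0.001, as expected)
  wm_all <- NULL; lab_all <- NULL
  for (s in c(19, 20, 21, 22)) {
    cfg <- paradigm_config(n_reps = 2, n_sessions = 2, seed = s,
                           eeg_rate_hz = 125)
    sch <- build_schedule(cfg)
    e <- generate_eeg(sch, ground_truth(), seed = s)
    flt <- bandpass_filter(e$eeg, cfg$eeg_rate_hz, 1, 30)
    ep <- baseline_correct(epoch_extract(flt, cfg$eeg_rate_hz, sch,
                                         c(-0.7, 3.5), modality = "EEG"))
    wm_all <- rbind(wm_all, window_mean(ep, c(0.35, 0.40)))
    lab_all <- c(lab_all, as.character(ep$labels))
  }
  ep_pool <- epoch_set(array(wm_all, c(nrow(wm_all), 64, 1)), 1, 0,
                       lab_all, "EEG")
  res <- channel_anova(ep_pool, c(-0.5, 0.5), alpha = 0.001)
  sig <- which(res$significant)
  tr <- ground_truth()
  expect_true(all(tr$responsive_eeg %in% sig))       # full coverage
  expect_true(all(sig %in% tr$responsive_eeg))       # and no false channels
})
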