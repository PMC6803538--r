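test_that("generators are deterministic given a seed and differ across seeds", {
  cfg <- tiny_config()
  sch <- build_schedule(cfg)
  tr <- ground_truth()
  a <- generate_eeg(sch, tr, seed = 9)
  b <- generate_eeg(sch, tr, seed = 9)
  c <- generate_eeg(sch, tr, seed = 10)
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$eog, b$eog)
  expect_false(identical(a$eeg, c$eeg))
  fa <- generate_fnirs(sch, tr, seed = 9)
  fb <- generate_fnirs(sch, tr, seed = 9)
  expect_identical(fa$intensity, fb$intensity)
  # intensities strictly positive
  expect_true(all(fa$intensity > 0))
})

test_that("recording dimensions follow the schedule arithmetic", {
  cfg <- tiny_config()
  rec <- generate_subject(cfg, ground_truth(), seed = 2)
  total <- attr(rec$schedule, "total_duration_s")
  expect_equal(dim(rec$eeg), c(64, round(total * cfg$eeg_rate_hz)))
  expect_equal(dim(rec$fnirs$intensity),
               c(48, 3, floor(total / cfg$fnirs_dt_s) + 1))
  expect_equal(dim(rec$eog)[1], 2)
})

test_that("noise-free ERP window means are ordered Sd > Sm > Su on responsive channels", {
  cfg <- tiny_config()
  sch <- build_schedule(cfg)
  tr <- quiet_truth()
  e <- generate_eeg(sch, tr, seed = 1)
  ep <- baseline_correct(epoch_extract(e$eeg, cfg$eeg_rate_hz, sch,
                                       c(-0.7, 3.5), modality = "EEG"))
  wm <- window_mean(ep, c(0.35, 0.40))
  means <- apply(wm, 2, function(v) tapply(v, ep$labels, mean))
  resp <- tr$responsive_eeg
  expect_true(all(means["Sd", resp] > means["Sm", resp]))
  expect_true(all(means["Sm", resp] > means["Su", resp]))
  # non-responsive channels carry no intention component
  nonresp <- setdiff(1:64, resp)
  expect_lt(max(abs(means[, nonresp])), 1e-9)
})

test_that("zero effect size plants identical conditions", {
  cfg <- tiny_config()
  sch <- build_schedule(cfg)
  tr0 <- quiet_truth(effect_size = 0)
  e <- generate_eeg(sch, tr0, seed = 1)
  ep <- epoch_extract(e$eeg, cfg$eeg_rate_hz, sch, c(-0.7, 3.5),
                      modality = "EEG")
  wm <- window_mean(ep, c(0.35, 0.40))
  means <- apply(wm, 2, function(v) tapply(v, ep$labels, mean))
  expect_lt(max(abs(means["Sd", ] - means["Su", ])), 1e-9)
})

test_that("noise-free HbO peaks at the planted time after MBLL round trip", {
  cfg <- tiny_config()
  sch <- build_schedule(cfg)
  # coupling carrier off: the peak-time contract concerns the hemodynamic
  # response component (for the weakest condition the equally strong
  # carrier lobe would otherwise rival the response peak)
  tr <- quiet_truth(coupling_amp = 0)
  f <- generate_fnirs(sch, tr, seed = 3)
  hb <- mbll_convert(f$intensity, ref = "first")
  # round trip recovers the planted concentrations to numerical precision
  expect_lt(max(abs(hb$hbo - f$planted$hbo)) / max(abs(f$planted$hbo)), 1e-9)
  expect_lt(max(abs(hb$hbr - f$planted$hbr)) / max(abs(f$planted$hbr)), 1e-9)
  ep <- baseline_correct(epoch_extract(hb$hbo, 1 / f$dt_s, sch, c(-6.5, 5.5),
                                       modality = "HbO"), c(-6.5, -0.5))
  ga <- grand_average(ep)
  tt <- attr(ga, "times_s")
  wave <- summary_waveform(ga)
  for (cond in rownames(wave)) {
    pk <- tt[which.max(wave[cond, ])]
    expect_lt(abs(pk - tr$hbo_peak_time_s), f$dt_s + 1e-9)
  }
  # condition-ordered peak amplitudes
  pks <- apply(wave, 1, max)
  expect_true(pks["Sd"] > pks["Sm"] && pks["Sm"] > pks["Su"])
})

test_that("hemodynamic response kernel peaks where requested", {
  t <- seq(0, 15, by = 0.001)
  # peak is located to within the internal integration step (5 ms)
  r <- hbo_response(t, peak_time_s = 3, lag_s = 1.7, duration_s = 3.5)
  expect_lt(abs(t[which.max(r)] - 3), 0.006)
  expect_equal(max(r), 1, tolerance = 1e-3)
  r2 <- hbo_response(t, peak_time_s = 4, lag_s = 0.5, duration_s = 3.5)
  expect_lt(abs(t[which.max(r2)] - 4), 0.006)
  # zero before the lag
  expect_equal(max(abs(r[t < 1.7])), 0)
})

test_that("EOG leakage is planted with the stored mixing", {
  cfg <- tiny_config()
  sch <- build_schedule(cfg)
  tr <- quiet_truth()
  set.seed(6)
  e <- generate_eeg(sch, tr, seed = 6)
  B <- attr(e$eeg, "eog_mixing")
  expect_equal(dim(B), c(64, 2))
  # frontal rows lead, posterior rows are zero in the first column
  layout <- eeg_layout_64()
  expect_true(all(B[layout$y <= 0.1, 1] == 0))
  expect_true(all(B[layout$y > 0.2, 1] > 0))
})
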