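test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  # DC offset removed
  dc <- bandpass_filter(rep(3, length(t)), fs, 1, 30)
  expect_lt(mean(abs(dc[500:9500])), 0.05)
  # 10 Hz passes within 5 %; oracle: squared Butterworth magnitude response
  s10 <- bandpass_filter(sin(2 * pi * 10 * t), fs, 1, 30)
  amp10 <- max(abs(s10[2000:8000]))
  expect_lt(abs(amp10 - 1), 0.05)
  # 60 Hz attenuated below 0.1
  s60 <- bandpass_filter(sin(2 * pi * 60 * t), fs, 1, 30)
  expect_lt(max(abs(s60[2000:8000])), 0.1)
  expect_error(bandpass_filter(t, fs, 1, 600), "Nyquist")
})

test_that("filters are linear operators", {
  fs <- 250
  set.seed(1)
  x <- rnorm(2000); y <- rnorm(2000)
  fx <- bandpass_filter(x, fs, 1, 30)
  fy <- bandpass_filter(y, fs, 1, 30)
  fxy <- bandpass_filter(2 * x - 3 * y, fs, 1, 30)
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8)
  nx <- notch_filter(x, fs, 50)
  ny <- notch_filter(y, fs, 50)
  nxy <- notch_filter(0.5 * x + y, fs, 50)
  expect_equal(nxy, 0.5 * nx + ny, tolerance = 1e-8)
})

test_that("notch suppresses the notch frequency and spares neighbors", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  n50 <- notch_filter(sin(2 * pi * 50 * t), fs, 50)
  expect_lt(max(abs(n50[2000:8000])), 0.1)  # >= 10x reduction
  n10 <- notch_filter(sin(2 * pi * 10 * t), fs, 50)
  expect_lt(abs(max(abs(n10[2000:8000])) - 1), 0.05)
  expect_equal(notch_filter(rep(0, 1000), fs, 50), rep(0, 1000))
  expect_error(notch_filter(t, fs, 700), "Nyquist")
})

test_that("EOG regression recovers a known linear mixing exactly", {
  set.seed(2)
  n <- 5000
  clean <- matrix(rnorm(4 * n), 4, n)
  eog <- matrix(rnorm(2 * n), 2, n)
  B <- matrix(c(0.5, -0.2, 0.1, 0, 0.3, 0.25, -0.4, 0.05), 4, 2)
  contaminated <- clean + B %*% eog
  out <- remove_eog(contaminated, eog)
  # recovered mixing matches planted B and clean data is restored up to the
  # (small) sample covariance between clean and eog
  expect_lt(max(abs(attr(out, "mixing") - B)), 0.05)
  expect_lt(max(abs(out - clean)), 0.2)
  expect_gt(cor(out[1, ], clean[1, ]), 0.999)
})

test_that("EOG regression degenerate cases leave EEG unchanged", {
  set.seed(3)
  eeg <- matrix(rnorm(600), 2, 300)
  expect_message(out <- remove_eog(eeg, matrix(1, 2, 300)), "constant")
  expect_equal(out, eeg, ignore_attr = TRUE)
  # orthogonal eog (in expectation): change is tiny
  eog <- matrix(rnorm(300), 1, 300)
  out2 <- remove_eog(eeg, eog)
  expect_lt(max(abs(out2 - eeg)), 0.2)
})

test_that("epoching yields the documented sample counts and labels", {
  cfg <- tiny_config()
  sch <- build_schedule(cfg)
  n_eeg <- round(attr(sch, "total_duration_s") * 1000)
  cont <- matrix(rnorm(2 * n_eeg), 2, n_eeg)
  ep <- epoch_extract(cont, 1000, sch, c(-0.7, 3.5), modality = "EEG")
  expect_equal(dim(ep$data), c(nrow(sch), 2, 4201))
  expect_identical(as.character(ep$labels), as.character(sch$condition))
  # fNIRS window arithmetic: floor(12.0 / 0.027) + 1 samples
  nf <- floor(attr(sch, "total_duration_s") / 0.027) + 1
  contf <- matrix(rnorm(nf), 1, nf)
  epf <- epoch_extract(contf, 1 / 0.027, sch, c(-6.5, 5.5), modality = "HbO")
  expect_equal(dim(epf$data)[3], floor(12.0 / 0.027) + 1)
  expect_equal(dim(epf$data)[3], 445)
  # out-of-bounds trials are reported by index
  expect_error(epoch_extract(cont, 1000, sch, c(-10, 3.5)), "trial")
  # empty schedule -> empty epoch set
  ep0 <- epoch_extract(cont, 1000, sch[integer(0), ], c(-0.7, 3.5))
  expect_equal(dim(ep0$data)[1], 0)
})

test_that("baseline correction zeroes the baseline mean exactly", {
  set.seed(4)
  dat <- array(rnorm(5 * 3 * 100) + 7, c(5, 3, 100))
  ep <- epoch_set(dat, 100, -0.5, rep(c("Sd", "Sm", "Su"), length.out = 5),
                  "EEG")
  out <- baseline_correct(ep, c(-0.5, -0.3))
  t <- epoch_times(out)
  idx <- which(t >= -0.5 & t <= -0.3)
  base <- apply(out$data[, , idx], c(1, 2), mean)
  expect_equal(max(abs(base)), 0, tolerance = 1e-12)
  # constant epochs become all zeros
  epc <- epoch_set(array(3, c(2, 2, 50)), 100, -0.5, c("Sd", "Sm"), "EEG")
  outc <- baseline_correct(epc, c(-0.5, -0.2))
  expect_equal(max(abs(outc$data)), 0)
  # pulse outside the baseline window is untouched, verified arithmetically
  x <- array(0, c(1, 1, 100))
  x[1, 1, 80:90] <- 5
  epp <- baseline_correct(epoch_set(x, 100, -0.5, "Sd", "EEG"),
                          c(-0.5, -0.3))
  expect_equal(epp$data[1, 1, 85], 5)
  expect_error(baseline_correct(ep, c(-2, -1)), "outside epoch")
})
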