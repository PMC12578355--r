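# Per-window feature extraction: statistics, peaks, HRV, electrodermal
# decomposition, attribute encoding and tensor assembly.

test_that("basic_stats matches direct arithmetic and handles degenerates", {
  s <- basic_stats(c(1, 2, 3, 4))
  expect_equal(unname(s), c(2.5, sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)), 4, 1))
  expect_equal(s[["std"]], 1.1180, tolerance = 1e-4)
  expect_equal(unname(basic_stats(rep(3.3, 17))), c(3.3, 0, 3.3, 3.3))
  expect_equal(unname(basic_stats(7)), c(7, 0, 7, 7))
  expect_error(basic_stats(numeric(0)), "empty")
})

test_that("basic_stats agrees with a brute-force oracle on random input", {
  set.seed(42)
  for (i in 1:1000) {
    x <- rnorm(sample(1:30, 1), sd = sample(c(0.1, 1, 50), 1))
    s <- basic_stats(x)
    expect_equal(s[["mean"]], sum(x) / length(x), tolerance = 1e-12)
    expect_equal(s[["std"]], sqrt(sum((x - mean(x))^2) / length(x)),
                 tolerance = 1e-12)
    expect_identical(s[["max"]], max(x))
    expect_identical(s[["min"]], min(x))
  }
})

test_that("accelerometer features use the per-sample sum channel", {
  f <- extract_acc(list(c(1, 1), c(2, 2), c(3, 3)))
  expect_length(f, 16)
  expect_equal(f[["ACC_net_mean"]], 6)
  expect_equal(f[["ACC_net_std"]], 0)
  f0 <- extract_acc(list(rep(0, 5), rep(0, 5), rep(0, 5)))
  expect_true(all(f0 == 0))
  # one sample (3,4,0): sum 7, l2 norm 5
  expect_equal(extract_acc(list(3, 4, 0))[["ACC_net_mean"]], 7)
  expect_equal(extract_acc(list(3, 4, 0), acc_net = "l2")[["ACC_net_mean"]], 5)
  expect_error(extract_acc(list(1:3, 1:2, 1:3)), "equal length")
})

test_that("electrodermal decomposition reconstructs and localises", {
  fs <- 4
  # tonic + phasic reconstructs exactly
  set.seed(5)
  x <- 2 + cumsum(rnorm(120, 0, 0.05))
  d <- eda_decompose(x, fs)
  expect_lt(max(abs(d$tonic + d$phasic - x)), 1e-9)
  # slow ramp is almost entirely tonic
  ramp <- seq(1, 3, length.out = 120)
  dr <- eda_decompose(ramp, fs)
  expect_lt(max(abs(dr$phasic)), 0.05 * 2)
  # one SCR bump: driver support confined to t0 +/- 3 s
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  t0 <- 15
  bump <- 2 + exp(-(t - t0)^2 / 0.5) * (t > t0 - 2 & t < t0 + 2)
  db <- eda_decompose(bump, fs)
  outside <- abs(t - t0) > 3
  expect_lt(max(db$driver[outside]), 1e-6 * max(1, max(db$driver)))
  expect_error(eda_decompose(rnorm(8), 4), "4 s")
})

test_that("EDA features: 12 per window, offset-invariant phasic/driver", {
  x <- 3 + rnorm(120, 0, 0.05)
  f <- extract_eda(x, 4)
  expect_length(f, 12)
  fc <- extract_eda(rep(2.5, 120), 4)
  expect_equal(unname(fc[c("EDA_tonic_mean", "EDA_tonic_std",
                           "EDA_tonic_max", "EDA_tonic_min")]),
               c(2.5, 0, 2.5, 2.5), tolerance = 1e-6)
  expect_true(all(abs(fc[5:12]) < 1e-6))
  f2 <- extract_eda(x + 1.5, 4)
  expect_equal(f2[["EDA_tonic_mean"]] - f[["EDA_tonic_mean"]], 1.5,
               tolerance = 1e-6)
  expect_equal(f2[5:12], f[5:12], tolerance = 1e-9)
})

test_that("peak detection finds sinusoid maxima and respects distance", {
  fs <- 50
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  pk <- detect_peaks(sin(2 * pi * 1 * t), fs, min_distance_s = 0.4,
                     min_prominence = 0.5)
  expect_length(pk, 10)
  expect_length(detect_peaks(rep(1, 100), fs), 0)
  # two well-separated unit bumps
  x <- numeric(200)
  x[50] <- 1; x[150] <- 1
  pk2 <- detect_peaks(x, fs, min_distance_s = 0.4, min_prominence = 0.5)
  expect_equal(pk2, c(50, 150), tolerance = 1)
})

test_that("SDNN and RMSSD match their direct formulas", {
  nn <- c(800, 810, 790, 805)
  expect_equal(hrv_sdnn(nn), sd(nn))
  expect_equal(hrv_sdnn(nn), 8.539, tolerance = 1e-3)
  expect_equal(hrv_rmssd(nn), sqrt(mean(diff(nn)^2)))
  expect_equal(hrv_rmssd(nn), 15.546, tolerance = 1e-3)
  expect_equal(hrv_sdnn(rep(812, 9)), 0)
  expect_equal(hrv_rmssd(rep(812, 9)), 0)
  expect_error(hrv_sdnn(800), ">= 2")
  expect_error(hrv_rmssd(800), ">= 2")
})

test_that("BVP features recover the pulse rate of a synthetic train", {
  fs <- 64
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  beats <- seq(0.3, 29.7, by = 1 / 1.2)       # 1.2 Hz pulse train
  x <- rowSums(sapply(beats, function(b) exp(-(t - b)^2 / (2 * 0.05^2))))
  f <- extract_bvp(x, fs)
  expect_gte(f[["BVP_peak_freq_hz"]], 1.13)
  expect_lte(f[["BVP_peak_freq_hz"]], 1.27)
  expect_lt(f[["BVP_sdnn_ms"]], 2)            # perfectly periodic
  expect_lt(f[["BVP_rmssd_ms"]], 2)
  flat <- extract_bvp(rep(0.5, fs * 30), fs)
  expect_true(all(flat == 0))
  expect_true(isTRUE(attr(flat, "low_peaks")))
})

test_that("ECG features match known beat timing", {
  fs <- 175
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  mk_ecg <- function(beat_times) {
    x <- numeric(length(t))
    for (b in beat_times) {
      i <- which.min(abs(t - b))
      w <- max(1, round(0.02 * fs))
      idx <- max(1, i - w):min(length(x), i + w)
      x[idx] <- pmax(x[idx], 1 - abs(t[idx] - b) / 0.03)
    }
    x
  }
  f <- extract_ecg(mk_ecg(seq(0.5, 29.5, by = 1)), fs)   # 60 bpm, no jitter
  expect_lt(f[["ECG_sdnn_ms"]], 2)
  # alternating 950/1050 ms intervals: RMSSD = 100 ms
  bt <- cumsum(c(0.5, rep(c(0.950, 1.050), 14)))
  f2 <- extract_ecg(mk_ecg(bt), fs)
  expect_equal(f2[["ECG_rmssd_ms"]], 100, tolerance = 5)
  flat <- extract_ecg(rep(0, fs * 30), fs)
  expect_true(all(flat == 0))
  expect_true(isTRUE(attr(flat, "low_peaks")))
})

test_that("temperature slope is the least-squares trend per second", {
  f <- extract_temp(c(30.0, 30.1, 30.2, 30.3), 1)
  expect_equal(f[["TEMP_slope"]], 0.1, tolerance = 1e-12)
  expect_equal(extract_temp(rep(31, 10), 1)[["TEMP_slope"]], 0)
  expect_equal(extract_temp(rev(c(30.0, 30.1, 30.2, 30.3)), 1)[["TEMP_slope"]],
               -0.1, tolerance = 1e-12)
})

test_that("EMG and RESP features scale linearly with the signal", {
  x <- abs(rnorm(240, 1, 0.1))
  for (ex in list(extract_emg, extract_resp)) {
    f1 <- ex(x, 8)
    f2 <- ex(3 * x, 8)
    expect_length(f1, 4)
    expect_equal(unname(f2), unname(3 * f1), tolerance = 1e-9)
  }
  expect_equal(unname(extract_emg(rep(0.4, 100), 8)), c(0.4, 0, 0.4, 0.4),
               tolerance = 1e-6)
  expect_true(all(abs(extract_resp(rep(0, 100), 8)) < 1e-12))
})

test_that("attribute encoding is one-hot with a fixed schema", {
  a <- list(age = 30, gender = "female", height = 170, weight = 60,
            smoker = FALSE, exercised_today = TRUE)
  v <- encode_attributes(a)
  expect_length(v, 9)   # 3 continuous + 2 + 2 + 2 one-hot slots
  expect_equal(sum(v[c("gender.female", "gender.male")]), 1)
  expect_equal(sum(v[c("smoker.FALSE", "smoker.TRUE")]), 1)
  a2 <- a; a2$age <- 41
  v2 <- encode_attributes(a2)
  expect_identical(unname(which(v != v2)), which(names(v) == "age"))
  expect_error(encode_attributes(modifyList(a, list(height = NULL))),
               "height")
})

test_that("assembled tensors have the documented shape and alignment", {
  feats <- small_feats()
  fs <- feats[[1]]
  expect_identical(sort(names(fs$B)), sort(c("ACC", "BVP", "EDA", "TEMP")))
  m <- sum(vapply(fs$B, ncol, numeric(1)))
  expect_equal(m, 16 + 3 + 12 + 5)
  expect_identical(ncol(fs$PF), as.integer(length(fs$A) + m))
  # row q of PF restricted to an indicator's columns equals B row q
  for (ind in names(fs$B)) {
    expect_identical(fs$PF[, colnames(fs$B[[ind]])], fs$B[[ind]])
  }
  expect_false(any(!is.finite(fs$PF)))
  # manifest is a bijection with the columns
  expect_identical(colnames(fs$PF),
                   c(fs$manifest$attributes,
                     unlist(lapply(fs$manifest$indicators, identity),
                            use.names = FALSE)))
})
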