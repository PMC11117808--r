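test_that("Morlet power has a ridge at the stimulus frequency and scales quadratically", {
  srate <- 250
  n_t <- 500
  times <- (seq_len(n_t) - 1 - 100) / srate
  sig <- sin(2 * pi * 10 * times)
  ep <- epoched_recording(array(sig, c(1, 1, n_t)), srate, times)
  tfp <- tf_power(ep, freqs = c(10, 20))
  mid <- tf_valid_times(tfp, 1, min(times), max(times))
  ridge <- mean(tfp$power[1, 1, mid])
  off <- mean(tfp$power[1, 2, mid])
  expect_gt(ridge / off, 5)
  # normalization: unit sinusoid gives ridge power ~ 1
  expect_equal(ridge, 1, tolerance = 0.05)

  # zero signal -> all-zero power; doubling amplitude quadruples power
  ep0 <- epoched_recording(array(0, c(1, 1, n_t)), srate, times)
  expect_equal(max(tf_power(ep0, c(10, 20))$power), 0)
  ep2 <- epoched_recording(array(2 * sig, c(1, 1, n_t)), srate, times)
  tfp2 <- tf_power(ep2, freqs = c(10, 20))
  expect_equal(tfp2$power, 4 * tfp$power, tolerance = 1e-10)

  # wavelet longer than the epoch is an explicit error naming the minimum
  short <- epoched_recording(array(1, c(1, 1, 50)), srate,
                             (0:49) / srate)
  expect_error(tf_power(short, 2), "epoch of at least")
})

test_that("baseline power averages pre-stimulus samples per channel and frequency", {
  srate <- 250
  n_t <- 1000
  times <- (seq_len(n_t) - 1 - 500) / srate  # -2 .. ~2 s
  ep <- epoched_recording(array(rnorm(2 * 3 * n_t), c(2, 3, n_t)), srate, times)
  tfp <- tf_power(ep, freqs = c(8, 12))

  # constant power over time -> baseline equals that constant
  tfc <- tfp
  tfc$power[] <- 7
  bp <- baseline_power(tfc, -1, 0)
  expect_equal(as.numeric(bp$power), rep(7, 4))

  # power only post-stimulus -> baseline 0
  tfz <- tfp
  tfz$power[] <- 0
  tfz$power[, , times > 0.5] <- 3
  expect_equal(max(baseline_power(tfz, -1, 0)$power), 0)

  # single-sample spike of k averaged over m samples gives k/m
  tfs <- tfp
  tfs$power[] <- 0
  sel <- tf_valid_times(tfs, 1, -1, 0)
  tfs$power[1, 1, sel[3]] <- 5
  expect_equal(baseline_power(tfs, -1, 0)$power[1, 1], 5 / length(sel))

  expect_error(baseline_power(tfp, -1, 0.5), "before t = 0")
})

test_that("distortion objective is the ratio of baseline-corrected evoked power", {
  srate <- 500
  n_t <- 1500
  times <- (seq_len(n_t) - 1 - 500) / srate
  win <- analysis_windows(0, 1, -1, 0, 9, 11)
  set.seed(71)
  base_sig <- array(rnorm(2 * 2 * n_t, sd = 0.1), c(2, 2, n_t))
  burst <- ifelse(times > 0 & times < 1, 1, 0) * sin(2 * pi * 10 * times)
  base_sig[1, , ] <- base_sig[1, , ] + rep(3 * burst, each = 2)
  base_sig[2, , ] <- base_sig[2, , ] + rep(1 * burst, each = 2)
  ep <- epoched_recording(base_sig, srate, times)
  tfp <- tf_power(ep, 9:11)
  bp <- baseline_power(tfp, -1, 0)

  # denoised identical to raw: F_B = 1 exactly
  expect_equal(as.numeric(distortion_objective(tfp, bp, tfp, bp, win)), 1)

  # denoised identically zero: F_B = 0
  zr <- tf_power(epoched_recording(array(0, dim(base_sig)), srate, times), 9:11)
  zb <- baseline_power(zr, -1, 0)
  expect_equal(as.numeric(distortion_objective(tfp, bp, zr, zb, win)), 0)
  expect_error(distortion_objective(zr, zb, tfp, bp, win), "no evoked power")

  # printed-number toy: raw per-channel summaries (4, 2), denoised (2, 1)
  mk <- function(s1, s2) {
    t2 <- tfp
    t2$power[] <- 0
    t2$power[1, , times > 0] <- s1
    t2$power[2, , times > 0] <- s2
    list(tf = t2, b = baseline_power(t2, -1, 0))
  }
  raw <- mk(4, 2); den <- mk(2, 1)
  expect_equal(as.numeric(distortion_objective(raw$tf, raw$b, den$tf, den$b, win)),
               0.5)
})

test_that("channel weights are noise-proportional, normalized and scale-invariant", {
  n_t <- 100
  set.seed(81)
  base <- rnorm(n_t)
  data <- array(0, c(2, 3, n_t))
  for (k in 1:3) {
    data[1, k, ] <- 3 * base
    data[2, k, ] <- 1 * base
  }
  ep <- epoched_recording(data, 100, (seq_len(n_t) - 50) / 100)
  w <- channel_weights(ep)
  expect_equal(w, c(0.75, 0.25))
  expect_equal(sum(w), 1)

  # identical channels -> uniform; scaling leaves weights unchanged
  data[2, , ] <- data[1, , ]
  epu <- epoched_recording(data, 100, (seq_len(n_t) - 50) / 100)
  expect_equal(channel_weights(epu), c(0.5, 0.5))
  eps <- epoched_recording(5 * data, 100, (seq_len(n_t) - 50) / 100)
  expect_equal(channel_weights(eps), channel_weights(epu))
})

test_that("noise objective is a weighted power ratio with masking weights", {
  set.seed(91)
  ep <- toy_epochs(n_ch = 2, n_tr = 5, n_t = 80, srate = 100)
  w <- c(0.5, 0.5)
  expect_equal(noise_objective(ep, ep, w), 1)

  half <- ep
  half$data <- half$data / 2
  expect_equal(noise_objective(ep, half, w), 4)

  # weight (1, 0): channel 2 cannot affect the value
  den1 <- ep; den1$data[2, , ] <- den1$data[2, , ] * 100
  den2 <- ep; den2$data[2, , ] <- 0
  expect_equal(noise_objective(ep, den1, c(1, 0)),
               noise_objective(ep, den2, c(1, 0)))

  # all power removed -> Inf sentinel
  zero <- ep; zero$data[] <- 0
  expect_equal(noise_objective(ep, zero, w), Inf)
})

test_that("degenerate threshold identities hold: x = 0 leaves both objectives at 1", {
  ds <- cached("ds_small", small_dataset(seed = 5, n_trials = 12))
  ep <- bandpass_filter(ds$epochs, 1, 40)
  er <- bandpass_filter(ds$emptyroom, 1, 40)
  win <- sim_windows()
  den0 <- ssp_apply(ep, noise_subspace_svd(er, 0))
  expect_identical(den0$data, ep$data)
  tfp <- tf_power(ep, 9:11)
  bp <- baseline_power(tfp, win$baseline_tmin, win$baseline_tmax)
  tfd <- tf_power(den0, 9:11)
  bd <- baseline_power(tfd, win$baseline_tmin, win$baseline_tmax)
  expect_equal(as.numeric(distortion_objective(tfp, bp, tfd, bd, win)), 1)
  expect_equal(noise_objective(ep, den0, channel_weights(ep)), 1)
})

test_that("threshold sweep normalizes, combines and selects as specified", {
  ds <- cached("ds_small", small_dataset(seed = 5, n_trials = 12))
  ep <- bandpass_filter(ds$epochs, 1, 40)
  er <- bandpass_filter(ds$emptyroom, 1, 40)
  win <- sim_windows()

  tr <- cached("trace_small",
               estimate_threshold(ep, er, "ssp", win, x_range = 1:6, alpha = 0.5))
  ok <- !is.na(tr$Fall)
  expect_true(all(tr$FB_norm[ok] >= -1e-12 & tr$FB_norm[ok] <= 1 + 1e-12))
  expect_true(all(tr$FN_norm[ok] >= -1e-12 & tr$FN_norm[ok] <= 2 + 1e-12))
  expect_equal(tr$Fall[ok],
               0.5 * tr$FB_norm[ok] + 0.5 * tanh(tr$FN_norm[ok]))
  expect_equal(tr$selected, tr$thresholds[which.max(tr$Fall)])
  expect_equal(sum(tr$weights), 1)

  # alpha extremes reduce to single-objective argmax (smallest-x ties)
  tr1 <- estimate_threshold(ep, er, "ssp", win, x_range = 1:6, alpha = 1)
  expect_equal(tr1$selected, tr1$thresholds[which.max(tr1$FB_norm)])
  tr0 <- estimate_threshold(ep, er, "ssp", win, x_range = 1:6, alpha = 0)
  expect_equal(tr0$selected, tr0$thresholds[which.max(tanh(tr0$FN_norm))])

  # single-candidate range: that x selected, degenerate normalization handled
  trs <- suppressWarnings(estimate_threshold(ep, er, "ssp", win, x_range = 4))
  expect_equal(trs$selected, 4L)
  expect_warning(minmax_norm_check <- sspdim:::minmax_norm(c(2, 2), 0, 1), "constant")
  expect_equal(minmax_norm_check, c(1, 1))

  # a common positive rescaling of the data leaves the trace unchanged
  ep2 <- ep; ep2$data <- ep2$data * 3.7
  tr_s <- estimate_threshold(ep2, er, "ssp", win, x_range = 1:6, alpha = 0.5)
  expect_equal(tr_s$FB_raw, tr$FB_raw, tolerance = 1e-10)
  expect_equal(tr_s$FN_raw, tr$FN_raw, tolerance = 1e-10)
  expect_equal(tr_s$selected, tr$selected)
})
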