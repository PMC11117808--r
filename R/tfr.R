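#' Morlet wavelet time-frequency power
#'
#' Convolves every channel and trial with complex Morlet wavelets and
#' averages the squared coefficient magnitude over trials, giving the
#' trial-mean induced+evoked power Y(f, t) in fT^2.  The number of cycles
#' per frequency is `max(f/2, 3)`, a common compromise between temporal
#' and spectral resolution for evoked bands around 10 Hz.  Wavelets are
#' normalized so that a unit-amplitude sinusoid at f yields power 1 at its
#' ridge.
#'
#' Samples closer than two Gaussian widths (2 sigma_t) to either epoch
#' edge are contaminated by the convolution's edge effects; the per-
#' frequency extent of that region is stored in `edge_s` and excluded by
#' the window averages in [baseline_power()] and [distortion_objective()].
#'
#' @param ep an `epoched_recording` (band-passed).
#' @param freqs frequencies of interest in Hz, within `(0, srate/2)`.
#' @return An object of class `tf_power`: `power` (channels x freqs x
#'   time, fT^2), `freqs`, `times`, `n_trials`, `edge_s` (per-frequency
#'   edge-exclusion width, seconds).
#' @export
tf_power <- function(ep, freqs) {
  stopifnot(inherits(ep, "epoched_recording"), length(freqs) >= 1)
  if (any(freqs <= 0 | freqs >= ep$srate / 2)) {
    stop("freqs must lie strictly inside (0, srate/2)")
  }
  if (ep$n_trials < 1) stop("need at least one trial")
  srate <- ep$srate
  n_ch <- dim(ep$data)[1]
  n_tr <- dim(ep$data)[2]
  n_t <- dim(ep$data)[3]

  wavelets <- lapply(freqs, function(f) {
    n_cyc <- max(f / 2, 3)
    sigma_t <- n_cyc / (2 * pi * f)
    half <- ceiling(3 * sigma_t * srate)
    if (2 * half + 1 > n_t) {
      stop(sprintf(
        "frequency %g Hz needs an epoch of at least %.3f s (%d samples); epoch has %d",
        f, (2 * half + 1) / srate, 2 * half + 1, n_t))
    }
    tt <- (-half:half) / srate
    w <- exp(-tt^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tt)
    # ridge response of unit sinusoid = (A/2) * sum(gaussian); scale to A
    w <- w * 2 / sum(exp(-tt^2 / (2 * sigma_t^2)))
    list(w = w, half = half, sigma_t = sigma_t)
  })
  max_half <- max(vapply(wavelets, function(x) as.integer(x$half), 1L))
  nfft <- stats::nextn(n_t + 2 * max_half, 2)

  wf <- lapply(wavelets, function(wl) {
    wpad <- complex(length.out = nfft)
    wpad[seq_along(wl$w)] <- wl$w
    stats::fft(wpad)
  })

  power <- array(0, dim = c(n_ch, length(freqs), n_t))
  xpad <- matrix(0, nfft, n_tr)
  for (ch in seq_len(n_ch)) {
    xpad[] <- 0
    xpad[seq_len(n_t), ] <- t(ep$data[ch, , , drop = TRUE])
    X <- stats::mvfft(xpad)
    for (j in seq_along(freqs)) {
      conv <- stats::mvfft(X * wf[[j]], inverse = TRUE) / nfft
      half <- wavelets[[j]]$half
      coef <- conv[(half + 1):(half + n_t), , drop = FALSE]
      power[ch, j, ] <- rowMeans(Mod(coef)^2)
    }
  }
  structure(
    list(power = power, freqs = as.numeric(freqs), times = ep$times,
         n_trials = n_tr,
         edge_s = vapply(wavelets, function(wl) 2 * wl$sigma_t, 0)),
    class = "tf_power"
  )
}

# Valid (edge-free) sample selector for frequency row j of a tf_power.
tf_valid_times <- function(tfp, j, tmin, tmax) {
  t0 <- min(tfp$times) + tfp$edge_s[j]
  t1 <- max(tfp$times) - tfp$edge_s[j]
  which(tfp$times >= tmin & tfp$times <= tmax &
          tfp$times >= t0 & tfp$times <= t1)
}

#' Baseline (pre-stimulus) power
#'
#' Averages time-frequency power over the pre-stimulus baseline window,
#' per channel and frequency, excluding the per-frequency wavelet edge
#' region (see [tf_power()]).
#'
#' @param tfp a `tf_power`.
#' @param baseline_tmin,baseline_tmax baseline window in seconds, ending at
#'   or before 0.
#' @return An object of class `baseline_power`: `power` (channels x
#'   freqs, fT^2) plus the window used.
#' @export
baseline_power <- function(tfp, baseline_tmin, baseline_tmax) {
  stopifnot(inherits(tfp, "tf_power"))
  if (baseline_tmax > 0) stop("baseline window must end at or before t = 0")
  if (baseline_tmax <= baseline_tmin) stop("empty baseline window")
  n_ch <- dim(tfp$power)[1]
  out <- matrix(0, n_ch, length(tfp$freqs))
  for (j in seq_along(tfp$freqs)) {
    sel <- tf_valid_times(tfp, j, baseline_tmin, baseline_tmax)
    if (length(sel) == 0) {
      stop(sprintf(
        "no baseline samples survive the %.0f ms edge exclusion at %g Hz; use a longer pre-stimulus window",
        1000 * tfp$edge_s[j], tfp$freqs[j]))
    }
    m <- tfp$power[, j, sel, drop = FALSE]
    dim(m) <- c(n_ch, length(sel))
    out[, j] <- rowMeans(m)
  }
  structure(
    list(power = out, baseline_tmin = baseline_tmin,
         baseline_tmax = baseline_tmax),
    class = "baseline_power"
  )
}
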