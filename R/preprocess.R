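#' Zero-phase band-pass filter
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' per channel.  Zero-phase filtering preserves evoked-response latencies,
#' which matters because the objectives compare pre- and post-stimulus
#' windows at fixed times.
#'
#' @param rec a `continuous_recording` or `epoched_recording`.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < srate/2`.
#' @return An object of the same class with filtered data.
#' @export
bandpass_filter <- function(rec, low, high) {
  UseMethod("bandpass_filter")
}

butter_band <- function(low, high, srate) {
  if (!(0 < low && low < high)) stop("band must satisfy 0 < low < high")
  if (high >= srate / 2) {
    stop(sprintf("band edge %g Hz is at or above the Nyquist frequency %g Hz",
                 high, srate / 2))
  }
  signal::butter(4, c(low, high) / (srate / 2), type = "pass")
}

filtfilt_rows <- function(mat, filt) {
  out <- mat
  for (i in seq_len(nrow(mat))) {
    out[i, ] <- signal::filtfilt(filt, mat[i, ])
  }
  out
}

#' @export
bandpass_filter.continuous_recording <- function(rec, low, high) {
  filt <- butter_band(low, high, rec$srate)
  rec$data <- filtfilt_rows(rec$data, filt)
  rec
}

#' @export
bandpass_filter.epoched_recording <- function(rec, low, high) {
  filt <- butter_band(low, high, rec$srate)
  d <- rec$data
  for (k in seq_len(dim(d)[2])) {
    d[, k, ] <- filtfilt_rows(d[, k, , drop = TRUE], filt)
  }
  rec$data <- d
  rec
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Cuts windows `[tmin, tmax]` (closed at both ends, sample-aligned by
#' rounding `tmin * srate` to the nearest integer) around each stimulus
#' onset.  Trials whose window would exceed the recording bounds are
#' dropped; the number dropped is reported via a message and stored in the
#' `n_dropped` attribute.
#'
#' @param rec a `continuous_recording`.
#' @param onsets stimulus onsets as 1-based sample indices; the onset sample
#'   is t = 0.
#' @param tmin,tmax epoch window in seconds relative to onset.
#' @return An `epoched_recording`; attribute `n_dropped` counts out-of-bounds
#'   trials.
#' @export
epoch <- function(rec, onsets, tmin, tmax) {
  stopifnot(inherits(rec, "continuous_recording"), tmin < tmax)
  i0 <- round(tmin * rec$srate)
  i1 <- round(tmax * rec$srate)
  n_time <- ncol(rec$data)
  onsets <- sort(as.integer(onsets))
  ok <- (onsets + i0 >= 1L) & (onsets + i1 <= n_time)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("epoch: dropped %d trial(s) whose window exceeds the recording bounds",
                    n_dropped))
  }
  onsets <- onsets[ok]
  if (length(onsets) == 0L) stop("no epoch window fits inside the recording")
  n_samp <- i1 - i0 + 1L
  data <- array(0, dim = c(nrow(rec$data), length(onsets), n_samp))
  for (k in seq_along(onsets)) {
    data[, k, ] <- rec$data[, (onsets[k] + i0):(onsets[k] + i1)]
  }
  ep <- epoched_recording(data, rec$srate, times = (i0:i1) / rec$srate,
                          channel_ids = rec$channel_ids)
  attr(ep, "n_dropped") <- n_dropped
  ep
}

#' Reject trials with excessive peak-to-peak amplitude
#'
#' A trial is removed iff any channel's peak-to-peak amplitude within the
#' epoch exceeds `threshold` (MNE-style semantics).  The rejection report
#' (removed trial indices and the offending channels for each) is attached
#' as the `rejection` attribute.
#'
#' @param ep an `epoched_recording`.
#' @param threshold peak-to-peak rejection threshold in fT; `Inf` keeps
#'   every trial.
#' @return The `epoched_recording` restricted to surviving trials.
#' @export
reject_bad_epochs <- function(ep, threshold) {
  stopifnot(inherits(ep, "epoched_recording"), threshold > 0)
  d <- ep$data
  p2p <- apply(d, c(1, 2), function(v) max(v) - min(v))  # channels x trials
  bad <- which(apply(p2p, 2, max) > threshold)
  report <- list(
    threshold_fT = threshold,
    n_in = ep$n_trials,
    n_removed = length(bad),
    removed_trials = as.integer(bad),
    offending_channels = lapply(bad, function(k) ep$channel_ids[p2p[, k] > threshold])
  )
  if (length(bad) == ep$n_trials) {
    stop(sprintf("all %d trials exceed the %g fT peak-to-peak threshold; averaging undefined",
                 ep$n_trials, threshold))
  }
  if (length(bad) > 0) {
    keep <- setdiff(seq_len(ep$n_trials), bad)
    ep <- epoched_recording(ep$data[, keep, , drop = FALSE], ep$srate,
                            ep$times, ep$channel_ids)
  }
  attr(ep, "rejection") <- report
  ep
}

#' Trial-average (evoked) waveform
#'
#' @param ep an `epoched_recording`.
#' @return channels x time matrix of the mean over trials, fT.
#' @export
evoked_average <- function(ep) {
  stopifnot(inherits(ep, "epoched_recording"))
  apply(ep$data, c(1, 3), mean)
}
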