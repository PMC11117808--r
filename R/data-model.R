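#' Sensor array geometry
#'
#' Container for an OPM magnetometer array: channel identifiers, sensor
#' positions in head-centered Cartesian coordinates (meters) and unit
#' orientation vectors giving each sensor's sensitive axis (radial for the
#' simulated helmet).
#'
#' @param channel_ids character vector of unique channel identifiers.
#' @param positions numeric matrix, one row per channel, columns x/y/z in
#'   meters.
#' @param orientations numeric matrix of unit 3-vectors, one row per channel.
#' @return An object of class `sensor_array`.
#' @export
sensor_array <- function(channel_ids, positions, orientations) {
  channel_ids <- as.character(channel_ids)
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  if (anyDuplicated(channel_ids)) {
    stop("channel_ids must be unique")
  }
  if (nrow(positions) != length(channel_ids) ||
      nrow(orientations) != length(channel_ids) ||
      ncol(positions) != 3L || ncol(orientations) != 3L) {
    stop("positions and orientations must be n_channels x 3 matrices")
  }
  if (!all(is.finite(positions))) stop("sensor positions must be finite")
  rad <- sqrt(rowSums(positions^2))
  if (any(rad <= 0)) stop("sensor positions must have |position| > 0")
  onorm <- sqrt(rowSums(orientations^2))
  if (any(abs(onorm - 1) > 1e-9)) {
    stop("orientation vectors must have unit norm (tolerance 1e-9)")
  }
  structure(
    list(channel_ids = channel_ids, positions = positions,
         orientations = orientations),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d channels, radius %.1f-%.1f cm\n",
              length(x$channel_ids),
              100 * min(sqrt(rowSums(x$positions^2))),
              100 * max(sqrt(rowSums(x$positions^2)))))
  invisible(x)
}

#' Continuous multichannel recording
#'
#' A channels x time matrix of magnetic field values in femtotesla with its
#' sampling rate.  Used both for raw (pre-epoch) data and for empty-room
#' noise recordings from which the interference subspace is estimated.
#'
#' @param data numeric matrix, channels x time samples, values in fT.
#' @param srate sampling rate in Hz.
#' @param channel_ids channel identifiers; defaults to `ch01`, `ch02`, ...
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, srate,
                                 channel_ids = sprintf("ch%02d", seq_len(nrow(data)))) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("recording data must be finite")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0) {
    stop("srate must be a positive scalar (Hz)")
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(data)) {
    stop("number of channel_ids must equal the number of data rows")
  }
  structure(
    list(data = data, srate = srate, channel_ids = channel_ids),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  invisible(x)
}

#' Epoched (trial-segmented) recording
#'
#' A channels x trials x time array of field values in fT with a
#' stimulus-relative time axis (t = 0 at stimulus onset).
#'
#' @param data numeric array channels x trials x time, fT.
#' @param srate sampling rate in Hz.
#' @param times time axis in seconds relative to stimulus onset; must be
#'   uniformly spaced at `1/srate`.
#' @param channel_ids channel identifiers.
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, srate, times,
                              channel_ids = sprintf("ch%02d", seq_len(dim(data)[1]))) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("epoched data must be channels x trials x time")
  if (!all(is.finite(data))) stop("epoched data must be finite")
  if (length(times) != dim(data)[3]) stop("length(times) must equal the time dimension")
  dt <- diff(times)
  if (any(dt <= 0) || any(abs(dt - 1 / srate) > 1e-9)) {
    stop("times must be strictly increasing and uniformly spaced at 1/srate")
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != dim(data)[1]) {
    stop("number of channel_ids must equal the channel dimension")
  }
  structure(
    list(data = data, srate = srate, times = as.numeric(times),
         channel_ids = channel_ids, n_trials = dim(data)[2]),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf("<epoched_recording> %d channels x %d trials x %d samples @ %g Hz, t in [%g, %g] s\n",
              dim(x$data)[1], x$n_trials, dim(x$data)[3], x$srate,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Analysis windows for the evoked objectives
#'
#' Time segment of the evoked component of interest, pre-stimulus baseline
#' window, and the frequency band used by the time-frequency objectives.
#'
#' @param signal_tmin,signal_tmax post-stimulus signal window, seconds.
#' @param baseline_tmin,baseline_tmax pre-stimulus baseline window, seconds
#'   (`baseline_tmax <= 0`).
#' @param fmin,fmax frequency band of interest, Hz.
#' @return An object of class `analysis_windows`.
#' @export
analysis_windows <- function(signal_tmin, signal_tmax,
                             baseline_tmin, baseline_tmax,
                             fmin, fmax) {
  if (!(baseline_tmin < baseline_tmax && baseline_tmax <= 0)) {
    stop("baseline window must satisfy baseline_tmin < baseline_tmax <= 0")
  }
  if (!(0 <= signal_tmin && signal_tmin < signal_tmax)) {
    stop("signal window must satisfy 0 <= signal_tmin < signal_tmax")
  }
  if (!(0 < fmin && fmin < fmax)) stop("band must satisfy 0 < fmin < fmax")
  structure(
    list(signal_tmin = signal_tmin, signal_tmax = signal_tmax,
         baseline_tmin = baseline_tmin, baseline_tmax = baseline_tmax,
         fmin = fmin, fmax = fmax),
    class = "analysis_windows"
  )
}

n_channels <- function(rec) {
  if (inherits(rec, "epoched_recording")) dim(rec$data)[1] else nrow(rec$data)
}
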