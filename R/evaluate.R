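#' Peak error (PE)
#'
#' Mean absolute difference between the reconstructed and simulated
#' trial-average waveforms at the peak moments of the source sine wave,
#' averaged over channels.  Both maxima and minima of the sine are used as
#' peak moments.
#'
#' @param recon,sim channels x time trial-average waveforms, fT.
#' @param times time axis in seconds shared by both.
#' @param peak_times times of the source-waveform extrema, seconds.
#' @return Scalar PE in fT; attribute `per_channel` carries the channel
#'   breakdown.
#' @export
peak_error <- function(recon, sim, times, peak_times) {
  if (!identical(dim(recon), dim(sim))) stop("recon/sim shape mismatch")
  if (length(peak_times) == 0) stop("peak_times must be non-empty")
  if (any(peak_times < min(times) | peak_times > max(times))) {
    stop("peak_times must lie within the time axis")
  }
  idx <- vapply(peak_times, function(tp) which.min(abs(times - tp)), 1L)
  diffs <- abs(recon[, idx, drop = FALSE] - sim[, idx, drop = FALSE])
  per_ch <- rowMeans(diffs)
  structure(mean(per_ch), per_channel = per_ch)
}

#' Mean absolute error (MAE)
#'
#' Mean over channels and all time samples of the absolute difference
#' between the reconstructed and simulated trial-average waveforms.
#'
#' @inheritParams peak_error
#' @return Scalar MAE in fT; attribute `per_channel` carries the channel
#'   breakdown.
#' @export
mae <- function(recon, sim) {
  if (!identical(dim(recon), dim(sim))) stop("recon/sim shape mismatch")
  per_ch <- rowMeans(abs(recon - sim))
  structure(mean(per_ch), per_channel = per_ch)
}

#' Peak moments of a sinusoidal burst
#'
#' All extrema (maxima and minima) of `sin(2 pi f t)` inside the active
#' window: `t = (2k + 1) / (4 f)`.
#'
#' @param frequency source frequency, Hz.
#' @param active_tmin,active_tmax active window, seconds.
#' @return Vector of extremum times in seconds.
#' @export
sine_peak_times <- function(frequency, active_tmin, active_tmax) {
  k <- 0:ceiling(4 * frequency * (active_tmax - active_tmin))
  tp <- active_tmin + (2 * k + 1) / (4 * frequency)
  tp[tp < active_tmax]
}

#' Equivalent current dipole fit on a spherical conductor
#'
#' Coarse-to-fine grid search: at every candidate position the optimal
#' moment is the linear least-squares solution against the radial lead
#' field (the radial moment component is unobservable and is returned as
#' the minimum-norm zero), and the position minimizing the residual norm
#' wins; a local refinement pass at 1 mm then polishes the coarse optimum.
#'
#' @param snapshot per-channel field values at the peak moment, fT.
#' @param sensors a `sensor_array` (at least 6 channels).
#' @param grid_spacing coarse grid step in meters (default 0.01).
#' @param r_max search radius in meters; default 90% of the innermost
#'   sensor radius.
#' @param refine_step refinement step in meters (default 0.001).
#' @return List with `position` (m), `moment` (nA.m), `residual`, and
#'   goodness of fit `gof` (1 - residual^2 / |snapshot|^2).
#' @export
ecd_fit <- function(snapshot, sensors, grid_spacing = 0.01, r_max = NULL,
                    refine_step = 0.001) {
  snapshot <- as.numeric(snapshot)
  n_ch <- length(sensors$channel_ids)
  if (length(snapshot) != n_ch) stop("snapshot length must equal channel count")
  if (n_ch < 6) stop("ECD fitting needs at least 6 channels")
  if (max(abs(snapshot)) == 0) stop("all-zero field snapshot; dipole fit undefined")
  if (is.null(r_max)) r_max <- 0.9 * min(sqrt(rowSums(sensors$positions^2)))

  fit_at <- function(p) {
    # lead field for unit moments along the axes, fT per nA.m
    G <- cbind(radial_lead_field(sensors, p, c(1, 0, 0)),
               radial_lead_field(sensors, p, c(0, 1, 0)),
               radial_lead_field(sensors, p, c(0, 0, 1)))
    sv <- svd(G)
    keep <- sv$d > max(sv$d) * 1e-8
    m <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], snapshot)) / sv$d[keep])
    res <- sqrt(sum((G %*% m - snapshot)^2))
    list(moment = as.numeric(m), residual = res)
  }

  ax <- seq(-r_max, r_max, by = grid_spacing)
  best <- NULL
  for (gx in ax) for (gy in ax) for (gz in ax) {
    p <- c(gx, gy, gz)
    if (sum(p^2) > r_max^2) next
    f <- fit_at(p)
    if (is.null(best) || f$residual < best$residual) {
      best <- c(f, list(position = p))
    }
  }
  # one refinement pass at refine_step around the coarse optimum
  off <- seq(-grid_spacing / 2, grid_spacing / 2, by = refine_step)
  coarse <- best
  for (dx in off) for (dy in off) for (dz in off) {
    p <- coarse$position + c(dx, dy, dz)
    if (sum(p^2) > r_max^2) next
    f <- fit_at(p)
    if (f$residual < best$residual) best <- c(f, list(position = p))
  }
  list(position = best$position, moment = best$moment,
       residual = best$residual,
       gof = 1 - best$residual^2 / sum(snapshot^2))
}

#' Localization error (LE)
#'
#' Euclidean distance between a fitted and a true dipole position,
#' reported in millimeters.
#'
#' @param fit_position,truth_position 3-vectors in meters.
#' @return Distance in mm.
#' @export
location_error <- function(fit_position, truth_position) {
  sqrt(sum((as.numeric(fit_position) - as.numeric(truth_position))^2)) * 1000
}

#' Evaluate a denoised dataset against simulation ground truth
#'
#' Computes PE and MAE between the trial-average reconstructed waveform
#' and the clean simulated waveform, and (when sensors are available) the
#' localization error of an ECD fit at the peak moment -- the sample in
#' the active window where the reconstructed average has maximal RMS
#' across channels.
#'
#' @param den denoised `epoched_recording`.
#' @param truth a `simulation_truth`.
#' @param x subspace dimension used (recorded in the report).
#' @param algorithm algorithm label (recorded in the report).
#' @param fit_le compute the ECD localization error (default TRUE).
#' @return An object of class `metrics_report`: `pe`, `mae` (fT), `le`
#'   (mm or NA), `x`, `algorithm`, plus per-channel breakdowns.
#' @export
evaluate_denoising <- function(den, truth, x = NA_integer_,
                               algorithm = NA_character_, fit_le = TRUE) {
  stopifnot(inherits(den, "epoched_recording"), inherits(truth, "simulation_truth"))
  recon <- evoked_average(den)
  sim <- evoked_average(truth$B_sim)
  src <- truth$dipole
  peaks <- sine_peak_times(src$frequency, src$active_tmin, src$active_tmax)
  pe <- peak_error(recon, sim, den$times, peaks)
  mv <- mae(recon, sim)
  le <- NA_real_
  if (fit_le && !is.null(truth$sensors)) {
    active <- den$times >= src$active_tmin & den$times < src$active_tmax
    rms_t <- sqrt(colMeans(recon[, active, drop = FALSE]^2))
    t_peak <- which(active)[which.max(rms_t)]
    fit <- ecd_fit(recon[, t_peak], truth$sensors)
    le <- location_error(fit$position, src$position)
  }
  structure(
    list(pe = as.numeric(pe), mae = as.numeric(mv), le = le,
         x = x, algorithm = algorithm,
         pe_per_channel = attr(pe, "per_channel"),
         mae_per_channel = attr(mv, "per_channel")),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s x=%s: PE %.2f fT, MAE %.2f fT, LE %s\n",
              toupper(ifelse(is.na(x$algorithm), "?", x$algorithm)),
              ifelse(is.na(x$x), "?", x$x), x$pe, x$mae,
              ifelse(is.na(x$le), "n/a", sprintf("%.2f mm", x$le))))
  invisible(x)
}
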