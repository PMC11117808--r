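#' Signal-distortion objective F_B
#'
#' Ratio of the evoked time-frequency signal after denoising to the same
#' quantity before denoising.  Per channel i, the evoked signal is
#' summarized as
#' `S_i = | mean_{f in band, t in signal window} Y_i(f,t) - mean_{f in band} N_i(f) |`,
#' the band/segment-averaged wavelet power minus the band-averaged
#' baseline power; F_B is the channel-mean of the denoised summaries over
#' the channel-mean of the raw summaries.  F_B = 1 means no distortion,
#' 0 means the evoked response was removed entirely.
#'
#' @param tf_raw,base_raw [tf_power()] and [baseline_power()] of the raw
#'   epochs.
#' @param tf_den,base_den the same quantities computed on denoised epochs
#'   (wavelet power is quadratic, so it must be recomputed, not projected).
#' @param win an [analysis_windows()] giving the signal window and band.
#' @return A positive scalar; attribute `per_channel` carries the raw and
#'   denoised per-channel summaries.
#' @export
distortion_objective <- function(tf_raw, base_raw, tf_den, base_den, win) {
  stopifnot(inherits(tf_raw, "tf_power"), inherits(tf_den, "tf_power"),
            inherits(win, "analysis_windows"))
  if (!isTRUE(all.equal(tf_raw$freqs, tf_den$freqs)) ||
      !isTRUE(all.equal(tf_raw$times, tf_den$times))) {
    stop("raw and denoised time-frequency grids must be identical")
  }
  s_raw <- evoked_band_summary(tf_raw, base_raw, win)
  s_den <- evoked_band_summary(tf_den, base_den, win)
  if (mean(s_raw) == 0) {
    stop("no evoked power in selected window: raw baseline-corrected power is zero")
  }
  structure(mean(s_den) / mean(s_raw),
            per_channel = list(raw = s_raw, denoised = s_den))
}

evoked_band_summary <- function(tfp, base, win) {
  band <- which(tfp$freqs >= win$fmin & tfp$freqs <= win$fmax)
  if (length(band) == 0) stop("analysis band contains no wavelet frequencies")
  n_ch <- dim(tfp$power)[1]
  y <- matrix(0, n_ch, length(band))
  for (jj in seq_along(band)) {
    j <- band[jj]
    sel <- tf_valid_times(tfp, j, win$signal_tmin, win$signal_tmax)
    if (length(sel) == 0) {
      stop(sprintf("no signal-window samples survive edge exclusion at %g Hz",
                   tfp$freqs[j]))
    }
    m <- tfp$power[, j, sel, drop = FALSE]
    dim(m) <- c(n_ch, length(sel))
    y[, jj] <- rowMeans(m)
  }
  abs(rowMeans(y) - rowMeans(base$power[, band, drop = FALSE]))
}

#' Noise-level channel weights
#'
#' `w_i = sigma_i / sum(sigma)`, where `sigma_i` is the standard deviation
#' of channel i over all trials and time samples of the raw band-passed
#' epochs.  Noisier channels therefore weigh more in the noise-suppression
#' objective.  Weights sum to 1 and are invariant to a common rescaling of
#' the data.
#'
#' @param ep an `epoched_recording` (raw, pre-denoising).
#' @return Numeric vector of per-channel weights summing to 1.
#' @export
channel_weights <- function(ep) {
  stopifnot(inherits(ep, "epoched_recording"))
  n_ch <- dim(ep$data)[1]
  sds <- vapply(seq_len(n_ch), function(i) stats::sd(as.vector(ep$data[i, , ])), 0)
  tot <- sum(sds)
  if (tot == 0) stop("all channels are constant; weights undefined")
  sds / tot
}

#' Noise-suppression objective F_N
#'
#' Because environmental interference dominates the total power of raw
#' evoked MEG data, total signal power stands in for the noise level.  Per
#' channel, `f_N(i)` is the trial-mean of the summed squared samples over
#' the full epoch; `F_N = sum(w_i f_N(i)) / sum(w_i f_N_hat(i))` with the
#' denoised power in the denominator, so larger F_N means more power
#' removed.  F_N = 1 when nothing was removed.  If denoising removed all
#' (weighted) power, `Inf` is returned; normalization in
#' [estimate_threshold()] maps it to the top of the range.
#'
#' @param raw,den raw and denoised `epoched_recording`s of identical shape.
#' @param weights per-channel weights from [channel_weights()].
#' @return A positive scalar (possibly `Inf`).
#' @export
noise_objective <- function(raw, den, weights) {
  stopifnot(inherits(raw, "epoched_recording"), inherits(den, "epoched_recording"))
  if (!identical(dim(raw$data), dim(den$data))) stop("raw/denoised shape mismatch")
  n_ch <- dim(raw$data)[1]
  if (length(weights) != n_ch) stop("weights length must equal channel count")
  f_n <- function(ep) {
    vapply(seq_len(n_ch), function(i) {
      mean(rowSums(matrix(ep$data[i, , ], nrow = ep$n_trials)^2))
    }, 0)
  }
  num <- sum(weights * f_n(raw))
  den_p <- sum(weights * f_n(den))
  if (den_p == 0) return(Inf)
  num / den_p
}

# Min-max normalization to [lo, hi].  Inf sentinels map to hi; a degenerate
# spread (max == min) maps everything to 1 with a warning.
minmax_norm <- function(v, lo, hi) {
  fin <- is.finite(v)
  if (!any(fin)) {
    warning("all objective values are non-finite; normalized to 1")
    return(rep(1, length(v)))
  }
  mn <- min(v[fin]); mx <- max(v[fin])
  out <- numeric(length(v))
  if (mx == mn) {
    if (any(!fin)) {
      out[fin] <- lo + (hi - lo) * 0  # degenerate finite values at the bottom
      out[!fin] <- hi
      warning("degenerate objective spread with Inf sentinel present")
    } else {
      warning("objective is constant over the threshold range; normalized to 1")
      out[] <- 1
    }
  } else {
    out[fin] <- lo + (hi - lo) * (v[fin] - mn) / (mx - mn)
    out[!fin] <- hi
  }
  out
}

#' Sweep candidate subspace dimensions and select the optimum
#'
#' The core estimator.  For every candidate dimension x in `x_range` it
#' builds the interference subspace from the empty-room noise, denoises
#' the epochs, and computes the distortion objective F_B(x) and the
#' noise-suppression objective F_N(x).  F_B is then min-max normalized to
#' \[0, 1\] and F_N to \[0, 2\] over the range, and the total objective
#'
#'   `F_all(x) = alpha * F_B_norm(x) + (1 - alpha) * tanh(F_N_norm(x))`
#'
#' is maximized by simple traversal; the hyperbolic tangent saturates the
#' noise term so that large noise-suppression gains cannot mask serious
#' signal distortion.  Ties are broken toward the smallest x (less
#' projection, less distortion risk).
#'
#' The epochs and the empty-room noise are expected to be band-pass
#' filtered identically beforehand (as [run_pipeline()] does); pass
#' `bandpass = c(low, high)` to have this function filter both.
#'
#' @param ep raw `epoched_recording`.
#' @param noise empty-room `continuous_recording`.
#' @param algorithm `"ssp"` (spatial) or `"s3p"` (spectral).
#' @param win an [analysis_windows()].
#' @param x_range integer candidate dimensions (default 1:10).
#' @param alpha balance weight in \[0, 1\] between distortion (alpha) and
#'   noise suppression (1 - alpha); default 0.5.
#' @param bandpass optional `c(low, high)` Hz applied to both inputs.
#' @param s3p_band frequency band for the S3P subspace and projection;
#'   defaults to `bandpass` when given, else the analysis band widened to
#'   the full filtered range cannot be inferred, so `c(win$fmin, win$fmax)`.
#' @param freqs wavelet frequency grid; default integer Hz steps spanning
#'   the analysis band.
#' @return An object of class `objective_trace` with per-threshold raw and
#'   normalized objectives, `Fall`, the `selected` dimension, `alpha`,
#'   channel `weights`, and any per-threshold failures.
#' @export
estimate_threshold <- function(ep, noise, algorithm = c("ssp", "s3p"), win,
                               x_range = 1:10, alpha = 0.5,
                               bandpass = NULL, s3p_band = NULL,
                               freqs = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(ep, "epoched_recording"),
            inherits(noise, "continuous_recording"),
            inherits(win, "analysis_windows"))
  x_range <- sort(unique(as.integer(x_range)))
  if (length(x_range) == 0) stop("x_range must be non-empty")
  if (max(x_range) > n_channels(ep)) stop("x_range exceeds the channel count")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!is.null(bandpass)) {
    ep <- bandpass_filter(ep, bandpass[1], bandpass[2])
    noise <- bandpass_filter(noise, bandpass[1], bandpass[2])
  }
  if (is.null(s3p_band)) {
    s3p_band <- if (!is.null(bandpass)) bandpass else c(win$fmin, win$fmax)
  }
  if (is.null(freqs)) freqs <- seq(ceiling(win$fmin), floor(win$fmax))

  weights <- channel_weights(ep)
  tf_raw <- tf_power(ep, freqs)
  base_raw <- baseline_power(tf_raw, win$baseline_tmin, win$baseline_tmax)

  # One spectral decomposition serves every candidate dimension.
  full_sub <- if (algorithm == "ssp") {
    noise_subspace_svd(noise, max(x_range))
  } else {
    s3p_subspace(noise, max(x_range), s3p_band)
  }
  slice_sub <- function(x) {
    basis <- full_sub$basis[, seq_len(min(x, ncol(full_sub$basis))), drop = FALSE]
    interference_subspace(basis, full_sub$singular_values,
                          algorithm = algorithm, band = full_sub$band)
  }

  FB <- FN <- rep(NA_real_, length(x_range))
  errors <- character(length(x_range))
  for (i in seq_along(x_range)) {
    res <- tryCatch({
      sub <- slice_sub(x_range[i])
      den <- denoise(ep, sub)
      tf_den <- tf_power(den, freqs)
      base_den <- baseline_power(tf_den, win$baseline_tmin, win$baseline_tmax)
      fb <- as.numeric(distortion_objective(tf_raw, base_raw, tf_den, base_den, win))
      fn <- noise_objective(ep, den, weights)
      c(fb, fn)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[i] <- conditionMessage(res)
    } else {
      FB[i] <- res[1]; FN[i] <- res[2]
    }
  }
  ok <- !is.na(FB)
  if (sum(ok) == 0 || (length(x_range) > 1 && sum(ok) < 2)) {
    stop("threshold sweep failed: ", paste(unique(errors[nzchar(errors)]), collapse = "; "))
  }

  FBn <- FNn <- Fall <- rep(NA_real_, length(x_range))
  FBn[ok] <- minmax_norm(FB[ok], 0, 1)
  FNn[ok] <- minmax_norm(FN[ok], 0, 2)
  Fall[ok] <- alpha * FBn[ok] + (1 - alpha) * tanh(FNn[ok])
  selected <- x_range[which.max(Fall)]  # ascending x_range: first max = smallest x

  structure(
    list(thresholds = x_range, FB_raw = FB, FN_raw = FN,
         FB_norm = FBn, FN_norm = FNn, Fall = Fall,
         alpha = alpha, selected = selected, weights = weights,
         algorithm = algorithm, failed = errors[nzchar(errors)],
         s3p_band = if (algorithm == "s3p") s3p_band else NULL),
    class = "objective_trace"
  )
}

#' @export
print.objective_trace <- function(x, ...) {
  cat(sprintf("<objective_trace> %s sweep over x = %d..%d, alpha = %g\n",
              toupper(x$algorithm), min(x$thresholds), max(x$thresholds), x$alpha))
  tab <- data.frame(x = x$thresholds, FB = x$FB_raw, FN = x$FN_raw,
                    FB_norm = x$FB_norm, FN_norm = x$FN_norm, Fall = x$Fall)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("selected x = %d\n", x$selected))
  invisible(x)
}

#' Tabular export of an objective trace
#'
#' @param trace an `objective_trace`.
#' @param path optional file; when given, a whitespace-aligned table with
#'   columns x, FB, FN, Fall is written there.
#' @return The trace as a `data.frame`, invisibly when writing.
#' @export
trace_table <- function(trace, path = NULL) {
  tab <- data.frame(x = trace$thresholds, FB = trace$FB_raw,
                    FN = trace$FN_raw, Fall = trace$Fall)
  if (!is.null(path)) {
    utils::write.table(format(tab, digits = 8), path, quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
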