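#' Interference subspace
#'
#' An orthonormal channel-space basis spanning the interference (external)
#' subspace, together with the full singular/eigen spectrum it was cut
#' from.  `x = ncol(basis)` is the subspace dimension -- the threshold this
#' package selects automatically.
#'
#' @param basis channels x x matrix with orthonormal columns (may have zero
#'   columns for `x = 0`).
#' @param singular_values full non-increasing spectrum, for diagnostics.
#' @param algorithm `"ssp"` or `"s3p"`.
#' @param band optional frequency band (Hz, length 2); S3P only.
#' @return An object of class `interference_subspace`.
#' @export
interference_subspace <- function(basis, singular_values,
                                  algorithm = c("ssp", "s3p"), band = NULL) {
  algorithm <- match.arg(algorithm)
  basis <- as.matrix(basis)
  x <- ncol(basis)
  if (x > 0) {
    g <- crossprod(basis)
    if (max(abs(g - diag(x))) > 1e-10) {
      stop("basis columns must be orthonormal (tolerance 1e-10)")
    }
  }
  sv <- as.numeric(singular_values)
  if (any(sv < -1e-12) || is.unsorted(rev(sv))) {
    stop("singular_values must be non-negative and non-increasing")
  }
  if (x > nrow(basis)) stop("subspace dimension exceeds the number of channels")
  structure(
    list(basis = basis, singular_values = sv, x = x,
         algorithm = algorithm, band = band),
    class = "interference_subspace"
  )
}

#' @export
print.interference_subspace <- function(x, ...) {
  cat(sprintf("<interference_subspace> %s, dimension %d of %d channels\n",
              toupper(x$algorithm), x$x, nrow(x$basis)))
  invisible(x)
}

# Reproducible sign convention: flip each column so its largest-magnitude
# entry is positive.
fix_signs <- function(basis) {
  for (j in seq_len(ncol(basis))) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  basis
}

#' Estimate the interference subspace by SVD of empty-room noise (SSP)
#'
#' Takes the left (channel-space) singular vectors of the channels x time
#' empty-room matrix, ordered by decreasing singular value; the top `x`
#' form the interference basis removed by [ssp_apply()].
#'
#' @param noise a `continuous_recording` of empty-room data with at least
#'   as many time samples as channels.
#' @param x requested subspace dimension, `0 <= x <= channels`.
#' @return An `interference_subspace` (algorithm `"ssp"`).
#' @export
noise_subspace_svd <- function(noise, x) {
  stopifnot(inherits(noise, "continuous_recording"))
  n_ch <- nrow(noise$data)
  if (x < 0 || x > n_ch) stop("x must satisfy 0 <= x <= number of channels")
  if (ncol(noise$data) < n_ch) {
    stop("empty-room recording needs at least as many time samples as channels")
  }
  sv <- svd(noise$data, nu = n_ch, nv = 0)
  tol <- max(dim(noise$data)) * .Machine$double.eps * sv$d[1]
  if (x > sum(sv$d > tol)) {
    warning(sprintf("requested dimension %d exceeds the numerical rank %d of the noise matrix",
                    x, sum(sv$d > tol)))
  }
  basis <- fix_signs(sv$u[, seq_len(x), drop = FALSE])
  interference_subspace(basis, sv$d, algorithm = "ssp")
}

project_out <- function(mat, basis) {
  if (ncol(basis) == 0) return(mat)
  mat - basis %*% crossprod(basis, mat)
}

#' Apply spatial subspace projection (SSP)
#'
#' Replaces every time-sample channel vector y by `(I - F F') y`, i.e.
#' projects the data onto the complement of the interference subspace.
#' Epoched input is projected per trial.
#'
#' @param rec a `continuous_recording` or `epoched_recording`.
#' @param sub an `interference_subspace` with matching channel dimension.
#' @return A recording of the same class; the subspace used is attached as
#'   the `subspace` attribute.
#' @export
ssp_apply <- function(rec, sub) {
  stopifnot(inherits(sub, "interference_subspace"))
  if (nrow(sub$basis) != n_channels(rec)) {
    stop(sprintf("subspace has %d channels but recording has %d",
                 nrow(sub$basis), n_channels(rec)))
  }
  if (inherits(rec, "continuous_recording")) {
    rec$data <- project_out(rec$data, sub$basis)
  } else if (inherits(rec, "epoched_recording")) {
    d <- rec$data
    dm <- dim(d)
    flat <- matrix(d, nrow = dm[1])  # channels x (trials*time)
    rec$data <- array(project_out(flat, sub$basis), dim = dm)
  } else {
    stop("unsupported recording class")
  }
  attr(rec, "subspace") <- sub
  rec
}

# Welch cross-spectral density, averaged over the Fourier bins inside band.
# 1 s Hann segments, 50% overlap.
welch_csd_band <- function(data, srate, band, seg_seconds = 1) {
  n_ch <- nrow(data)
  n_time <- ncol(data)
  nseg <- min(round(seg_seconds * srate), n_time)
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, n_time - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / nseg)  # Hann
  freqs <- (seq_len(nseg) - 1) / nseg * srate
  bins <- which(freqs >= band[1] & freqs <= band[2] & freqs <= srate / 2)
  if (length(bins) == 0) {
    stop(sprintf("band [%g, %g] Hz contains no Fourier bins at a %g-sample segment",
                 band[1], band[2], nseg))
  }
  S <- matrix(0 + 0i, n_ch, n_ch)
  for (s0 in starts) {
    seg <- data[, s0:(s0 + nseg - 1L), drop = FALSE] *
      rep(win, each = n_ch)
    X <- t(stats::mvfft(t(seg)))  # channels x freq bins
    for (b in bins) {
      v <- X[, b]
      S <- S + v %*% Conj(t(v))
    }
  }
  S / (length(starts) * length(bins))
}

# Resolve complex eigenvectors to a real orthonormal basis.  Each vector is
# first rotated by the phase of its largest-magnitude entry; if a
# significant imaginary part remains (phase-shifted interference across
# channels), both real and imaginary parts are kept.  The threshold is
# relative to the real part so that Welch estimation noise (a few percent
# of the eigenvector norm for hundreds of segments) does not spuriously
# double the dimension.  QR then orthonormalizes.
complexify_to_real <- function(vectors, tol = 0.1) {
  cols <- list()
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j]
    i <- which.max(Mod(v))
    v <- v * Conj(v[i]) / Mod(v[i])
    re <- Re(v); im <- Im(v)
    cols <- c(cols, list(re))
    if (sqrt(sum(im^2)) > tol * sqrt(sum(re^2))) cols <- c(cols, list(im))
  }
  m <- do.call(cbind, cols)
  qr_d <- qr(m)
  keep <- seq_len(qr_d$rank)
  fix_signs(qr.Q(qr_d)[, keep, drop = FALSE])
}

#' Estimate the interference subspace from the noise cross-spectral density (S3P)
#'
#' Estimates the Hermitian cross-spectral density of the empty-room noise
#' by Welch's method (1 s Hann segments, 50% overlap), averages it over the
#' Fourier bins inside `band`, and takes the top-`x` eigenvectors as the
#' spectral interference basis.  When the CSD's imaginary part is small
#' relative to its real part (instantaneously mixed interference; the
#' imaginary part is then Welch estimation noise), the real part -- the
#' average of the CSD over positive and negative frequencies -- is
#' eigendecomposed directly, giving a stable real basis even under
#' eigenvalue degeneracy.  Otherwise (interference genuinely phase-shifted
#' across channels) the complex eigenvectors are resolved to a real
#' orthonormal basis, keeping the imaginary part as an extra direction
#' where it is substantial, so the returned dimension can exceed `x`.
#'
#' @inheritParams noise_subspace_svd
#' @param band frequency band in Hz (length 2) within `(0, srate/2)`.
#' @return An `interference_subspace` (algorithm `"s3p"`); eigenvalues of
#'   the band-averaged CSD are reported in `singular_values`.
#' @export
s3p_subspace <- function(noise, x, band) {
  stopifnot(inherits(noise, "continuous_recording"), length(band) == 2)
  n_ch <- nrow(noise$data)
  if (x < 0 || x > n_ch) stop("x must satisfy 0 <= x <= number of channels")
  if (band[1] <= 0 || band[2] >= noise$srate / 2 || band[1] >= band[2]) {
    stop("band must lie strictly inside (0, srate/2)")
  }
  S <- welch_csd_band(noise$data, noise$srate, band)
  im_ratio <- sqrt(sum(Im(S)^2) / sum(Re(S)^2))
  if (im_ratio <= 0.1) {
    e <- eigen(Re(S), symmetric = TRUE)
    vals <- pmax(e$values, 0)
    basis <- if (x == 0) matrix(0, n_ch, 0) else
      fix_signs(e$vectors[, seq_len(x), drop = FALSE])
  } else {
    e <- eigen(S, symmetric = TRUE)
    vals <- pmax(Re(e$values), 0)
    basis <- if (x == 0) matrix(0, n_ch, 0) else
      complexify_to_real(as.matrix(e$vectors[, seq_len(x), drop = FALSE]))
  }
  interference_subspace(basis, vals, algorithm = "s3p", band = band)
}

#' Apply spectral subspace projection (S3P)
#'
#' Fourier-transforms each channel (per trial for epoched input), projects
#' the channel-vector of Fourier coefficients at every bin inside
#' `sub$band` onto the complement of the interference basis, leaves
#' out-of-band bins untouched, and inverse-transforms.  The projector is
#' real and is applied at both positive and negative frequencies, so the
#' output is real to machine precision.
#'
#' @inheritParams ssp_apply
#' @return A recording of the same class.
#' @export
s3p_apply <- function(rec, sub) {
  stopifnot(inherits(sub, "interference_subspace"))
  if (is.null(sub$band)) stop("s3p_apply needs a subspace with a frequency band")
  if (nrow(sub$basis) != n_channels(rec)) {
    stop(sprintf("subspace has %d channels but recording has %d",
                 nrow(sub$basis), n_channels(rec)))
  }
  proj_mat <- function(mat, srate) {
    n <- ncol(mat)
    f_alias <- pmin(0:(n - 1), n - (0:(n - 1))) / n * srate
    idx <- which(f_alias >= sub$band[1] & f_alias <= sub$band[2])
    if (length(idx) == 0 || ncol(sub$basis) == 0) return(mat)
    X <- stats::mvfft(t(mat))               # freq x channels
    X[idx, ] <- X[idx, ] - (X[idx, , drop = FALSE] %*% sub$basis) %*% t(sub$basis)
    y <- stats::mvfft(X, inverse = TRUE) / n
    if (max(abs(Im(y))) > 1e-9 * max(1, max(abs(Re(y))))) {
      stop("S3P output has a non-negligible imaginary part; projection is inconsistent")
    }
    t(Re(y))
  }
  if (inherits(rec, "continuous_recording")) {
    rec$data <- proj_mat(rec$data, rec$srate)
  } else if (inherits(rec, "epoched_recording")) {
    d <- rec$data
    for (k in seq_len(dim(d)[2])) {
      d[, k, ] <- proj_mat(d[, k, , drop = TRUE], rec$srate)
    }
    rec$data <- d
  } else {
    stop("unsupported recording class")
  }
  attr(rec, "subspace") <- sub
  rec
}

#' Denoise with either algorithm
#'
#' Dispatches to [ssp_apply()] or [s3p_apply()] according to
#' `sub$algorithm`.
#'
#' @inheritParams ssp_apply
#' @export
denoise <- function(rec, sub) {
  if (sub$algorithm == "ssp") ssp_apply(rec, sub) else s3p_apply(rec, sub)
}

#' Export a subspace for audit
#'
#' Writes the basis and singular spectrum both as JSON
#' (`<prefix>.json`: algorithm, dimension, band, singular values, basis
#' columns) and as columnar text (`<prefix>_basis.txt`, one row per
#' channel; `<prefix>_values.txt`, one singular value per line).
#'
#' @param sub an `interference_subspace`.
#' @param prefix output path prefix.
#' @return The JSON path, invisibly.
#' @export
write_subspace <- function(sub, prefix) {
  stopifnot(inherits(sub, "interference_subspace"))
  jsonlite::write_json(
    list(algorithm = sub$algorithm, x = sub$x, band = sub$band,
         singular_values = sub$singular_values,
         basis = apply(sub$basis, 2, identity, simplify = FALSE)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(sub$basis, paste0(prefix, "_basis.txt"),
                     row.names = FALSE, col.names = FALSE)
  writeLines(format(sub$singular_values, digits = 17),
             paste0(prefix, "_values.txt"))
  invisible(paste0(prefix, ".json"))
}
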