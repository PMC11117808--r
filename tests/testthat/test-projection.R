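test_that("SVD noise subspace recovers known spatial structure", {
  srate <- 100
  # rank-1 noise: outer(u, s(t))
  u <- c(0.6, 0.8, 0)
  s_t <- sin(seq(0, 20, length.out = 500))
  noise <- continuous_recording(outer(u, s_t), srate)
  sub <- noise_subspace_svd(noise, 1)
  expect_equal(abs(as.numeric(crossprod(sub$basis, u))), 1, tolerance = 1e-8)

  # x = 0 gives an empty basis
  sub0 <- noise_subspace_svd(noise, 0)
  expect_equal(ncol(sub0$basis), 0)

  # independent eigendecomposition oracle: top-2 eigenvectors of the
  # channel covariance span the same subspace as the SVD basis
  set.seed(7)
  m <- matrix(rnorm(4 * 50), 4)
  noise2 <- continuous_recording(m, srate)
  sub2 <- noise_subspace_svd(noise2, 2)
  ev <- eigen(tcrossprod(m), symmetric = TRUE)$vectors[, 1:2]
  overlap <- svd(crossprod(sub2$basis, ev))$d
  expect_equal(overlap, c(1, 1), tolerance = 1e-10)

  expect_error(noise_subspace_svd(noise2, 5), "0 <= x")
  expect_warning(noise_subspace_svd(noise, 3), "numerical rank")
  expect_error(noise_subspace_svd(continuous_recording(matrix(1, 4, 3), 10), 1),
               "at least as many time samples")
})

test_that("SSP projector satisfies annihilation, identity and idempotence", {
  set.seed(11)
  noise <- continuous_recording(matrix(rnorm(5 * 100), 5), 100)
  rec <- continuous_recording(matrix(rnorm(5 * 40), 5), 100)

  # x = 0: exact identity
  expect_identical(ssp_apply(rec, noise_subspace_svd(noise, 0))$data, rec$data)

  # a sample lying inside span(F_x) is annihilated
  sub <- noise_subspace_svd(noise, 2)
  inside <- continuous_recording(sub$basis %*% matrix(rnorm(2 * 10), 2), 100)
  out <- ssp_apply(inside, sub)
  expect_lt(max(abs(out$data)), 1e-10)

  # idempotence
  once <- ssp_apply(rec, sub)
  twice <- ssp_apply(once, sub)
  expect_lt(max(abs(twice$data - once$data)), 1e-10)

  # channel mismatch is rejected
  small <- continuous_recording(matrix(rnorm(3 * 20), 3), 100)
  expect_error(ssp_apply(small, sub), "channels")
})

test_that("projector algebra holds for random channel counts", {
  set.seed(21)
  for (n_ch in c(5, 12, 31)) {
    noise <- continuous_recording(matrix(rnorm(n_ch * 200), n_ch), 100)
    x <- sample(0:n_ch, 1)
    sub <- noise_subspace_svd(noise, x)
    P <- sub$basis %*% t(sub$basis)
    expect_lt(max(abs(P %*% P - P)), 1e-10)
    expect_lt(max(abs(P - t(P))), 1e-10)
    y <- rnorm(n_ch)
    expect_lte(sqrt(sum(((diag(n_ch) - P) %*% y)^2)), sqrt(sum(y^2)) + 1e-12)
  }
})

test_that("SSP matches a brute-force Gram-Schmidt oracle on small matrices", {
  # oracle: orthonormalize the top singular directions by explicit
  # Gram-Schmidt, then subtract projections one vector at a time
  gram_schmidt <- function(vs) {
    basis <- NULL
    for (j in seq_len(ncol(vs))) {
      v <- vs[, j]
      if (!is.null(basis)) {
        for (k in seq_len(ncol(basis))) v <- v - sum(v * basis[, k]) * basis[, k]
      }
      nv <- sqrt(sum(v^2))
      if (nv > 1e-12) basis <- cbind(basis, v / nv)
    }
    basis
  }
  brute_ssp <- function(data, noise, x) {
    B <- gram_schmidt(svd(noise)$u[, seq_len(x), drop = FALSE])
    out <- data
    for (t in seq_len(ncol(data))) {
      y <- data[, t]
      for (k in seq_len(ncol(B))) y <- y - sum(y * B[, k]) * B[, k]
      out[, t] <- y
    }
    out
  }
  set.seed(31)
  for (rep in 1:5) {
    n_ch <- sample(3:5, 1); n_t <- sample(10:20, 1)
    noise_m <- matrix(rnorm(n_ch * 30), n_ch)
    data_m <- matrix(rnorm(n_ch * n_t), n_ch)
    x <- sample(1:(n_ch - 1), 1)
    got <- ssp_apply(continuous_recording(data_m, 10),
                     noise_subspace_svd(continuous_recording(noise_m, 10), x))$data
    expect_lt(max(abs(got - brute_ssp(data_m, noise_m, x))), 1e-8)
  }
})

test_that("SSP output power is non-increasing in x and zero at x = channels", {
  set.seed(41)
  n_ch <- 8
  noise <- continuous_recording(matrix(rnorm(n_ch * 300), n_ch), 100)
  rec <- continuous_recording(matrix(rnorm(n_ch * 50), n_ch), 100)
  pw <- vapply(0:n_ch, function(x) {
    sum(ssp_apply(rec, noise_subspace_svd(noise, x))$data^2)
  }, 0)
  expect_true(all(diff(pw) <= 1e-9))
  expect_lt(pw[n_ch + 1], 1e-18 * pw[1] + 1e-20)
})

test_that("S3P subspace matches spatial structure of narrowband and broadband noise", {
  srate <- 200
  set.seed(51)
  # unit spatial pattern times an in-band tone
  u <- rnorm(6); u <- u / sqrt(sum(u^2))
  tone <- sin(2 * pi * 11 * seq(0, 60, by = 1 / srate))
  noise <- continuous_recording(outer(u, tone) +
                                  matrix(rnorm(6 * length(tone), sd = 1e-3), 6),
                                srate)
  sub <- s3p_subspace(noise, 1, band = c(9, 13))
  expect_equal(abs(as.numeric(crossprod(sub$basis[, 1], u))), 1, tolerance = 1e-4)

  # white spatially-uncorrelated noise: leading eigenvalue close to the mean
  white <- continuous_recording(matrix(rnorm(6 * 200 * srate), 6), srate)
  subw <- s3p_subspace(white, 1, band = c(5, 45))
  expect_lt(subw$singular_values[1] / mean(subw$singular_values), 2)

  # band covering the full spectrum on broadband low-rank noise: same
  # subspace as the SVD route (principal angles < 5 degrees)
  pats <- qr.Q(qr(matrix(rnorm(6 * 2), 6)))
  tc <- matrix(rnorm(2 * 100 * srate), 2)
  lowrank <- continuous_recording(pats %*% tc +
                                    matrix(rnorm(6 * 100 * srate, sd = 0.01), 6),
                                  srate)
  s_spec <- s3p_subspace(lowrank, 2, band = c(1, 95))
  s_svd <- noise_subspace_svd(lowrank, 2)
  ang <- acos(pmin(svd(crossprod(s_svd$basis, s_spec$basis))$d, 1)) * 180 / pi
  expect_lt(max(ang), 5)

  expect_error(s3p_subspace(noise, 1, band = c(99, 120)), "inside")
})

test_that("S3P projection acts only inside its band and returns real data", {
  srate <- 200
  set.seed(61)
  u <- rnorm(5); u <- u / sqrt(sum(u^2))
  t_ax <- seq(0, 2 - 1 / srate, by = 1 / srate)

  noise <- continuous_recording(outer(u, sin(2 * pi * 10 * t_ax)) +
                                  matrix(rnorm(5 * length(t_ax), sd = 1e-3), 5),
                                srate)
  sub <- s3p_subspace(noise, 1, band = c(8, 12))
  sub0 <- s3p_subspace(noise, 0, band = c(8, 12))

  # x = 0: identity
  rec <- continuous_recording(matrix(rnorm(5 * length(t_ax)), 5), srate)
  expect_lt(max(abs(s3p_apply(rec, sub0)$data - rec$data)), 1e-9)

  # in-band tone with the noise pattern is annihilated
  inband <- continuous_recording(outer(u, sin(2 * pi * 10 * t_ax)), srate)
  res <- s3p_apply(inband, sub)
  expect_lt(sum(res$data^2) / sum(inband$data^2), 1e-6)

  # out-of-band signal passes through unchanged even with the same pattern
  outband <- continuous_recording(outer(u, sin(2 * pi * 30 * t_ax)), srate)
  passed <- s3p_apply(outband, sub)
  expect_lt(max(abs(passed$data - outband$data)), 1e-9)
})

test_that("subspace export writes matching JSON and columnar text", {
  tmp <- withr::local_tempdir()
  noise <- continuous_recording(matrix(rnorm(4 * 60), 4), 100)
  sub <- noise_subspace_svd(noise, 2)
  p <- write_subspace(sub, file.path(tmp, "sub"))
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$x, 2)
  expect_equal(j$singular_values, sub$singular_values)
  expect_equal(t(j$basis), sub$basis, ignore_attr = TRUE)
  bt <- as.matrix(read.table(file.path(tmp, "sub_basis.txt")))
  expect_equal(bt, sub$basis, tolerance = 1e-6, ignore_attr = TRUE)
})
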