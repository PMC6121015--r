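test_that("windowed-variance outliers are flagged exactly (GESD oracle)", {
  set.seed(5)
  fs <- 100
  x <- matrix(rnorm(3000 * 3), 3000, 3)
  x[501:600, ] <- x[501:600, ] * 100  # window 6 of 30
  ts <- parcel_ts(x, fs)
  mask <- detect_bad_segments(ts, window_s = 1)
  expect_true(all(mask[501:600]))
  expect_true(all(!mask[-(501:600)]))

  # direct-formula oracle on the window statistic vector
  stats <- vapply(seq(1, 3000, 100), function(s) sd(x[s:(s + 99), ]), 0)
  expect_identical(oracle_gesd(stats, 0.05, 6L), 6L)
})

test_that("GESD respects its cap, ties and degenerate input", {
  set.seed(6)
  x <- matrix(rnorm(2000), 2000, 1)
  ts <- parcel_ts(x, 100)
  mask <- detect_bad_segments(ts, window_s = 1, max_prop = 0.2)
  runs <- rle(mask)
  expect_lte(sum(runs$values), floor(0.2 * 20))

  # identical window statistics cannot be rejected
  y <- matrix(rep(sin(seq_len(100) / 5), 10), ncol = 1)
  expect_equal(sum(detect_bad_segments(parcel_ts(y, 100), window_s = 1)), 0)

  expect_error(detect_bad_segments(parcel_ts(matrix(1, 500, 2), 100)),
               "degenerate variance")
  expect_error(detect_bad_segments(parcel_ts(matrix(rnorm(400), 200, 2), 100)),
               "at least 3 windows")
})

test_that("symmetric orthogonalisation removes zero-lag correlation with
           minimal displacement", {
  set.seed(7)
  n <- 500
  base <- matrix(rnorm(n * 3), n, 3)
  Y <- base %*% matrix(c(1, 0.6, 0.3, 0, 1, 0.5, 0, 0, 1), 3, 3)
  O <- symmetric_orthogonalise(Y)
  G <- crossprod(O)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)

  # oracle: single-pass Loewdin, norm-preserving scaling
  s <- svd(Y)
  L <- s$u %*% t(s$v)
  L <- sweep(L, 2, sqrt(colSums(Y^2)), `*`)
  expect_lte(sum((Y - O)^2), sum((Y - L)^2) + 1e-8)

  # fixed point: already-orthogonal input returned unchanged
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) %*% diag(c(2, 3, 4))
  expect_equal(symmetric_orthogonalise(Q), Q, tolerance = 1e-8)

  # idempotence
  expect_equal(symmetric_orthogonalise(O), O, tolerance = 1e-7)

  dup <- cbind(Y[, 1], Y[, 1], Y[, 2])
  expect_error(symmetric_orthogonalise(dup), "rank-deficient")
})

test_that("sign alignment recovers planted channel flips", {
  set.seed(8)
  base <- matrix(rnorm(2000 * 8), 2000, 8) %*%
    chol(0.5 * diag(8) + 0.5)
  flipped <- base
  flipped[, c(3, 7)] <- -flipped[, c(3, 7)]
  signs <- align_signs(list(base, flipped), seed = 4)
  expect_equal(signs[1, ], rep(1, 8))
  expect_equal(which(signs[2, ] == -1), c(3L, 7L))

  same <- align_signs(list(base, base, base), seed = 4)
  expect_true(all(same == 1))

  expect_warning(single <- align_signs(list(base)), "single session")
  expect_true(all(single == 1))
})

test_that("envelope tracks amplitude and normalises over good samples", {
  fs <- 250
  tt <- seq_len(5000) / fs
  # plateau: analytic-signal magnitude of a pure tone equals its amplitude
  x <- 3 * sin(2 * pi * 10 * tt)
  env_raw <- Mod(statewave:::analytic_signal(x))
  interior <- 500:4500
  expect_lt(max(abs(env_raw[interior] - 3)) / 3, 0.02)

  # known modulator oracle
  a <- 1 + 0.5 * sin(2 * pi * 0.3 * tt)
  xm <- a * sin(2 * pi * 10 * tt)
  ts <- parcel_ts(cbind(xm, rnorm(5000)), fs)
  env <- compute_envelope(ts, band = c(2, 40), smooth_ms = 100)
  expect_gt(cor(env$data[interior, 1], a[interior]), 0.95)

  # normalisation over good samples only
  bad <- rep(FALSE, 5000); bad[1:400] <- TRUE
  ts2 <- parcel_ts(cbind(xm, 2 + rnorm(5000)), fs, bad_mask = bad)
  env2 <- compute_envelope(ts2)
  good <- !bad
  expect_equal(colMeans(env2$data[good, ]), c(0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(env2$data[good, ], 2, sd), c(1, 1), tolerance = 1e-10,
               ignore_attr = TRUE)

  # envelope is invariant to a sign flip of the signal
  ts3 <- parcel_ts(cbind(xm, -xm), fs)
  env3 <- compute_envelope(ts3)
  expect_equal(env3$data[, 1], env3$data[, 2], tolerance = 1e-8)

  expect_error(compute_envelope(ts, smooth_ms = 1), "under 1 sample")
  expect_error(compute_envelope(ts, band = c(2, 200)), "band")
})

test_that("time-delay embedding bookkeeping is exact", {
  emb <- time_delay_embed(matrix(1:4, 4, 1), lags = -1:1)
  expect_equal(unname(unclass(emb)[, ]), rbind(c(1, 2, 3), c(2, 3, 4)))

  expect_equal(ncol(time_delay_embed(matrix(rnorm(39 * 50), 50, 39),
                                     lags = -7:7)), 585L)

  # lag-0 columns reproduce the interior of the original data
  set.seed(9)
  X <- matrix(rnorm(300 * 3), 300, 3)
  lags <- -7:7
  emb <- time_delay_embed(X, lags)
  lag0 <- which(lags == 0)
  cols <- (seq_len(3) - 1) * length(lags) + lag0
  expect_identical(unname(unclass(emb)[, cols]), X[8:293, ])

  # embedded covariance block equals the lagged cross-covariance
  Xb <- matrix(rnorm(20000 * 2), 20000, 2)
  Xb[, 2] <- 0.7 * c(Xb[-1, 1], 0) + 0.3 * Xb[, 2]
  embb <- time_delay_embed(Xb, -1:1)
  C <- cov(unclass(embb))
  # block between (channel 1, lag -1) and (channel 2, lag 1): lag diff 2
  direct <- cov(Xb[1:(20000 - 2), 1], Xb[3:20000, 2])
  expect_equal(C[1, 6], direct, tolerance = 0.01)

  expect_error(time_delay_embed(matrix(1:5, 5, 1), lags = -3:3),
               "lag span")
})

test_that("PCA reduction is ordered, sign-fixed and frequency-aware", {
  set.seed(10)
  W <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))
  X <- matrix(rnorm(400 * 3), 400, 3) %*% t(W)
  red <- pca_reduce(X, 3)
  recon <- red$reduced %*% t(red$projection)
  recon <- sweep(recon, 2, red$center, `+`)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_true(all(diff(red$explained_variance) <= 1e-12))
  expect_error(pca_reduce(X, 5), "rank|exceeds")

  # fewer components bias reconstruction toward low frequencies
  fs <- 250; S <- 6000; N <- 2
  tt <- seq_len(S) / fs
  slow <- sin(2 * pi * 3 * tt); fast <- sin(2 * pi * 35 * tt)
  raw <- cbind(2 * slow + 0.7 * fast + rnorm(S, sd = 0.3),
               2 * slow - 0.7 * fast + rnorm(S, sd = 0.3))
  emb <- time_delay_embed(raw, -7:7)
  band_ratio <- function(ncomp) {
    r <- pca_reduce(emb, ncomp)
    rec <- sweep(r$reduced %*% t(r$projection), 2, r$center, `+`)
    x <- rec[, 8]  # channel 1, lag 0
    pg <- Mod(fft(x - mean(x)))^2
    fr <- (seq_along(x) - 1) * fs / length(x)
    sum(pg[fr > 0 & fr < 10]) / sum(pg[fr > 25 & fr < 45])
  }
  expect_gt(band_ratio(2 * N), band_ratio(4 * N))
})

test_that("good-segment concatenation respects masks and boundaries", {
  set.seed(11)
  x <- matrix(rnorm(100 * 2), 100, 2)
  bad <- rep(FALSE, 100); bad[41:50] <- TRUE
  ds <- concatenate_good(list(parcel_ts(x, 250, bad_mask = bad)))
  expect_equal(ds$T, c(40L, 50L))

  two <- concatenate_good(list(parcel_ts(x, 250, session_id = 1),
                               parcel_ts(x, 250, session_id = 2)))
  expect_equal(two$T, c(100L, 100L))

  masks <- matrix(runif(300) < 0.2, 100, 3)
  sess <- lapply(1:3, function(i)
    parcel_ts(x, 250, session_id = i, bad_mask = masks[, i]))
  ds3 <- concatenate_good(sess)
  expect_equal(sum(ds3$T), sum(!masks))
  expect_equal(nrow(ds3$X), sum(!masks))

  allbad <- parcel_ts(x, 250, session_id = 9,
                      bad_mask = rep(TRUE, 100))
  expect_warning(ds4 <- concatenate_good(list(sess[[1]], allbad)),
                 "no good samples")
  expect_true(all(ds4$session_of_segment == 1))
})
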