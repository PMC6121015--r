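#' Parcel time-series container
#'
#' One session's samples x parcels matrix together with its sampling rate,
#' per-sample bad mask and (optionally) an events table.
#'
#' @param data numeric samples x parcels matrix; no NaN/Inf.
#' @param fs sampling rate in Hz.
#' @param session_id session identifier.
#' @param bad_mask logical per-sample vector; defaults to all good.
#' @param events optional data frame with 0-based `onset_sample` and
#'   `condition`.
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, fs, session_id = 1L, bad_mask = NULL,
                      events = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stopf("data contains NaN/Inf")
  if (is.null(bad_mask)) bad_mask <- rep(FALSE, nrow(data))
  if (length(bad_mask) != nrow(data))
    stopf("bad_mask length %d != %d samples", length(bad_mask), nrow(data))
  structure(list(data = data, fs = fs, session_id = session_id,
                 bad_mask = as.logical(bad_mask), events = events),
            class = "parcel_ts")
}

# Generalized extreme Studentized deviate test (two-sided) on a vector.
# Returns indices of detected outliers.
#' @noRd
gesd <- function(x, alpha = 0.05, max_out = NULL) {
  n <- length(x)
  if (is.null(max_out)) max_out <- floor(0.2 * n)
  max_out <- min(max_out, n - 2L)
  if (max_out < 1L) return(integer(0))
  idx <- seq_len(n)
  removed <- integer(0)
  R <- numeric(max_out)
  lam <- numeric(max_out)
  for (i in seq_len(max_out)) {
    xr <- x[idx]
    s <- sd(xr)
    if (!is.finite(s) || s == 0) { max_out <- i - 1L; break }
    dev <- abs(xr - mean(xr))
    j <- which.max(dev)
    R[i] <- dev[j] / s
    removed[i] <- idx[j]
    idx <- idx[-j]
    ni <- n - i + 1L
    p <- 1 - alpha / (2 * ni)
    tq <- stats::qt(p, ni - 2L)
    lam[i] <- (ni - 1L) * tq / sqrt((ni - 2L + tq^2) * ni)
  }
  if (max_out < 1L) return(integer(0))
  last <- which(R[seq_len(max_out)] > lam[seq_len(max_out)])
  if (!length(last)) return(integer(0))
  sort(removed[seq_len(max(last))])
}

#' Detect bad segments by windowed-variance outliers
#'
#' Splits the recording into non-overlapping windows, summarises each
#' window by the standard deviation over all samples and channels, and
#' flags outlier windows with the generalized extreme Studentized deviate
#' (GESD) test, two-sided so flat/dropout segments are caught as well as
#' high-variance artifacts. A trailing partial window is tested as its own
#' window when at least half a window long, otherwise merged into the last
#' full window.
#'
#' @param ts a [parcel_ts()].
#' @param window_s window length in seconds.
#' @param alpha GESD significance level.
#' @param max_prop maximum fraction of windows that can be flagged.
#' @return Logical bad mask, one entry per sample.
#' @export
detect_bad_segments <- function(ts, window_s = 1, alpha = 0.05,
                                max_prop = 0.2) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (max_prop <= 0 || max_prop >= 1) stopf("max_prop must be in (0, 1)")
  w <- round(window_s * ts$fs)
  if (w < 2L) stopf("window of %.3g s is under 2 samples at fs = %.4g",
                    window_s, ts$fs)
  S <- nrow(ts$data)
  starts <- seq(1L, S, by = w)
  ends <- pmin(starts + w - 1L, S)
  n_last <- ends[length(ends)] - starts[length(starts)] + 1L
  if (length(starts) > 1L && n_last < w / 2) {
    # merge trailing partial window into the previous full window
    ends[length(ends) - 1L] <- S
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }
  nw <- length(starts)
  if (nw < 3L) stopf("need at least 3 windows, got %d", nw)
  stat <- vapply(seq_len(nw),
                 function(i) sd(ts$data[starts[i]:ends[i], ]), 0)
  if (all(stat == 0)) stopf("degenerate variance: all windows constant")
  bad_w <- gesd(stat, alpha = alpha, max_out = floor(max_prop * nw))
  mask <- rep(FALSE, S)
  for (i in bad_w) mask[starts[i]:ends[i]] <- TRUE
  mask
}

# Single-pass Loewdin (symmetric) orthogonalisation: Y (Y'Y)^(-1/2),
# rescaled to preserve column norms. Used as starting point; the
# exported routine iterates to the closest orthogonal solution.
#' @noRd
loewdin <- function(Y) {
  s <- svd(Y)
  O <- s$u %*% t(s$v)
  sweep(O, 2, sqrt(colSums(Y^2)), `*`)
}

#' Symmetric multivariate leakage correction
#'
#' Finds the set of mutually orthogonal time-courses least displaced (in
#' Frobenius norm) from the input columns: the closest-orthogonal-matrix
#' construction, iterating an orthogonal-Procrustes solve with per-column
#' scaling. Removes all zero-lag correlation across the network, which is
#' the signature of spatial leakage between reconstructed sources.
#'
#' @param data samples x N matrix with full column rank, N >= 2.
#' @param tol convergence tolerance on the relative objective change.
#' @param max_iter maximum iterations.
#' @return Matrix of the same shape with mutually orthogonal columns.
#' @export
symmetric_orthogonalise <- function(data, tol = 1e-10, max_iter = 100L) {
  Y <- as.matrix(data)
  N <- ncol(Y)
  if (N < 2L) stopf("need at least 2 channels")
  qrY <- qr(Y)
  if (qrY$rank < N) {
    dep <- sort(qrY$pivot[(qrY$rank + 1L):N])
    stopf("rank-deficient input: column(s) %s linearly dependent",
          paste(dep, collapse = ", "))
  }
  d <- sqrt(colSums(Y^2))
  obj_old <- Inf
  O <- NULL
  for (it in seq_len(max_iter)) {
    s <- svd(sweep(Y, 2, d, `*`))
    O <- s$u %*% t(s$v)
    d <- colSums(O * Y)
    obj <- sum((Y - sweep(O, 2, d, `*`))^2)
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol * max(obj, 1)) break
    obj_old <- obj
  }
  sweep(O, 2, d, `*`)
}

# Stacked lagged covariance matrices of one session (N x N x n_lags).
#' @noRd
lagged_cov <- function(X, lags) {
  N <- ncol(X); S <- nrow(X)
  out <- array(0, c(N, N, length(lags)))
  Xc <- sweep(X, 2, colMeans(X))
  for (i in seq_along(lags)) {
    l <- lags[i]
    a <- Xc[seq_len(S - l), , drop = FALSE]
    b <- Xc[seq_len(S - l) + l, , drop = FALSE]
    out[, , i] <- crossprod(a, b) / (S - l)
  }
  out
}

#' Resolve the per-session sign ambiguity of reconstructed parcels
#'
#' Source reconstruction leaves each parcel's time-course with an arbitrary
#' sign per session, which suppresses group-level phase relations. This
#' searches over per-session sign assignments to maximise the summed
#' magnitude of the group-mean lagged covariance across channel pairs,
#' using greedy single-channel flips to convergence with seeded random
#' restarts. The first session is anchored to all +1.
#'
#' @param sessions list of samples x N matrices (raw, not enveloped).
#' @param lags integer lags over which covariance similarity is assessed.
#' @param n_restarts random restarts of the greedy search.
#' @param seed integer seed making restarts deterministic.
#' @return An n_sessions x N matrix of +-1 sign factors.
#' @export
align_signs <- function(sessions, lags = 0:3, n_restarts = 10L, seed = 1L) {
  ns <- length(sessions)
  N <- ncol(sessions[[1]])
  if (ns < 2L) {
    warnf("single session: returning identity signs")
    return(matrix(1, max(ns, 1L), N))
  }
  if (!all(vapply(sessions, ncol, 0L) == N))
    stopf("sessions must share the channel count")
  covs <- lapply(sessions, lagged_cov, lags = lags)

  objective <- function(signs) {
    M <- 0
    for (s in seq_len(ns)) {
      f <- outer(signs[s, ], signs[s, ])
      M <- M + array(f, dim(covs[[s]])) * covs[[s]]
    }
    sum(abs(M / ns))
  }

  set.seed(seed)
  best <- NULL; best_obj <- -Inf
  for (r in seq_len(n_restarts)) {
    signs <- matrix(1, ns, N)
    if (r > 1L)
      signs[-1, ] <- matrix(sample(c(-1, 1), (ns - 1) * N, replace = TRUE),
                            ns - 1, N)
    obj <- objective(signs)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (s in 2:ns) for (c in seq_len(N)) {
        signs[s, c] <- -signs[s, c]
        o2 <- objective(signs)
        if (o2 > obj + 1e-12) { obj <- o2; improved <- TRUE }
        else signs[s, c] <- -signs[s, c]
      }
    }
    if (obj > best_obj) { best_obj <- obj; best <- signs }
  }
  structure(best, objective = best_obj)
}

# Analytic signal via FFT half-spectrum doubling.
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Centered moving average with shrinking edge windows.
#' @noRd
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half_l <- floor((w - 1) / 2); half_r <- w - 1L - half_l
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Amplitude envelope of parcel time-courses
#'
#' Band-pass filters each channel (zero-phase, order-5 IIR), takes the
#' analytic-signal magnitude, smooths with a moving-average window, and
#' z-normalises each channel using good samples only (bad samples are
#' excluded from the statistics, matching their later removal).
#'
#' @param ts a [parcel_ts()].
#' @param band two-element band edges in Hz, inside (0, fs/2).
#' @param smooth_ms moving-average window in milliseconds.
#' @return A [parcel_ts()] holding the normalised envelopes.
#' @export
compute_envelope <- function(ts, band = c(2, 40), smooth_ms = 100) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (band[1] <= 0 || band[2] >= ts$fs / 2)
    stopf("band (%.3g, %.3g) must lie inside (0, %.3g)", band[1], band[2],
          ts$fs / 2)
  w <- round(smooth_ms * ts$fs / 1000)
  if (w < 1L) stopf("smoothing window under 1 sample")
  bf <- signal::butter(5, band / (ts$fs / 2), type = "pass")
  env <- apply(ts$data, 2, function(x) {
    xf <- signal::filtfilt(bf, x)
    moving_average(Mod(analytic_signal(xf)), w)
  })
  good <- !ts$bad_mask
  mu <- colMeans(env[good, , drop = FALSE])
  sg <- apply(env[good, , drop = FALSE], 2, sd)
  if (any(sg == 0)) stopf("zero envelope variance in channel(s) %s",
                          paste(which(sg == 0), collapse = ", "))
  env <- sweep(sweep(env, 2, mu), 2, sg, `/`)
  parcel_ts(env, ts$fs, ts$session_id, ts$bad_mask, ts$events)
}

#' Time-delay embedding
#'
#' Builds the lag-expanded representation used by the spectrally resolved
#' HMM: column (n, l) holds channel n shifted by lag l; rows requiring
#' out-of-range samples are dropped, so the output has
#' `nrow(data) - (max(lags) - min(lags))` rows. Columns are ordered
#' channel-major, lag-minor. Each embedded row is timestamped by its lag-0
#' sample (attribute `t0` gives the original index of the first row), so
#' state time-courses stay aligned with the original time axis.
#'
#' @param data samples x N matrix (one continuous segment).
#' @param lags ordered integer lag list.
#' @return samples' x (N * length(lags)) matrix with attributes `lags`,
#'   `n_channels` and `t0`.
#' @export
time_delay_embed <- function(data, lags = -7:7) {
  data <- as.matrix(data)
  lags <- as.integer(sort(lags))
  S <- nrow(data); N <- ncol(data)
  span <- max(lags) - min(lags)
  if (span >= S) stopf("lag span %d >= segment length %d", span, S)
  Sp <- S - span
  t0 <- 1L - min(lags)  # original index of first embedded row's lag-0 sample
  out <- matrix(0, Sp, N * length(lags))
  for (n in seq_len(N)) for (i in seq_along(lags)) {
    out[, (n - 1L) * length(lags) + i] <-
      data[(t0 + lags[i]):(t0 + lags[i] + Sp - 1L), n]
  }
  structure(out, lags = lags, n_channels = N, t0 = t0)
}

#' PCA reduction of embedded data
#'
#' Projects onto the leading principal components, ordered by descending
#' explained variance, with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive). The retained
#' component count bounds the frequency content visible to the model:
#' fewer components bias it toward low frequencies, which dominate
#' variance.
#'
#' @param embedded samples' x (N * n_lags) matrix.
#' @param n_components components to keep; the conventional choice is 4N.
#' @return A list with `reduced` (scores), `projection` (loadings matrix),
#'   `center`, and `explained_variance`.
#' @export
pca_reduce <- function(embedded, n_components) {
  X <- as.matrix(embedded)
  n_components <- as.integer(n_components)
  if (n_components > min(dim(X)))
    stopf("n_components = %d exceeds min(dim) = %d", n_components,
          min(dim(X)))
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  r <- sum(p$sdev > p$sdev[1] * 1e-10)
  if (n_components > r)
    stopf("n_components = %d exceeds data rank %d", n_components, r)
  W <- p$rotation[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(n_components),
                 function(j) sign(W[which.max(abs(W[, j])), j]), 0)
  W <- sweep(W, 2, flip, `*`)
  scores <- sweep(X, 2, p$center) %*% W
  list(reduced = scores, projection = W, center = p$center,
       explained_variance = p$sdev[seq_len(n_components)]^2)
}

#' Segmented dataset container
#'
#' The concatenated "good" data across sessions: a total-samples x D
#' matrix, the ordered segment lengths `T` (segments never span a bad
#' sample or a session boundary — the inference must not explain
#' transitions across discontinuities), the session of each segment, and a
#' per-row map back to (session, original sample) so state time-courses
#' can be epoched on the original time axis.
#'
#' @param X numeric matrix.
#' @param T integer segment lengths summing to `nrow(X)`.
#' @param session_of_segment session id per segment.
#' @param sample_index data frame with `session` and 0-based `sample` per
#'   row of `X`.
#' @param meta list of representation metadata (tag, lags, projection, fs).
#' @return An object of class `segmented_dataset`.
#' @export
segmented_dataset <- function(X, T, session_of_segment, sample_index,
                              meta = list()) {
  X <- as.matrix(X)
  T <- as.integer(T)
  if (sum(T) != nrow(X)) stopf("sum(T) = %d != nrow(X) = %d", sum(T), nrow(X))
  if (any(T < 1L)) stopf("every segment length must be >= 1")
  if (length(session_of_segment) != length(T))
    stopf("session_of_segment must have one entry per segment")
  structure(list(X = X, T = T, session_of_segment = session_of_segment,
                 sample_index = sample_index, meta = meta),
            class = "segmented_dataset")
}

# Maximal good runs of a bad mask: data.frame(start, end), 1-based.
#' @noRd
good_runs <- function(bad_mask) {
  r <- rle_runs(!bad_mask)
  r[r$value, c("start", "end"), drop = FALSE]
}

#' Concatenate good segments across sessions
#'
#' Removes bad samples and stacks each maximal good run (within a session)
#' as one segment. Session boundaries always break segments, even for
#' back-to-back clean sessions. Sessions with zero good samples are
#' excluded with a warning.
#'
#' @param sessions list of [parcel_ts()] objects with consistent channel
#'   counts.
#' @param tag representation tag stored in the metadata.
#' @return A [segmented_dataset()].
#' @export
concatenate_good <- function(sessions, tag = "envelope") {
  stopifnot(length(sessions) >= 1L)
  N <- ncol(sessions[[1]]$data)
  Xs <- list(); Ts <- integer(0); seg_sess <- c(); idx <- list()
  for (ts in sessions) {
    if (ncol(ts$data) != N) stopf("inconsistent channel count")
    runs <- good_runs(ts$bad_mask)
    if (!nrow(runs)) {
      warnf("session %s has no good samples; excluded", ts$session_id)
      next
    }
    for (i in seq_len(nrow(runs))) {
      sl <- runs$start[i]:runs$end[i]
      Xs[[length(Xs) + 1L]] <- ts$data[sl, , drop = FALSE]
      Ts <- c(Ts, length(sl))
      seg_sess <- c(seg_sess, ts$session_id)
      idx[[length(idx) + 1L]] <-
        data.frame(session = ts$session_id, sample = sl - 1L)
    }
  }
  if (!length(Xs)) stopf("no good samples in any session")
  segmented_dataset(do.call(rbind, Xs), Ts, seg_sess, do.call(rbind, idx),
                    meta = list(tag = tag, fs = sessions[[1]]$fs))
}

#' Envelope representation of a multi-session dataset
#'
#' Convenience wrapper: per session, computes the normalised amplitude
#' envelope and then concatenates good segments.
#'
#' @inheritParams compute_envelope
#' @param sessions list of [parcel_ts()].
#' @return A [segmented_dataset()] tagged `"envelope"`.
#' @export
prepare_envelope <- function(sessions, band = c(2, 40), smooth_ms = 100) {
  concatenate_good(lapply(sessions, compute_envelope, band = band,
                          smooth_ms = smooth_ms), tag = "envelope")
}

#' Time-delay embedded + PCA representation of a multi-session dataset
#'
#' Per session and per maximal good run, applies the time-delay embedding;
#' each embedded run becomes one segment (rows timestamped by their lag-0
#' sample). A single PCA is then fitted across all segments and the scores
#' returned. Runs shorter than the lag span are dropped with a warning.
#'
#' @param sessions list of [parcel_ts()].
#' @param lags integer lag list.
#' @param n_pca retained components; default 4N.
#' @param signs optional n_sessions x N sign matrix from [align_signs()].
#' @return A [segmented_dataset()] tagged `"embedded"`, with the lag list
#'   and PCA projection in `meta`.
#' @export
prepare_tde <- function(sessions, lags = -7:7, n_pca = NULL, signs = NULL) {
  N <- ncol(sessions[[1]]$data)
  if (is.null(n_pca)) n_pca <- 4L * N
  span <- max(lags) - min(lags)
  Xs <- list(); Ts <- integer(0); seg_sess <- c(); idx <- list()
  for (si in seq_along(sessions)) {
    ts <- sessions[[si]]
    dat <- ts$data
    if (!is.null(signs)) dat <- sweep(dat, 2, signs[si, ], `*`)
    runs <- good_runs(ts$bad_mask)
    for (i in seq_len(nrow(runs))) {
      sl <- runs$start[i]:runs$end[i]
      if (length(sl) <= span) {
        warnf("session %s: good run of %d samples shorter than lag span %d; dropped",
              ts$session_id, length(sl), span + 1L)
        next
      }
      emb <- time_delay_embed(dat[sl, , drop = FALSE], lags)
      Xs[[length(Xs) + 1L]] <- emb
      Ts <- c(Ts, nrow(emb))
      seg_sess <- c(seg_sess, ts$session_id)
      t0 <- attr(emb, "t0")
      idx[[length(idx) + 1L]] <-
        data.frame(session = ts$session_id,
                   sample = sl[t0:(t0 + nrow(emb) - 1L)] - 1L)
    }
  }
  if (!length(Xs)) stopf("no usable good runs")
  emb_all <- do.call(rbind, Xs)
  red <- pca_reduce(emb_all, n_pca)
  segmented_dataset(red$reduced, Ts, seg_sess, do.call(rbind, idx),
                    meta = list(tag = "embedded", lags = as.integer(lags),
                                n_channels = N, projection = red$projection,
                                pca_center = red$center,
                                fs = sessions[[1]]$fs))
}
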