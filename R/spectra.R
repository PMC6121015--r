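#' State-wise activation maps from the observation model
#'
#' For a mean-and-covariance (envelope) model, the expectation of the
#' posterior distribution of the mean envelope per state and parcel is a
#' direct map of the features driving the inference. Optionally
#' z-transformed across parcels within each state for display.
#'
#' @param fit an `hmm_fit` with `obs_kind = "mean_and_cov"`.
#' @param z z-transform across parcels within each state.
#' @return K x N matrix of state maps.
#' @export
activation_maps <- function(fit, z = FALSE) {
  if (fit$obs_kind != "mean_and_cov")
    stopf("zero-mean observation model has no mean maps; use statewise_multitaper spectra instead")
  maps <- t(vapply(fit$states, `[[`, numeric(fit$D), "mean"))
  if (z) {
    maps <- t(apply(maps, 1, function(m) {
      s <- sd(m)
      if (s == 0) { warnf("constant map; z-transform returned zeros"); m * 0 }
      else (m - mean(m)) / s
    }))
  }
  maps
}

# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem; columns are the leading `n_tapers` tapers, unit energy.
#' @noRd
dpss_tapers <- function(n, nw = 3, n_tapers = 5L) {
  W <- nw / n
  t <- 0:(n - 1)
  md <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  od <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  M <- diag(md)
  M[cbind(1:(n - 1), 2:n)] <- od
  M[cbind(2:n, 1:(n - 1))] <- od
  ev <- eigen(M, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(n_tapers), drop = FALSE]
  for (j in seq_len(n_tapers)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' State-weighted multitaper spectra and coherence
#'
#' Splits the data into overlapping windows (segment-aware: windows never
#' span a segment boundary), computes a multitaper cross-spectral matrix
#' per window, and forms each state's spectrum as the window-CSD average
#' weighted by the window-mean posterior probability of that state,
#' normalised by the state's total probability mass. Window-level (not
#' sample-level) weighting is used because tapered windows cannot be
#' reweighted per sample without biasing the spectrum. Coherence is the
#' CSD magnitude normalised by the PSDs.
#'
#' @param data samples x N raw matrix aligned row-for-row with
#'   `stc$gamma`.
#' @param stc a [state_tc()].
#' @param fs sampling rate in Hz.
#' @param band frequency band retained, Hz.
#' @param window_s window length in seconds.
#' @param overlap fractional window overlap.
#' @param nw time-bandwidth product.
#' @param n_tapers number of tapers.
#' @return A list of class `state_spectra`: `freqs`, `psd`
#'   (K x N x n_freq), `csd` (K x N x N x n_freq, complex, Hermitian),
#'   `coherence` (same shape, real), `gamma_mass` (per-state summed
#'   window weight), `n_windows`, and `low_mass` flags for states with
#'   total mass under one window.
#' @export
statewise_multitaper <- function(data, stc, fs, band = c(1, 40),
                                 window_s = 2, overlap = 0.5, nw = 3,
                                 n_tapers = 5L) {
  data <- as.matrix(data)
  stopifnot(inherits(stc, "state_tc"), nrow(data) == nrow(stc$gamma))
  if (band[1] <= 0 || band[2] >= fs / 2)
    stopf("band must lie inside (0, fs/2)")
  w <- round(window_s * fs)
  step <- max(1L, round(w * (1 - overlap)))
  tap <- dpss_tapers(w, nw, n_tapers)
  freqs_all <- (0:(w - 1)) * fs / w
  sel <- which(freqs_all >= band[1] & freqs_all <= band[2])
  freqs <- freqs_all[sel]
  N <- ncol(data); K <- ncol(stc$gamma); nf <- length(sel)

  acc <- array(0 + 0i, c(K, N, N, nf))
  mass <- numeric(K)
  n_windows <- 0L
  offs <- cumsum(c(0L, stc$T))
  for (s in seq_along(stc$T)) {
    seg_start <- offs[s] + 1L; seg_end <- offs[s + 1L]
    if (seg_end - seg_start + 1L < w) next
    for (st in seq(seg_start, seg_end - w + 1L, by = step)) {
      sl <- st:(st + w - 1L)
      Xw <- sweep(data[sl, , drop = FALSE], 2, colMeans(data[sl, , drop = FALSE]))
      # taper-averaged cross-spectra at the selected bins
      Sw <- array(0 + 0i, c(N, N, nf))
      Fts <- array(0 + 0i, c(nf, N, n_tapers))
      for (tp in seq_len(n_tapers)) {
        ft <- stats::mvfft(Xw * tap[, tp])
        Fts[, , tp] <- ft[sel, , drop = FALSE]
      }
      for (f in seq_len(nf)) {
        Ff <- matrix(Fts[f, , ], N, n_tapers)
        Sw[, , f] <- tcrossprod(Ff, Conj(Ff)) / n_tapers / fs
      }
      gbar <- colMeans(stc$gamma[sl, , drop = FALSE])
      for (k in seq_len(K)) acc[k, , , ] <- acc[k, , , ] + gbar[k] * Sw
      mass <- mass + gbar
      n_windows <- n_windows + 1L
    }
  }
  if (n_windows == 0L) stopf("no window fits inside any segment")

  psd <- array(0, c(K, N, nf))
  coh <- array(0, c(K, N, N, nf))
  csd <- array(0 + 0i, c(K, N, N, nf))
  low_mass <- mass < 1
  for (k in seq_len(K)) {
    if (low_mass[k]) {
      warnf("state %d has posterior mass %.3g < 1 window; spectra undefined",
            k, mass[k])
      psd[k, , ] <- NA; coh[k, , , ] <- NA; csd[k, , , ] <- NA
      next
    }
    Sk <- array(acc[k, , , ], c(N, N, nf)) / mass[k]
    csd[k, , , ] <- Sk
    for (n in seq_len(N)) psd[k, n, ] <- Re(Sk[n, n, ])
    for (f in seq_len(nf)) {
      Sf <- matrix(Sk[, , f], N, N)
      d <- sqrt(pmax(Re(Sf[cbind(1:N, 1:N)]), 1e-300))
      coh[k, , , f] <- Mod(Sf) / outer(d, d)
    }
  }
  structure(list(freqs = freqs, psd = psd, csd = csd, coherence = coh,
                 gamma_mass = mass, n_windows = n_windows,
                 low_mass = low_mass, fs = fs),
            class = "state_spectra")
}

# One ALS factorisation attempt; returns W, H and the error trace.
#' @noRd
nnmf_als <- function(X, r, max_iter = 60L, tol = 1e-8) {
  n <- nrow(X); m <- ncol(X)
  W <- matrix(runif(n * r), n, r)
  H <- matrix(runif(r * m), r, m)
  err <- numeric(0)
  for (it in seq_len(max_iter)) {
    H <- pmax(MASS::ginv(W) %*% X, 0)
    W <- pmax(X %*% MASS::ginv(H), 0)
    e <- sum((X - W %*% H)^2)
    err <- c(err, e)
    if (it > 1L && abs(err[it - 1L] - e) <= tol * max(e, 1)) break
  }
  list(W = W, H = H, error = err[length(err)], trace = err)
}

# Best single-Gaussian least-squares fit to a spectrum over a grid of
# centres and widths (amplitude closed-form, clamped non-negative).
# Returns the normalised residual.
#' @noRd
gaussian_fit_residual <- function(freqs, y) {
  ss <- sum(y^2)
  if (ss == 0) return(0)
  widths <- diff(range(freqs)) * c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8)
  best <- Inf
  for (c0 in freqs) for (wd in widths) {
    g <- exp(-(freqs - c0)^2 / (2 * wd^2))
    a <- max(sum(g * y) / sum(g^2), 0)
    r <- sum((y - a * g)^2)
    if (r < best) best <- r
  }
  best / ss
}

#' Spectral modes by non-negative matrix factorisation
#'
#' Factorises a stack of non-negative spectra (rows: any combination of
#' subject, state and parcel or parcel pair; columns: frequency) into
#' `n_modes` non-negative frequency profiles and loadings, playing the
#' role of data-driven frequency bands. Each repeat keeps the best of
#' `n_replicates` alternating-least-squares factorisations (lowest
#' reconstruction error); the final repeat is then selected by
#' unimodality — the repeat whose mode spectra are best approximated by
#' single Gaussian bumps — not by reconstruction error, so the retained
#' modes are interpretable as separate frequency bands. Mode spectra are
#' scaled to unit maximum.
#'
#' @param psd_stack rows x freq non-negative matrix.
#' @param n_modes number of modes (< both dimensions).
#' @param freqs frequency grid (for the unimodality fit); defaults to
#'   column index.
#' @param n_replicates ALS restarts per repeat.
#' @param n_repeats repeats entering the unimodality selection.
#' @param seed integer seed.
#' @return A list of class `spectral_modes`: `mode_spectra`
#'   (modes x freq), `weights` (rows x modes), `unimodality` (per-repeat
#'   score), `selected_repeat`, `reconstruction_error`.
#' @export
nnmf_spectral_modes <- function(psd_stack, n_modes, freqs = NULL,
                                n_replicates = 500L, n_repeats = 20L,
                                seed = 1L) {
  X <- as.matrix(psd_stack)
  if (any(X < 0)) stopf("spectra must be non-negative")
  keep <- rowSums(X) > 0
  if (!all(keep)) {
    warnf("dropping %d all-zero rows", sum(!keep))
    X <- X[keep, , drop = FALSE]
  }
  if (n_modes >= min(dim(X))) stopf("n_modes must be < min dimension")
  if (is.null(freqs)) freqs <- seq_len(ncol(X))

  set.seed(seed)
  repeats <- vector("list", n_repeats)
  scores <- numeric(n_repeats)
  for (rp in seq_len(n_repeats)) {
    best <- NULL
    for (rep in seq_len(n_replicates)) {
      f <- nnmf_als(X, n_modes)
      if (is.null(best) || f$error < best$error) best <- f
    }
    # scale modes to unit maximum, move scale into the weights
    sc <- apply(best$H, 1, max)
    sc[sc == 0] <- 1
    H <- best$H / sc
    W <- sweep(best$W, 2, sc, `*`)
    scores[rp] <- sum(vapply(seq_len(n_modes), function(j)
      gaussian_fit_residual(freqs, H[j, ]), 0))
    repeats[[rp]] <- list(H = H, W = W, error = best$error)
  }
  si <- which.min(scores)
  sel <- repeats[[si]]
  structure(list(mode_spectra = sel$H, weights = sel$W,
                 unimodality = scores, selected_repeat = si,
                 reconstruction_error = sel$error, freqs = freqs),
            class = "spectral_modes")
}

#' Threshold connection strengths with a two-Gaussian mixture
#'
#' Models the distribution of connection strengths as a mixture of two
#' Gaussians — a bulk of typical values and a high-valued population —
#' and keeps only connections more probably drawn from the higher-mean
#' component. If a single Gaussian is preferred (by BIC) the mask is
#' empty: no connections are shown.
#'
#' @param values numeric vector of connection strengths (>= 10 values).
#' @return Logical mask of retained connections.
#' @importFrom mclust Mclust mclustBIC
#' @export
gmm_threshold_connections <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 10L) stopf("need >= 10 values")
  if (sd(values) < 1e-12) {
    warnf("near-zero variance; no connections retained")
    return(rep(FALSE, length(values)))
  }
  fit <- mclust::Mclust(values, G = 1:2, modelNames = "V", verbose = FALSE)
  if (is.null(fit) || fit$G == 1L) return(rep(FALSE, length(values)))
  hi <- which.max(fit$parameters$mean)
  fit$z[, hi] > 0.5
}

#' Reconstruct a time-frequency response from state occupancies and
#' spectra
#'
#' The sum over states of the outer product of the task-evoked occupancy
#' time-course and the state power spectrum: a rank-K regularised
#' alternative to a conventional time-frequency transform, reflecting the
#' dynamics as represented by the model.
#'
#' @param evoked_occ timepoints x K occupancy matrix.
#' @param state_psd K x freq matrix of state spectra.
#' @return timepoints x freq matrix.
#' @export
reconstruct_tf <- function(evoked_occ, state_psd) {
  evoked_occ <- as.matrix(evoked_occ); state_psd <- as.matrix(state_psd)
  if (ncol(evoked_occ) != nrow(state_psd))
    stopf("state count mismatch: %d occupancies vs %d spectra",
          ncol(evoked_occ), nrow(state_psd))
  evoked_occ %*% state_psd
}

#' Morlet wavelet time-frequency power
#'
#' Complex Morlet transform with a fixed cycle count (default 5),
#' FFT-convolution per frequency, trial-averaged when `data` is a
#' trials x samples matrix. A comparison utility for the reconstructed
#' time-frequency responses. Columns within half a wavelet length of an
#' edge are flagged in the `edge` attribute.
#'
#' @param data numeric vector, or trials x samples matrix.
#' @param fs sampling rate in Hz.
#' @param freqs frequencies of interest, inside (0, fs/2).
#' @param n_cycles wavelet cycle count.
#' @return timepoints x freq power matrix with attribute `edge`.
#' @export
wavelet_tf <- function(data, fs, freqs, n_cycles = 5) {
  if (any(freqs <= 0 | freqs >= fs / 2)) stopf("freqs must be in (0, fs/2)")
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  S <- ncol(data)
  power <- matrix(0, S, length(freqs))
  max_half <- 0L
  for (fi in seq_along(freqs)) {
    f0 <- freqs[fi]
    sig_t <- n_cycles / (2 * pi * f0)
    half <- ceiling(3 * sig_t * fs)
    max_half <- max(max_half, half)
    tt <- (-half:half) / fs
    wav <- exp(-tt^2 / (2 * sig_t^2)) * exp(2i * pi * f0 * tt)
    wav <- wav / sqrt(sum(Mod(wav)^2))
    L <- S + length(wav) - 1L
    Wf <- fft(c(wav, rep(0, L - length(wav))))
    for (tr in seq_len(nrow(data))) {
      Xf <- fft(c(data[tr, ], rep(0, L - S)))
      conv <- fft(Xf * Wf, inverse = TRUE) / L
      power[, fi] <- power[, fi] + Mod(conv[half + seq_len(S)])^2
    }
  }
  power <- power / nrow(data)
  edge <- seq_len(S) <= max_half | seq_len(S) > S - max_half
  if (any(edge)) attr(power, "edge") <- edge
  power
}
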