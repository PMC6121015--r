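# Independent oracle implementations used across tests. These deliberately
# avoid the package's internal code paths.

# Multivariate normal log-density (independent of the package internals).
oracle_mvn_logdens <- function(y, mu, sigma) {
  y <- as.matrix(y)
  D <- ncol(y)
  out <- numeric(nrow(y))
  si <- solve(sigma)
  ld <- determinant(sigma, logarithm = TRUE)$modulus
  for (i in seq_len(nrow(y))) {
    d <- y[i, ] - mu
    out[i] <- -0.5 * drop(d %*% si %*% d) - 0.5 * ld -
      0.5 * D * log(2 * pi)
  }
  out
}

# Exhaustive smoothed marginals for a single segment.
enum_gamma <- function(logB, A, pi0) {
  T <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1, function(p) {
    v <- log(pi0[p[1]]) + logB[1, p[1]]
    if (T > 1) for (t in 2:T)
      v <- v + log(A[p[t - 1], p[t]]) + logB[t, p[t]]
    v
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  g <- matrix(0, T, K)
  for (t in seq_len(T)) for (k in seq_len(K))
    g[t, k] <- sum(w[paths[, t] == k])
  g
}

# Exhaustive most-probable path for a single segment.
enum_viterbi <- function(logB, A, pi0) {
  T <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1, function(p) {
    v <- log(pi0[p[1]]) + logB[1, p[1]]
    if (T > 1) for (t in 2:T)
      v <- v + log(A[p[t - 1], p[t]]) + logB[t, p[t]]
    v
  })
  as.integer(paths[which.max(lp), ])
}

# Build an hmm_fit-shaped object from known parameters, for decoding tests.
make_plugin_fit <- function(means, covs, A, pi0) {
  K <- length(means); D <- length(means[[1]])
  states <- lapply(seq_len(K), function(k)
    list(mean = means[[k]], cov = covs[[k]], m = means[[k]], kappa = 1e6,
         Psi = covs[[k]] * (1e6 - D - 1), nu = 1e6))
  structure(list(states = states, transition_matrix = A,
                 initial_probs = pi0, obs_kind = "mean_and_cov", D = D),
            class = "hmm_fit")
}

# Single-segment dataset wrapper.
make_dataset <- function(X, T = nrow(X), fs = 250) {
  X <- as.matrix(X)
  offs <- cumsum(c(0L, T))
  idx <- do.call(rbind, lapply(seq_along(T), function(s)
    data.frame(session = s, sample = 0:(T[s] - 1L))))
  segmented_dataset(X, T, seq_along(T), idx, meta = list(fs = fs))
}

# Random valid HMM parameters for small problems.
random_params <- function(K, D, seed) {
  set.seed(seed)
  A <- matrix(runif(K * K, 0.1, 1), K, K); A <- A / rowSums(A)
  pi0 <- runif(K, 0.1, 1); pi0 <- pi0 / sum(pi0)
  means <- lapply(seq_len(K), function(k) rnorm(D, sd = 2))
  covs <- lapply(seq_len(K), function(k) {
    M <- matrix(rnorm(D * D), D)
    crossprod(M) / D + diag(D) * 0.5
  })
  list(A = A, pi0 = pi0, means = means, covs = covs)
}

# Direct GESD (two-sided) on a statistic vector, per the textbook recipe.
oracle_gesd <- function(x, alpha, max_out) {
  n <- length(x)
  idx <- seq_len(n); removed <- integer(0)
  R <- lam <- numeric(max_out)
  for (i in seq_len(max_out)) {
    xr <- x[idx]
    dev <- abs(xr - mean(xr)) / sd(xr)
    j <- which.max(dev)
    R[i] <- dev[j]; removed[i] <- idx[j]; idx <- idx[-j]
    ni <- n - i + 1
    tq <- qt(1 - alpha / (2 * ni), ni - 2)
    lam[i] <- (ni - 1) * tq / sqrt((ni - 2 + tq^2) * ni)
  }
  keep <- which(R > lam)
  if (!length(keep)) integer(0) else sort(removed[seq_len(max(keep))])
}

# DerSimonian-Laird style random-effects summary for one cell.
oracle_dl <- function(y, v) {
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  tau2 <- max(0, (Q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  cope <- sum(ws * y) / sum(ws)
  list(cope = cope, se = 1 / sqrt(sum(ws)), stat = cope * sqrt(sum(ws)))
}

# Epoched-occupancy object built directly (for GLM tests).
make_epochs <- function(values, condition, fs = 250,
                        time_ms = NULL) {
  if (is.null(time_ms))
    time_ms <- seq(0, by = 1000 / fs, length.out = dim(values)[2])
  structure(list(values = values, time_ms = time_ms,
                 condition = condition, subject = 1L, n_dropped = 0L,
                 fs = fs), class = "epoched_occupancy")
}

hanning_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# Slepian tapers from the canonical tridiagonal eigenproblem (independent
# of the package's implementation), used to build the multitaper spectral
# window when comparing against periodogram oracles.
oracle_dpss <- function(n, nw, k) {
  t <- 0:(n - 1)
  M <- matrix(0, n, n)
  diag(M) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * nw / n)
  off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  M[cbind(1:(n - 1), 2:n)] <- off
  M[cbind(2:n, 1:(n - 1))] <- off
  v <- eigen(M, symmetric = TRUE)$vectors[, 1:k, drop = FALSE]
  sweep(v, 2, sqrt(colSums(v^2)), `/`)
}

# Random state time-course.
random_stc <- function(K, T, fs = 250, seed = 1) {
  set.seed(seed)
  S <- sum(T)
  vpath <- sample.int(K, S, replace = TRUE)
  gamma <- matrix(0, S, K)
  gamma[cbind(seq_len(S), vpath)] <- 1
  state_tc(gamma, vpath, T, fs = fs)
}
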