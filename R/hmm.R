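#' HMM inference configuration
#'
#' Settings for variational Bayes inference of a K-state hidden Markov
#' model with multivariate Gaussian observation models. Two observation
#' kinds are supported: `mean_and_cov` (mean vector plus covariance, the
#' amplitude-envelope model) and `zero_mean_cov` (covariance only, the
#' time-delay-embedded model, where signals are zero-mean by
#' construction).
#'
#' Priors are conjugate: Dirichlet over transition rows and the initial
#' distribution (concentration `dir_alpha` with a diagonal `stickiness`
#' boost encoding temporal persistence), and normal-inverse-Wishart (or
#' inverse-Wishart only) over emissions, with scale matrix set to the
#' empirical data covariance and `nu0 = D + 2` degrees of freedom so the
#' prior expected covariance equals the empirical one.
#'
#' @param K number of states (>= 1).
#' @param obs_kind `"mean_and_cov"` or `"zero_mean_cov"`.
#' @param max_iter maximum variational EM iterations.
#' @param tol relative free-energy change declaring convergence
#'   (full-batch mode).
#' @param n_runs independent seeded runs; the run with the lowest final
#'   free energy is kept.
#' @param seed integer seed; per-run seeds are derived from it.
#' @param batch_size `"full"` for standard variational inference, or the
#'   number of segments per stochastic batch.
#' @param dir_alpha,stickiness Dirichlet concentration and diagonal boost
#'   for transition rows.
#' @param kappa0 prior mean-precision scaling (mean_and_cov only).
#' @param forget,delay stochastic step-size schedule
#'   `rho_i = (i + delay)^(-forget)`.
#' @return An object of class `hmm_config`.
#' @export
hmm_config <- function(K, obs_kind = c("mean_and_cov", "zero_mean_cov"),
                       max_iter = 100L, tol = 1e-6, n_runs = 1L, seed = 1L,
                       batch_size = "full", dir_alpha = 1, stickiness = 10,
                       kappa0 = 0.1, forget = 0.6, delay = 1) {
  obs_kind <- match.arg(obs_kind)
  K <- as.integer(K)
  if (K < 1L) stopf("K must be >= 1")
  if (tol <= 0) stopf("tol must be > 0")
  structure(list(K = K, obs_kind = obs_kind, max_iter = as.integer(max_iter),
                 tol = tol, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), batch_size = batch_size,
                 dir_alpha = dir_alpha, stickiness = stickiness,
                 kappa0 = kappa0, forget = forget, delay = delay),
            class = "hmm_config")
}

# Resolved prior hyperparameters for a dataset.
#' @noRd
hmm_priors <- function(X, config) {
  D <- ncol(X)
  K <- config$K
  U0 <- matrix(config$dir_alpha, K, K) + diag(config$stickiness, K)
  Psi0 <- stats::cov(X)
  # guard near-singular empirical covariance
  Psi0 <- Psi0 + diag(1e-8 * max(diag(Psi0), 1e-12), D)
  list(U0 = U0, w0 = rep(config$dir_alpha, K),
       m0 = colMeans(X), kappa0 = config$kappa0,
       Psi0 = Psi0, nu0 = D + 2)
}

# ---- expected-parameter pieces -------------------------------------------

# Expected log emission densities under q(mu, Sigma), S x K.
#' @noRd
expected_logB <- function(X, states, obs_kind) {
  S <- nrow(X); D <- ncol(X)
  logB <- matrix(0, S, length(states))
  for (k in seq_along(states)) {
    st <- states[[k]]
    R <- chol(st$Psi)
    elogdet <- mvdigamma(st$nu / 2, D) + D * log(2) -
      2 * sum(log(diag(R)))
    z <- forwardsolve(t(R), t(X) - st$m)
    q <- colSums(z^2)
    extra <- if (obs_kind == "mean_and_cov") D / st$kappa else 0
    logB[, k] <- 0.5 * elogdet - 0.5 * D * log(2 * pi) -
      0.5 * (st$nu * q + extra)
  }
  logB
}

#' @noRd
dirichlet_elog <- function(u) {
  if (is.matrix(u)) digamma(u) - digamma(rowSums(u))
  else digamma(u) - digamma(sum(u))
}

#' @noRd
kl_dirichlet <- function(a, b) {
  sum(lgamma(sum(a)) - lgamma(sum(b)) - sum(lgamma(a) - lgamma(b)) +
        sum((a - b) * (digamma(a) - digamma(sum(a)))))
}

# KL of posterior (normal-)inverse-Wishart from prior, via the Wishart dual.
#' @noRd
kl_emission <- function(st, pri, obs_kind) {
  D <- nrow(st$Psi)
  ld1 <- determinant(st$Psi, logarithm = TRUE)$modulus
  ld0 <- determinant(pri$Psi0, logarithm = TRUE)$modulus
  P0iP1 <- sum(diag(solve(st$Psi, pri$Psi0)))  # tr(Psi0 Psi1^-1)
  kl <- -(pri$nu0 / 2) * (ld0 - ld1) +
    (st$nu / 2) * (P0iP1 - D) +
    lmvgamma(pri$nu0 / 2, D) - lmvgamma(st$nu / 2, D) +
    ((st$nu - pri$nu0) / 2) * mvdigamma(st$nu / 2, D)
  if (obs_kind == "mean_and_cov") {
    dm <- st$m - pri$m0
    quad <- drop(crossprod(dm, solve(st$Psi, dm)))
    kl <- kl + 0.5 * (pri$kappa0 * st$nu * quad +
                        D * pri$kappa0 / st$kappa - D +
                        D * log(st$kappa / pri$kappa0))
  }
  as.numeric(kl)
}

# ---- E and M steps --------------------------------------------------------

# Forward-backward over the listed segments with expected-log parameters.
# Returns per-state gamma, summed xi, initial-sample gamma sums, total
# log normalizer, and the energy term sum(gamma * logB) etc.
#' @noRd
vb_estep <- function(X, T, post, obs_kind, segments = NULL) {
  K <- nrow(post$U)
  ElogA <- dirichlet_elog(post$U)
  Elogpi <- dirichlet_elog(post$w)
  At <- exp(ElogA); pit <- exp(Elogpi)
  offs <- cumsum(c(0L, T))
  if (is.null(segments)) segments <- seq_along(T)

  gamma <- matrix(0, sum(T[segments]), K)
  xi <- matrix(0, K, K)
  g1 <- numeric(K)
  loglik <- 0
  energy <- 0
  row0 <- 0L
  for (s in segments) {
    sl <- (offs[s] + 1L):offs[s + 1L]
    logB <- expected_logB(X[sl, , drop = FALSE], post$states, obs_kind)
    fb <- fb_segment(logB, At, pit)
    g <- fb$gamma
    gamma[row0 + seq_along(sl), ] <- g
    row0 <- row0 + length(sl)
    xi <- xi + fb$xi_sum
    g1 <- g1 + g[1L, ]
    loglik <- loglik + fb$loglik
    energy <- energy + sum(g * logB) + sum(fb$xi_sum * ElogA) +
      sum(g[1L, ] * Elogpi)
  }
  list(gamma = gamma, xi = xi, g1 = g1, loglik = loglik, energy = energy)
}

# Expected sufficient statistics of the emissions from responsibilities.
#' @noRd
emission_stats <- function(X, gamma, obs_kind) {
  K <- ncol(gamma); D <- ncol(X)
  Nk <- colSums(gamma)
  if (obs_kind == "zero_mean_cov") {
    Sk <- lapply(seq_len(K), function(k) crossprod(X * gamma[, k], X))
    list(Nk = Nk, ybar = matrix(0, K, D), Sk = Sk)
  } else {
    ybar <- matrix(0, K, D)
    Sk <- vector("list", K)
    for (k in seq_len(K)) {
      if (Nk[k] > 1e-12) {
        ybar[k, ] <- colSums(X * gamma[, k]) / Nk[k]
        Xc <- sweep(X, 2, ybar[k, ])
        Sk[[k]] <- crossprod(Xc * gamma[, k], Xc)
      } else {
        Sk[[k]] <- matrix(0, D, D)
      }
    }
    list(Nk = Nk, ybar = ybar, Sk = Sk)
  }
}

# Conjugate posterior update from (possibly rescaled) sufficient stats.
#' @noRd
posterior_from_stats <- function(stats, xi, g1, pri, obs_kind) {
  K <- length(stats$Nk); D <- length(pri$m0)
  states <- vector("list", K)
  for (k in seq_len(K)) {
    Nk <- stats$Nk[k]
    if (obs_kind == "mean_and_cov") {
      kap <- pri$kappa0 + Nk
      m <- (pri$kappa0 * pri$m0 + Nk * stats$ybar[k, ]) / kap
      dm <- stats$ybar[k, ] - pri$m0
      Psi <- pri$Psi0 + stats$Sk[[k]] +
        (pri$kappa0 * Nk / kap) * tcrossprod(dm)
      states[[k]] <- list(m = m, kappa = kap, Psi = (Psi + t(Psi)) / 2,
                          nu = pri$nu0 + Nk)
    } else {
      Psi <- pri$Psi0 + stats$Sk[[k]]
      states[[k]] <- list(m = rep(0, D), kappa = Inf,
                          Psi = (Psi + t(Psi)) / 2, nu = pri$nu0 + Nk)
    }
  }
  list(U = pri$U0 + xi, w = pri$w0 + g1, states = states)
}

#' @noRd
param_kl <- function(post, pri, obs_kind) {
  kl <- kl_dirichlet(post$w, pri$w0)
  for (j in seq_len(nrow(post$U)))
    kl <- kl + kl_dirichlet(post$U[j, ], pri$U0[j, ])
  for (st in post$states) kl <- kl + kl_emission(st, pri, obs_kind)
  kl
}

# Initial responsibilities: short k-means on (smoothed) observations,
# perturbed by the run seed.
#' @noRd
init_gamma <- function(X, K, obs_kind, run_seed) {
  set.seed(run_seed)
  S <- nrow(X)
  if (K == 1L) return(matrix(1, S, 1L))
  feats <- if (obs_kind == "zero_mean_cov") {
    sqrt(apply(X^2, 2, moving_average, w = 25L))
  } else X
  km <- tryCatch(kmeans(feats, K, iter.max = 20L, nstart = 1L),
                 error = function(e) NULL)
  labels <- if (is.null(km)) sample.int(K, S, replace = TRUE) else km$cluster
  gamma <- matrix(0.1 / K, S, K)
  gamma[cbind(seq_len(S), labels)] <- gamma[cbind(seq_len(S), labels)] + 0.9
  noise <- matrix(runif(S * K, 0, 0.05), S, K)
  gamma <- gamma + noise
  gamma / rowSums(gamma)
}

# Transition pseudo-counts from hard-ish responsibilities, per segment.
#' @noRd
init_xi <- function(gamma, T) {
  K <- ncol(gamma)
  offs <- cumsum(c(0L, T))
  xi <- matrix(0, K, K)
  g1 <- numeric(K)
  for (s in seq_along(T)) {
    sl <- (offs[s] + 1L):offs[s + 1L]
    g <- gamma[sl, , drop = FALSE]
    if (length(sl) > 1L)
      xi <- xi + crossprod(g[-nrow(g), , drop = FALSE],
                           g[-1L, , drop = FALSE])
    g1 <- g1 + g[1L, ]
  }
  list(xi = xi, g1 = g1)
}

# One full VB run. Returns an hmm_fit plus gamma for the whole dataset.
#' @noRd
vb_run <- function(X, T, config, pri, run_seed) {
  obs_kind <- config$obs_kind
  gamma0 <- init_gamma(X, config$K, obs_kind, run_seed)
  ix <- init_xi(gamma0, T)
  post <- posterior_from_stats(emission_stats(X, gamma0, obs_kind),
                               ix$xi, ix$g1, pri, obs_kind)

  stochastic <- !identical(config$batch_size, "full")
  if (stochastic) {
    bs <- as.integer(config$batch_size)
    if (bs > length(T)) stopf("batch_size %d exceeds %d segments", bs,
                              length(T))
  }
  total_T <- sum(T)
  fe_trace <- numeric(0)
  set.seed(run_seed + 1L)

  for (it in seq_len(config$max_iter)) {
    if (!stochastic) {
      e <- vb_estep(X, T, post, obs_kind)
      kl <- param_kl(post, pri, obs_kind)
      fe <- kl - e$loglik
      if (!is.finite(fe)) stopf("non-finite free energy at iteration %d", it)
      fe_trace <- c(fe_trace, fe)
      post_new <- posterior_from_stats(
        emission_stats(X, e$gamma, obs_kind), e$xi, e$g1, pri, obs_kind)
      post <- post_new
      if (it > 1L) {
        rel <- abs(fe_trace[it - 1L] - fe) / max(abs(fe), 1)
        if (rel < config$tol) break
      }
    } else {
      segs <- sample(seq_along(T), bs)
      offs <- cumsum(c(0L, T))
      rows <- unlist(lapply(segs, function(s) (offs[s] + 1L):offs[s + 1L]))
      e <- vb_estep(X, T, post, obs_kind, segments = segs)
      scale_T <- total_T / sum(T[segs])
      scale_seg <- length(T) / bs
      st <- emission_stats(X[rows, , drop = FALSE], e$gamma, obs_kind)
      st$Nk <- st$Nk * scale_T
      st$Sk <- lapply(st$Sk, `*`, scale_T)
      target <- posterior_from_stats(st, e$xi * scale_T, e$g1 * scale_seg,
                                     pri, obs_kind)
      rho <- (it + config$delay)^(-config$forget)
      post <- blend_posteriors(post, target, rho)
      kl <- param_kl(post, pri, obs_kind)
      fe_trace <- c(fe_trace, kl - e$loglik * scale_T)
    }
  }

  # final decode over the full dataset with the final posterior
  e <- vb_estep(X, T, post, obs_kind)
  fe_final <- param_kl(post, pri, obs_kind) - e$loglik
  fe_trace <- c(fe_trace, fe_final)

  D <- ncol(X)
  EA <- post$U / rowSums(post$U)
  Epi <- post$w / sum(post$w)
  states <- lapply(post$states, function(st) {
    list(mean = if (obs_kind == "mean_and_cov") st$m else rep(0, D),
         cov = st$Psi / (st$nu - D - 1),
         m = st$m, kappa = st$kappa, Psi = st$Psi, nu = st$nu)
  })
  occ <- colSums(e$gamma)
  fit <- structure(
    list(transition_matrix = EA, initial_probs = Epi, states = states,
         trans_post = post$U, init_post = post$w,
         free_energy_trace = fe_trace, final_free_energy = fe_final,
         effective_K = sum(occ >= config$K * D),
         state_occupancy = occ, config = config, priors = pri, D = D,
         obs_kind = obs_kind, run_seed = run_seed),
    class = "hmm_fit")
  list(fit = fit, gamma = e$gamma)
}

# Convex interpolation of natural parameters (stochastic update).
#' @noRd
blend_posteriors <- function(old, target, rho) {
  states <- vector("list", length(old$states))
  for (k in seq_along(states)) {
    o <- old$states[[k]]; t <- target$states[[k]]
    states[[k]] <- list(
      m = ((1 - rho) * ifelse(is.finite(o$kappa), o$kappa, 0) * o$m +
             rho * ifelse(is.finite(t$kappa), t$kappa, 0) * t$m) /
        max((1 - rho) * ifelse(is.finite(o$kappa), o$kappa, 0) +
              rho * ifelse(is.finite(t$kappa), t$kappa, 0), 1e-12),
      kappa = if (is.finite(o$kappa)) (1 - rho) * o$kappa + rho * t$kappa
              else Inf,
      Psi = (1 - rho) * o$Psi + rho * t$Psi,
      nu = (1 - rho) * o$nu + rho * t$nu)
  }
  list(U = (1 - rho) * old$U + rho * target$U,
       w = (1 - rho) * old$w + rho * target$w,
       states = states)
}

#' State time-course container
#'
#' Per-sample posterior state probabilities (`gamma`) and the hard Viterbi
#' path (`vpath`), aligned to a [segmented_dataset()].
#'
#' @param gamma S x K matrix; rows sum to 1.
#' @param vpath length-S integer path in 1..K.
#' @param T segment lengths.
#' @param sample_index per-row (session, original sample) map.
#' @param fs sampling rate in Hz.
#' @return An object of class `state_tc`.
#' @export
state_tc <- function(gamma, vpath, T, sample_index = NULL, fs = NA) {
  gamma <- as.matrix(gamma)
  if (sum(T) != nrow(gamma)) stopf("gamma rows inconsistent with T")
  if (max(abs(rowSums(gamma) - 1)) > 1e-8)
    stopf("gamma rows must sum to 1")
  if (length(vpath) != nrow(gamma)) stopf("vpath length inconsistent")
  structure(list(gamma = gamma, vpath = as.integer(vpath),
                 T = as.integer(T), sample_index = sample_index, fs = fs),
            class = "state_tc")
}

#' Fit a variational Bayes Gaussian HMM
#'
#' Variational EM on the concatenated good segments: the E-step runs a
#' scaled forward-backward independently within each segment (so the model
#' never explains a transition across a discontinuity), and the M-step
#' applies conjugate posterior updates. In full-batch mode iterations
#' continue until the relative free-energy change falls below `tol`; in
#' batched mode each iteration updates from a random subset of segments
#' with a stochastic natural-gradient interpolation. States whose total
#' expected occupancy falls below a floor of K*D samples are counted out
#' of `effective_K` (the variational optimisation itself is what empties
#' excess states).
#'
#' With `n_runs > 1`, independent seeded runs are fitted and the one with
#' the lowest final free energy returned (per-run free energies are kept
#' in `run_free_energies`).
#'
#' @param dataset a [segmented_dataset()].
#' @param config an [hmm_config()].
#' @return A list with `fit` (an `hmm_fit`) and `stc` (a [state_tc()] for
#'   the full dataset, including the Viterbi path).
#' @export
fit_hmm <- function(dataset, config) {
  stopifnot(inherits(dataset, "segmented_dataset"),
            inherits(config, "hmm_config"))
  X <- dataset$X
  if (config$K > nrow(X)) stopf("K = %d exceeds %d samples", config$K,
                                nrow(X))
  pri <- hmm_priors(X, config)
  runs <- lapply(seq_len(config$n_runs), function(r) {
    vb_run(X, dataset$T, config, pri,
           run_seed = stage_seed(config$seed, paste0("run", r)))
  })
  fes <- vapply(runs, function(r) r$fit$final_free_energy, 0)
  best <- select_best_run(lapply(runs, `[[`, "fit"))
  fit <- runs[[best]]$fit
  fit$run_free_energies <- fes
  vpath <- viterbi_decode(fit, dataset)
  stc <- state_tc(runs[[best]]$gamma, vpath, dataset$T,
                  dataset$sample_index, dataset$meta$fs %||% NA)
  list(fit = fit, stc = stc)
}

# Plug-in log emission densities at the posterior expected parameters.
#' @noRd
plugin_logB <- function(fit, X) {
  K <- length(fit$states)
  logB <- matrix(0, nrow(X), K)
  for (k in seq_len(K))
    logB[, k] <- mvn_logdens(X, fit$states[[k]]$mean, fit$states[[k]]$cov)
  logB
}

#' Posterior state probabilities under the fitted expected parameters
#'
#' Runs the scaled forward-backward per segment using the plug-in
#' posterior-expected transition matrix, initial distribution and Gaussian
#' emission parameters. This is the decoding counterpart of
#' [viterbi_decode()] and the quantity checked against exhaustive
#' enumeration in the tests.
#'
#' @param fit an `hmm_fit`.
#' @param dataset a [segmented_dataset()].
#' @return S x K matrix of smoothed state probabilities.
#' @export
posterior_decode <- function(fit, dataset) {
  X <- dataset$X
  offs <- cumsum(c(0L, dataset$T))
  gamma <- matrix(0, nrow(X), length(fit$states))
  for (s in seq_along(dataset$T)) {
    sl <- (offs[s] + 1L):offs[s + 1L]
    fb <- fb_segment(plugin_logB(fit, X[sl, , drop = FALSE]),
                     fit$transition_matrix,
                     fit$initial_probs)
    gamma[sl, ] <- fb$gamma
  }
  gamma
}

#' Viterbi decoding
#'
#' Per segment, the exact maximum-probability state path under the fitted
#' posterior-expected parameters, computed in log space with deterministic
#' tie-breaking to the lowest state index.
#'
#' @param fit an `hmm_fit`.
#' @param dataset a [segmented_dataset()].
#' @return Integer path of length `nrow(dataset$X)`.
#' @export
viterbi_decode <- function(fit, dataset) {
  X <- dataset$X
  if (length(fit$states[[1]]$mean) != ncol(X))
    stopf("fit dimension %d does not match data dimension %d",
          length(fit$states[[1]]$mean), ncol(X))
  logA <- log(pmax(fit$transition_matrix, 1e-300))
  logpi <- log(pmax(fit$initial_probs, 1e-300))
  offs <- cumsum(c(0L, dataset$T))
  path <- integer(nrow(X))
  for (s in seq_along(dataset$T)) {
    sl <- (offs[s] + 1L):offs[s + 1L]
    path[sl] <- as.integer(viterbi_segment(
      plugin_logB(fit, X[sl, , drop = FALSE]), logA, logpi))
  }
  path
}

#' Variational free energy of a fit on a dataset
#'
#' Recomputes the variational free energy (negative evidence lower bound):
#' expected energy minus state-sequence entropy plus the KL divergence of
#' the parameter posteriors from their priors. Lower is better. The
#' decomposition is attached as attribute `"decomposition"`.
#'
#' @param fit an `hmm_fit`.
#' @param dataset a [segmented_dataset()].
#' @return Scalar free energy with a `decomposition` attribute listing
#'   `energy` (expected log joint under expected log parameters),
#'   `entropy` (of the state-sequence posterior) and `param_kl`.
#' @export
free_energy <- function(fit, dataset) {
  post <- list(U = fit$trans_post, w = fit$init_post,
               states = lapply(fit$states, function(s)
                 list(m = s$m, kappa = s$kappa, Psi = s$Psi, nu = s$nu)))
  e <- vb_estep(dataset$X, dataset$T, post, fit$obs_kind)
  kl <- param_kl(post, fit$priors, fit$obs_kind)
  fe <- kl - e$loglik
  attr(fe, "decomposition") <- list(energy = e$energy,
                                    entropy = e$loglik - e$energy,
                                    param_kl = kl)
  fe
}

#' Select the best of several runs by free energy
#'
#' @param fits list of `hmm_fit` objects fitted to the same data and
#'   configuration with different seeds.
#' @return Index of the fit with the lowest final free energy; ties break
#'   to the lowest index.
#' @export
select_best_run <- function(fits) {
  if (!length(fits)) stopf("empty fit list")
  fes <- vapply(fits, function(f) f$final_free_energy, 0)
  which.min(fes)
}

# All permutations of 1..n (n small).
#' @noRd
permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

#' Match fitted states to reference states
#'
#' Finds the state permutation minimising the summed Euclidean distance
#' between fitted and reference descriptors (means, or vectorised
#' covariances for zero-mean models). Exhaustive over permutations, so
#' intended for the small K typical of these models. Used for reporting
#' and parameter-recovery checks only; inference never depends on labels.
#'
#' @param fitted matrix with one descriptor row per fitted state.
#' @param reference matrix with one descriptor row per reference state.
#' @return Integer vector `perm` such that fitted state `perm[j]` matches
#'   reference state `j`.
#' @export
match_states <- function(fitted, reference) {
  fitted <- as.matrix(fitted); reference <- as.matrix(reference)
  K <- nrow(reference)
  if (K > 8L) stopf("exhaustive matching limited to K <= 8")
  perms <- permutations(K)
  cost <- apply(perms, 1, function(p)
    sum(sqrt(rowSums((fitted[p, , drop = FALSE] - reference)^2))))
  as.integer(unname(perms[which.min(cost), ]))
}
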