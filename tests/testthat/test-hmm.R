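test_that("forward-backward and Viterbi match exhaustive enumeration", {
  for (case in 1:6) {
    K <- sample(2:3, 1)
    T <- sample(4:8, 1)
    D <- 2
    p <- random_params(K, D, seed = 100 + case)
    X <- matrix(rnorm(T * D, sd = 2), T, D)
    fit <- make_plugin_fit(p$means, p$covs, p$A, p$pi0)
    ds <- make_dataset(X, T)

    logB <- vapply(seq_len(K), function(k)
      oracle_mvn_logdens(X, p$means[[k]], p$covs[[k]]), numeric(T))
    g_ref <- enum_gamma(logB, p$A, p$pi0)
    v_ref <- enum_viterbi(logB, p$A, p$pi0)

    expect_lt(max(abs(posterior_decode(fit, ds) - g_ref)), 1e-8)
    expect_identical(viterbi_decode(fit, ds), v_ref)
  }
})

test_that("decoding respects segment boundaries independently", {
  p <- random_params(3, 2, seed = 42)
  set.seed(43)
  X1 <- matrix(rnorm(12), 6, 2); X2 <- matrix(rnorm(10), 5, 2)
  fit <- make_plugin_fit(p$means, p$covs, p$A, p$pi0)
  g12 <- posterior_decode(fit, make_dataset(rbind(X1, X2), c(6L, 5L)))
  g21 <- posterior_decode(fit, make_dataset(rbind(X2, X1), c(5L, 6L)))
  expect_equal(g12[1:6, ], g21[6:11, ], tolerance = 1e-12)
  expect_equal(g12[7:11, ], g21[1:5, ], tolerance = 1e-12)
})

test_that("K = 1 reduces to the conjugate Gaussian model exactly", {
  set.seed(44)
  S <- 150; D <- 2
  X <- matrix(rnorm(S * D), S, D) + 3
  ds <- make_dataset(X)
  res <- fit_hmm(ds, hmm_config(K = 1, max_iter = 5, seed = 1))
  expect_true(all(res$stc$gamma == 1))
  expect_equal(res$fit$transition_matrix, matrix(1, 1, 1))

  # oracle: closed-form normal-inverse-Wishart log evidence
  pri <- res$fit$priors
  lmvg <- function(a, D) 0.25 * D * (D - 1) * log(pi) +
    sum(lgamma(a + (1 - seq_len(D)) / 2))
  kapn <- pri$kappa0 + S; nun <- pri$nu0 + S
  ybar <- colMeans(X)
  Psin <- pri$Psi0 + crossprod(sweep(X, 2, ybar)) +
    pri$kappa0 * S / kapn * tcrossprod(ybar - pri$m0)
  logev <- -0.5 * S * D * log(pi) + lmvg(nun / 2, D) - lmvg(pri$nu0 / 2, D) +
    0.5 * pri$nu0 * determinant(pri$Psi0, TRUE)$modulus -
    0.5 * nun * determinant(Psin, TRUE)$modulus +
    0.5 * D * (log(pri$kappa0) - log(kapn))
  expect_equal(as.numeric(free_energy(res$fit, ds)), -as.numeric(logev),
               tolerance = 1e-6)
})

test_that("free energy equals the trace tail and decomposes", {
  set.seed(45)
  sim <- simulate_gaussian_hmm(figure_chain_spec(seed = 5), 2000)
  ds <- make_dataset(sim$data)
  res <- fit_hmm(ds, hmm_config(K = 3, max_iter = 40, seed = 2))
  fe <- free_energy(res$fit, ds)
  expect_equal(as.numeric(fe), tail(res$fit$free_energy_trace, 1),
               tolerance = 1e-6)
  d <- attr(fe, "decomposition")
  expect_equal(as.numeric(fe), -(d$energy + d$entropy) + d$param_kl,
               tolerance = 1e-8)
  expect_gt(d$param_kl, 0)
})

test_that("full-batch free energy is non-increasing", {
  for (case in 1:8) {
    set.seed(200 + case)
    K <- sample(2:3, 1)
    X <- matrix(rnorm(600 * 2), 600, 2) +
      rep(c(0, 3), each = 300) * sample(c(0, 1), 1)
    ds <- make_dataset(X, c(300L, 300L))
    res <- fit_hmm(ds, hmm_config(K = K, max_iter = 25, seed = case))
    expect_lte(max(diff(res$fit$free_energy_trace)), 1e-6)
  }
})

test_that("generating means are recovered on the two-node chain", {
  spec <- figure_chain_spec(seed = 7)
  sim <- simulate_gaussian_hmm(spec, 10000)
  ds <- make_dataset(sim$data)
  res <- fit_hmm(ds, hmm_config(K = 3, n_runs = 5, max_iter = 60, seed = 11))
  means <- t(sapply(res$fit$states, `[[`, "mean"))
  ref <- do.call(rbind, spec$means)
  perm <- match_states(means, ref)
  expect_lt(max(abs(means[perm, ] - ref)), 0.1)
  # hard assignments track the truth after relabelling
  acc <- mean(perm[sim$true_path] == res$stc$vpath)
  expect_gt(acc, 0.9)
})

test_that("transition matrix is recovered from a long realisation", {
  spec <- figure_chain_spec(seed = 23)
  sim <- simulate_gaussian_hmm(spec, 100000)
  ds <- make_dataset(sim$data)
  res <- fit_hmm(ds, hmm_config(K = 3, max_iter = 50, seed = 3))
  perm <- match_states(t(sapply(res$fit$states, `[[`, "mean")),
                       do.call(rbind, spec$means))
  A <- res$fit$transition_matrix[perm, perm]
  expect_lt(max(abs(A - spec$transition_matrix)), 0.05)
})

test_that("zero-mean observation model never produces a nonzero mean", {
  set.seed(46)
  X <- matrix(rnorm(3000 * 4), 3000, 4) + 5  # offset must be ignored
  ds <- make_dataset(X)
  res <- fit_hmm(ds, hmm_config(K = 2, obs_kind = "zero_mean_cov",
                                max_iter = 15, seed = 4))
  for (st in res$fit$states) expect_identical(st$mean, rep(0, 4))
})

test_that("stochastic batched inference still recovers the states", {
  spec <- figure_chain_spec(seed = 9)
  sim <- simulate_gaussian_hmm(spec, 10000)
  ds <- make_dataset(sim$data, T = rep(500L, 20L))
  res <- fit_hmm(ds, hmm_config(K = 3, batch_size = 5, max_iter = 60,
                                seed = 6))
  means <- t(sapply(res$fit$states, `[[`, "mean"))
  perm <- match_states(means, do.call(rbind, spec$means))
  expect_lt(max(abs(means[perm, ] - do.call(rbind, spec$means))), 0.15)
  expect_error(fit_hmm(ds, hmm_config(K = 3, batch_size = 50)),
               "batch_size")
})

test_that("well-separated states make Viterbi agree with gamma argmax", {
  set.seed(47)
  means <- list(c(0, 0), c(20, 20))
  path <- rep(c(1L, 2L), each = 250)
  X <- do.call(rbind, lapply(path, function(k)
    rnorm(2) + means[[k]]))
  ds <- make_dataset(X)
  res <- fit_hmm(ds, hmm_config(K = 2, max_iter = 20, seed = 5))
  expect_identical(res$stc$vpath, max.col(res$stc$gamma))
})

test_that("run selection picks the lowest free energy", {
  mk <- function(fe) structure(list(final_free_energy = fe),
                               class = "hmm_fit")
  expect_identical(select_best_run(list(mk(-10), mk(-12), mk(-11))), 2L)
  expect_identical(select_best_run(list(mk(5))), 1L)
  expect_identical(select_best_run(list(mk(1), mk(1))), 1L)
  expect_error(select_best_run(list()), "empty")
})

test_that("best-of-runs selection is no worse than the median run", {
  errs_sel <- errs_med <- numeric(6)
  ref <- do.call(rbind, figure_chain_spec()$means)
  for (r in 1:6) {
    sim <- simulate_gaussian_hmm(figure_chain_spec(seed = 300 + r), 3000)
    ds <- make_dataset(sim$data)
    fits <- lapply(1:5, function(i)
      fit_hmm(ds, hmm_config(K = 3, n_runs = 1, max_iter = 40,
                             seed = 1000 * r + i))$fit)
    errs <- vapply(fits, function(f) {
      m <- t(sapply(f$states, `[[`, "mean"))
      perm <- match_states(m, ref)
      max(abs(m[perm, ] - ref))
    }, 0)
    best <- select_best_run(fits)
    errs_sel[r] <- errs[best]
    errs_med[r] <- median(errs)
  }
  # ties between converged runs differ only by numerical noise
  expect_lte(mean(errs_sel), mean(errs_med) + 1e-4)
})

test_that("invalid configurations are rejected", {
  expect_error(hmm_config(K = 0), "K must be")
  expect_error(hmm_config(K = 2, tol = 0), "tol")
  X <- matrix(rnorm(8), 4, 2)
  expect_error(fit_hmm(make_dataset(X), hmm_config(K = 10)), "exceeds")
})

test_that("state matching finds a planted permutation", {
  set.seed(48)
  ref <- matrix(rnorm(12), 4, 3)
  q <- c(3L, 1L, 4L, 2L)
  fitted <- ref[q, ] + rnorm(12, sd = 0.01)
  p <- match_states(fitted, ref)
  expect_equal(fitted[p, ], ref, tolerance = 0.1)
  expect_identical(p, order(q))
})
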