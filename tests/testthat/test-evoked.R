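test_that("epoching slices gamma exactly and drops boundary trials", {
  set.seed(15)
  S <- 400; K <- 3
  g <- matrix(runif(S * K), S, K); g <- g / rowSums(g)
  stc <- state_tc(g, max.col(g), S,
                  sample_index = data.frame(session = 1L, sample = 0:(S - 1)),
                  fs = 250)
  ev <- data.frame(onset_sample = 100L, condition = "Famous_First")
  ep <- epoch_gamma(stc, ev, window_ms = c(0, 8))
  expect_equal(dim(ep$values), c(1L, 3L, 3L))
  expect_equal(ep$values[1, , ], g[101:103, ])  # samples 100..102, 0-based

  # window overrunning the recording end is dropped and counted
  ev2 <- data.frame(onset_sample = c(100L, 399L),
                    condition = c("Famous_First", "Famous_First"))
  ep2 <- epoch_gamma(stc, ev2, window_ms = c(0, 100))
  expect_equal(dim(ep2$values)[1], 1L)
  expect_equal(ep2$n_dropped, 1L)

  # arbitrary events equal a manual slicing oracle
  ons <- sort(sample(50:300, 8))
  ev3 <- data.frame(onset_sample = ons, condition = "Scrambled_Last")
  ep3 <- epoch_gamma(stc, ev3, window_ms = c(-40, 40))
  offs <- seq(round(-40 * 250 / 1000), round(40 * 250 / 1000))
  for (i in seq_along(ons))
    expect_equal(ep3$values[i, , ], g[ons[i] + offs + 1L, ])
})

test_that("trials crossing a segment discontinuity are dropped", {
  S <- 200; K <- 2
  g <- matrix(0.5, S, K)
  # two segments: original samples 0..99 and 120..219 of one session
  si <- data.frame(session = 1L, sample = c(0:99, 120:219))
  stc <- state_tc(g, rep(1L, S), c(100L, 100L), sample_index = si, fs = 250)
  ev <- data.frame(onset_sample = c(50L, 95L, 150L),
                   condition = "Famous_First")
  ep <- epoch_gamma(stc, ev, window_ms = c(-20, 40))
  expect_equal(dim(ep$values)[1], 2L)  # the onset-95 window hits the gap
  expect_equal(ep$n_dropped, 1L)
})

test_that("baseline normalisation subtracts the per-trial baseline mean", {
  vals <- array(0.2, c(2, 10, 3))
  vals[1, 6:10, 1] <- 0.33
  time_ms <- seq(-130, by = 30, length.out = 10)
  ep <- make_epochs(vals, rep("Famous_First", 2), time_ms = time_ms)
  bn <- baseline_normalise(ep, baseline_ms = c(-130, -30))
  expect_equal(bn$values[2, , ], matrix(0, 10, 3))       # constant trial
  expect_equal(bn$values[1, 10, 1], 0.13)                # 0.33 - 0.2
  # batch equals a per-trial loop oracle
  base_idx <- which(time_ms >= -130 & time_ms <= -30)
  for (tr in 1:2) for (k in 1:3)
    expect_equal(bn$values[tr, , k],
                 vals[tr, , k] - mean(vals[tr, base_idx, k]))
  expect_error(baseline_normalise(ep, baseline_ms = c(-500, -400)),
               "baseline")
})

test_that("first-level COPEs equal hand-computed OLS contrasts", {
  conds <- rep(c("Famous_First", "Unfamiliar_First", "Scrambled_First"),
               each = 2)
  vals <- array(0, c(6, 4, 2))
  mu <- c(0.5, 0.5, 0.3, 0.3, 0.1, 0.1)
  for (i in 1:6) vals[i, , ] <- mu[i]
  fl <- first_level_glm(make_epochs(vals, conds))
  expect_equal(fl$cope[1, 1, 1], mean(mu))               # mean contrast
  expect_equal(fl$cope[2, 1, 1], (0.5 + 0.3) / 2 - 0.1)  # faces - scrambled
  expect_equal(fl$cope[3, 1, 1], 0.5 - 0.3)              # famous - unfamiliar

  # oracle: hand OLS with pseudo-inverse on the demeaned-indicator design
  X <- cbind(1,
             as.numeric(grepl("Famous", conds) & !grepl("Un", conds)) - 1 / 3,
             as.numeric(grepl("Unfamiliar", conds)) - 1 / 3,
             as.numeric(grepl("Scrambled", conds)) - 1 / 3)
  beta <- MASS::ginv(X) %*% mu
  expect_equal(fl$cope[2, 2, 2], drop(c(0, 0.5, 0.5, -1) %*% beta))

  # identical values across trials: differential COPEs vanish
  flat <- array(0.4, c(6, 4, 2))
  fl2 <- first_level_glm(make_epochs(flat, conds))
  expect_equal(fl2$cope[2, , ], matrix(0, 4, 2))
  expect_equal(fl2$cope[1, 1, 1], 0.4)
})

test_that("a missing condition voids only its contrasts", {
  conds <- rep(c("Famous_First", "Unfamiliar_First"), each = 3)
  vals <- array(rnorm(6 * 4 * 2, sd = 0.1), c(6, 4, 2))
  expect_warning(fl <- first_level_glm(make_epochs(vals, conds)),
                 "rank")
  expect_true(all(is.na(fl$cope[2, , ])))     # needs Scrambled
  expect_false(anyNA(fl$cope[3, , ]))          # famous vs unfamiliar fine
  expect_false(anyNA(fl$cope[1, , ]))
})

test_that("group-level mixed effects match the closed form", {
  mk_fl <- function(cope_val, var_val) {
    cope <- array(cope_val, c(3, 2, 2))
    varcope <- array(var_val, c(3, 2, 2))
    structure(list(cope = cope, varcope = varcope,
                   contrasts = c("mean", "faces_vs_scrambled",
                                 "famous_vs_unfamiliar"),
                   time_ms = c(0, 4), subject = 1, n_trials = 10),
              class = "first_level")
  }
  # identical subjects: group cope equals the common value
  g <- group_glm(list(mk_fl(0.3, 0.01), mk_fl(0.3, 0.01), mk_fl(0.3, 0.01)))
  expect_equal(g$cope[1, 1, 1], 0.3)

  # two subjects, hand-computable weights
  y <- c(0.2, 0.6); v <- c(0.01, 0.04)
  g2 <- group_glm(list(mk_fl(y[1], v[1]), mk_fl(y[2], v[2])))
  ref <- oracle_dl(y, v)
  expect_equal(g2$cope[1, 1, 1], ref$cope, tolerance = 1e-12)
  expect_equal(g2$stat[1, 1, 1], ref$stat, tolerance = 1e-12)

  # zero between-subject variance reduces to fixed-effects weighting
  y3 <- c(0.3, 0.3, 0.3); v3 <- c(0.01, 0.02, 0.04)
  g3 <- group_glm(list(mk_fl(y3[1], v3[1]), mk_fl(y3[2], v3[2]),
                       mk_fl(y3[3], v3[3])))
  w <- 1 / v3
  expect_equal(g3$cope[1, 1, 1], sum(w * y3) / sum(w))
  expect_equal(g3$se[1, 1, 1], 1 / sqrt(sum(w)))

  expect_warning(g1 <- group_glm(list(mk_fl(0.5, 0.01))), "single subject")
  expect_equal(g1$cope[1, 1, 1], 0.5)
})

test_that("sign-flip max-statistic: identity flip, zero null, planted effect", {
  conds <- rep(c("Famous_First", "Unfamiliar_First", "Scrambled_First"),
               each = 4)
  mk_sub <- function(seed, effect = 0) {
    set.seed(seed)
    vals <- array(rnorm(12 * 20 * 4, sd = 0.05), c(12, 20, 4))
    vals[, 11, 2] <- vals[, 11, 2] + effect
    first_level_glm(make_epochs(vals, conds))
  }

  # all-zero COPEs: nothing significant
  zero_fl <- lapply(1:6, function(s) {
    f <- mk_sub(s)
    f$cope[] <- 0
    f
  })
  msz <- sign_flip_maxstat(zero_fl, n_perm = 100, seed = 1)
  expect_false(any(msz$mean$mask))

  # identity permutation reproduces the observed statistic
  fls <- lapply(1:8, function(s) mk_sub(s, effect = 0.5))
  ms <- sign_flip_maxstat(fls, n_perm = 200, seed = 2)
  expect_equal(ms$mean$null[1], max(abs(ms$mean$stat)))

  # only the planted cell survives correction
  expect_true(ms$mean$mask[11, 2])
  expect_lte(sum(ms$mean$mask) - 1, 1)  # at most one stray cell

  expect_error(sign_flip_maxstat(fls, n_perm = 10), "too small")
})

test_that("tidy evoked export includes every contrast cell", {
  conds <- rep(c("Famous_First", "Unfamiliar_First", "Scrambled_First"),
               each = 3)
  fls <- lapply(1:4, function(s) {
    set.seed(s)
    first_level_glm(make_epochs(
      array(rnorm(9 * 5 * 2, sd = 0.1), c(9, 5, 2)), conds))
  })
  grp <- group_glm(fls)
  ms <- sign_flip_maxstat(fls, n_perm = 50, seed = 3)
  f <- tempfile(fileext = ".tsv")
  df <- write_evoked_results(grp, ms, f)
  expect_equal(nrow(df), 3 * 2 * 5)
  expect_true(all(c("cope", "stat", "significant") %in% names(df)))
})
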