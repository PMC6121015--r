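#' Epoch posterior state probabilities around events
#'
#' Slices the continuous `gamma` time-course around each event onset,
#' yielding a trials x timepoints x states array. Trials whose window
#' touches a bad (missing) sample or crosses a segment boundary are
#' dropped and counted. The state time-course must carry a
#' `sample_index` (as produced by the preprocessing), which maps its rows
#' back to 0-based original sample indices per session; embedded
#' representations are timestamped by their lag-0 sample, so epochs stay
#' aligned with the original time axis.
#'
#' @param stc a [state_tc()] with `sample_index` and known `fs`.
#' @param events data frame with 0-based `onset_sample`, `condition`, and
#'   optionally `session` (defaults to the single session present).
#' @param window_ms two-element window relative to onset, in ms.
#' @param subject subject identifier stored with the epochs.
#' @return An object of class `epoched_occupancy`: `values`
#'   (trials x timepoints x K), `time_ms`, `condition`, `subject`,
#'   `n_dropped`.
#' @export
epoch_gamma <- function(stc, events, window_ms, subject = 1L) {
  stopifnot(inherits(stc, "state_tc"))
  if (is.null(stc$sample_index)) stopf("state time-course has no sample_index")
  if (is.na(stc$fs)) stopf("sampling rate unknown")
  fs <- stc$fs
  offsets <- seq(round(window_ms[1] * fs / 1000),
                 round(window_ms[2] * fs / 1000))
  time_ms <- offsets / fs * 1000
  K <- ncol(stc$gamma)

  si <- stc$sample_index
  if (is.null(events$session)) {
    if (length(unique(si$session)) > 1L)
      stopf("events need a session column for multi-session data")
    events$session <- si$session[1]
  }
  seg_of_row <- rep(seq_along(stc$T), stc$T)

  trials <- list(); cond <- character(0); dropped <- 0L
  for (i in seq_len(nrow(events))) {
    sess <- events$session[i]
    rows_sess <- which(si$session == sess)
    lookup <- rep(NA_integer_, max(si$sample[rows_sess]) + 1L)
    lookup[si$sample[rows_sess] + 1L] <- rows_sess
    want <- events$onset_sample[i] + offsets + 1L
    if (any(want < 1L) || any(want > length(lookup))) { dropped <- dropped + 1L; next }
    rows <- lookup[want]
    if (anyNA(rows) || any(diff(rows) != 1L) ||
        length(unique(seg_of_row[rows])) != 1L) {
      dropped <- dropped + 1L; next
    }
    trials[[length(trials) + 1L]] <- stc$gamma[rows, , drop = FALSE]
    cond <- c(cond, as.character(events$condition[i]))
  }
  if (!length(trials)) stopf("no surviving trials after epoching")
  values <- aperm(simplify2array(trials), c(3, 1, 2))  # trials x time x K
  structure(list(values = values, time_ms = time_ms, condition = cond,
                 subject = subject, n_dropped = dropped, fs = fs),
            class = "epoched_occupancy")
}

#' Baseline-normalise epoched occupancies
#'
#' Subtracts, per trial and state, the mean over the baseline window.
#' Subtraction (not division) is used because occupancies already share
#' the unit occupancy scale and baseline values near zero would make ratios
#' explode.
#'
#' @param ep an [epoch_gamma()] result.
#' @param baseline_ms two-element baseline window in ms relative to onset.
#' @return The normalised `epoched_occupancy`.
#' @export
baseline_normalise <- function(ep, baseline_ms = c(-130, -30)) {
  stopifnot(inherits(ep, "epoched_occupancy"))
  sel <- ep$time_ms >= baseline_ms[1] & ep$time_ms <= baseline_ms[2]
  if (!any(sel)) stopf("baseline window contains no timepoints")
  base <- apply(ep$values[, sel, , drop = FALSE], c(1, 3), mean)
  ep$values <- ep$values - aperm(
    array(base, c(dim(base), length(ep$time_ms))), c(1, 3, 2))
  ep$baseline_ms <- baseline_ms
  ep
}

#' @noRd
face_type <- function(condition) sub("_.*$", "", condition)

#' @noRd
contrast_matrix <- function() {
  rbind(mean = c(1, 0, 0, 0),
        faces_vs_scrambled = c(0, 0.5, 0.5, -1),
        famous_vs_unfamiliar = c(0, 1, -1, 0))
}

#' First-level (within-subject) GLM on epoched occupancies
#'
#' Per timepoint and state, ordinary least squares of the trial values on
#' a four-regressor design: a constant plus demeaned indicators for the
#' Famous, Unfamiliar and Scrambled conditions (trials pooled across
#' repeat levels). Because the demeaned indicators sum to zero the design
#' is rank 3 by construction, so the minimum-norm pseudo-inverse solution
#' is used; all reported contrasts are estimable under it. Three
#' contrasts of parameter estimates (COPEs) are returned: the mean, faces
#' minus scrambled faces, and famous minus unfamiliar faces, each with its
#' variance (VARCOPE).
#'
#' @param ep a (typically baseline-normalised) `epoched_occupancy`.
#' @return A list of class `first_level` with `cope` and `varcope` arrays
#'   (contrast x timepoint x state), `contrasts`, `time_ms`, `subject`.
#' @export
first_level_glm <- function(ep) {
  stopifnot(inherits(ep, "epoched_occupancy"))
  ft <- face_type(ep$condition)
  types <- c("Famous", "Unfamiliar", "Scrambled")
  present <- types %in% ft
  counts <- table(factor(ft, levels = types))
  if (any(counts[present] < 2L))
    stopf("need >= 2 trials per present condition")
  n <- length(ft)
  X <- cbind(1, vapply(types, function(tp)
    as.numeric(ft == tp) - mean(ft == tp), numeric(n)))
  r <- qr(X)$rank
  if (r < 3L) warnf("design rank %d < 3; pseudo-inverse solution", r)
  pinv <- MASS::ginv(X)
  XtXi <- tcrossprod(pinv)  # (X'X)^+
  C <- contrast_matrix()
  missing_contrast <- c(FALSE,
                        !all(present),            # faces vs scrambled
                        !all(present[1:2]))       # famous vs unfamiliar

  nt <- length(ep$time_ms); K <- dim(ep$values)[3]
  Y <- matrix(ep$values, nrow = n)  # trials x (time*K)
  B <- pinv %*% Y
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (n - r)
  cope <- array(NA_real_, c(nrow(C), nt, K))
  varcope <- cope
  for (ci in seq_len(nrow(C))) {
    if (missing_contrast[ci]) next
    cv <- C[ci, ]
    cope[ci, , ] <- matrix(drop(cv %*% B), nt, K)
    varcope[ci, , ] <- matrix(sigma2 * drop(cv %*% XtXi %*% cv), nt, K)
  }
  structure(list(cope = cope, varcope = varcope, contrasts = rownames(C),
                 time_ms = ep$time_ms, subject = ep$subject,
                 n_trials = n), class = "first_level")
}

# Mixed-effects group statistic, vectorised over cells.
# copes, varcopes: subjects x cells matrices. One-step method-of-moments
# estimate of the between-subject variance, then inverse-variance
# weighting.
#' @noRd
group_stat_core <- function(copes, varcopes, var_floor = 1e-12) {
  n <- nrow(copes)
  v <- pmax(varcopes, var_floor)
  w <- 1 / v
  sw <- colSums(w)
  ybar <- colSums(w * copes) / sw
  Q <- colSums(w * sweep(copes, 2, ybar)^2)
  cc <- sw - colSums(w^2) / sw
  tau2 <- pmax(0, (Q - (n - 1)) / pmax(cc, var_floor))
  ws <- 1 / (v + rep(tau2, each = n))
  sws <- colSums(ws)
  cope <- colSums(ws * copes) / sws
  se <- 1 / sqrt(sws)
  list(cope = cope, se = se, stat = cope / se)
}

# Stack first-level results into per-contrast subject x cell matrices.
#' @noRd
stack_first_level <- function(first_levels) {
  contrasts <- first_levels[[1]]$contrasts
  nt <- length(first_levels[[1]]$time_ms)
  K <- dim(first_levels[[1]]$cope)[3]
  lapply(seq_along(contrasts), function(ci) {
    list(copes = t(vapply(first_levels, function(f)
           as.numeric(f$cope[ci, , ]), numeric(nt * K))),
         varcopes = t(vapply(first_levels, function(f)
           as.numeric(f$varcope[ci, , ]), numeric(nt * K))))
  })
}

#' Group-level mixed-effects GLM
#'
#' Per timepoint, state and contrast: the inverse-variance-weighted group
#' mean of the subject COPEs, with a between-subject random-effect
#' variance estimated by a one-step method-of-moments and the first-level
#' VARCOPEs carried as the within-subject variances. The statistic is the
#' weighted mean divided by its standard error.
#'
#' @param first_levels list of [first_level_glm()] results, one per
#'   subject.
#' @return A list of class `group_glm` with `cope`, `se` and `stat`
#'   arrays (contrast x timepoint x state).
#' @export
group_glm <- function(first_levels) {
  if (length(first_levels) < 2L) {
    warnf("single subject: fixed-effects fallback")
    f <- first_levels[[1]]
    return(structure(list(cope = f$cope, se = sqrt(f$varcope),
                          stat = f$cope / sqrt(f$varcope),
                          contrasts = f$contrasts, time_ms = f$time_ms),
                     class = "group_glm"))
  }
  f1 <- first_levels[[1]]
  nt <- length(f1$time_ms); K <- dim(f1$cope)[3]
  stacks <- stack_first_level(first_levels)
  out <- list(cope = array(NA_real_, dim(f1$cope)),
              se = array(NA_real_, dim(f1$cope)),
              stat = array(NA_real_, dim(f1$cope)))
  for (ci in seq_along(f1$contrasts)) {
    if (anyNA(stacks[[ci]]$copes)) next
    g <- group_stat_core(stacks[[ci]]$copes, stacks[[ci]]$varcopes)
    out$cope[ci, , ] <- matrix(g$cope, nt, K)
    out$se[ci, , ] <- matrix(g$se, nt, K)
    out$stat[ci, , ] <- matrix(g$stat, nt, K)
  }
  structure(c(out, list(contrasts = f1$contrasts, time_ms = f1$time_ms)),
            class = "group_glm")
}

#' Sign-flip max-statistic permutation inference
#'
#' Tests, per contrast, the null hypothesis that the distribution of
#' first-level COPEs has zero mean: for each permutation every subject's
#' COPEs are multiplied by an independent random sign and the group
#' statistic recomputed; the maximum absolute statistic over all
#' timepoints and states forms the null distribution (family-wise
#' correction over the whole search space, per contrast). The identity
#' flip is included as the first permutation, guaranteeing valid p-values
#' of at least 1/n_perm. Significance: observed |statistic| above the
#' (1 - alpha) quantile of the null. Inference is two-sided via absolute
#' values (the differential contrasts are signed); set `sided = "one"`
#' for raw exceedance.
#'
#' @param first_levels list of [first_level_glm()] results (>= 2
#'   subjects).
#' @param n_perm number of permutations including the identity (>= 20).
#' @param alpha family-wise error level.
#' @param seed integer seed.
#' @param sided `"two"` (default) or `"one"`.
#' @return A list of class `maxstat_result`, one element per contrast:
#'   `stat` (observed, timepoint x state), `mask` (significant cells),
#'   `null` (length n_perm), `threshold`.
#' @export
sign_flip_maxstat <- function(first_levels, n_perm = 1000L, alpha = 0.05,
                              seed = 1L, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (n_perm < 20L) stopf("n_perm = %d too small for a stable quantile",
                          n_perm)
  if (length(first_levels) < 2L) stopf("need >= 2 subjects")
  f1 <- first_levels[[1]]
  nt <- length(f1$time_ms); K <- dim(f1$cope)[3]
  n_sub <- length(first_levels)
  stacks <- stack_first_level(first_levels)

  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                  n_perm, n_sub)
  flips[1L, ] <- 1  # identity permutation in the null

  out <- vector("list", length(f1$contrasts))
  names(out) <- f1$contrasts
  for (ci in seq_along(f1$contrasts)) {
    y <- stacks[[ci]]$copes; v <- stacks[[ci]]$varcopes
    if (anyNA(y)) next
    null <- numeric(n_perm)
    obs_stat <- NULL
    for (p in seq_len(n_perm)) {
      g <- group_stat_core(y * flips[p, ], v)
      st <- if (sided == "two") abs(g$stat) else g$stat
      null[p] <- max(st)
      if (p == 1L) obs_stat <- g$stat
    }
    threshold <- quantile(null, 1 - alpha, names = FALSE)
    obs <- matrix(obs_stat, nt, K)
    comp <- if (sided == "two") abs(obs) else obs
    out[[ci]] <- list(stat = obs, mask = comp > threshold, null = null,
                      threshold = threshold)
  }
  structure(out, class = "maxstat_result", time_ms = f1$time_ms)
}

#' Write evoked GLM results as a tidy TSV
#'
#' One row per (contrast, state, time_ms) with the group COPE, statistic
#' and significance flag.
#'
#' @param group a [group_glm()] result.
#' @param maxstat a [sign_flip_maxstat()] result.
#' @param path output file.
#' @return Invisibly, the data frame written.
#' @export
write_evoked_results <- function(group, maxstat, path) {
  rows <- list()
  for (ci in seq_along(group$contrasts)) {
    ms <- maxstat[[group$contrasts[ci]]]
    if (is.null(ms)) next
    K <- dim(group$cope)[3]
    for (k in seq_len(K)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = group$contrasts[ci], state = k,
        time_ms = group$time_ms, cope = group$cope[ci, , k],
        stat = group$stat[ci, , k], significant = ms$mask[, k])
    }
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
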