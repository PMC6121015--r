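#' Generative specification for a Gaussian hidden Markov chain
#'
#' Describes a K-state hidden Markov chain over N channels with
#' multivariate-normal emissions. This is the ground truth from which the
#' synthetic-data generators draw; every downstream stage of the pipeline
#' (preprocessing, inference, temporal statistics, task GLMs, spectra) can
#' therefore be exercised against known parameters.
#'
#' @param K number of hidden states.
#' @param N number of channels.
#' @param means list of K length-N emission mean vectors.
#' @param covariances list of K N-by-N positive-definite emission
#'   covariance matrices.
#' @param transition_matrix K-by-K row-stochastic matrix.
#' @param initial_probs length-K probability vector (defaults to uniform).
#' @param oscillations optional list of K entries, each `NULL` or a list
#'   with elements `channels` (integer vector), `freq` (Hz) and
#'   `amplitude`, describing a sinusoidal burst carried while that state
#'   is active.
#' @param seed integer seed; all randomness in the generators flows from
#'   one generator initialised with it.
#'
#' @return An object of class `generative_spec`.
#' @export
generative_spec <- function(K, N, means, covariances, transition_matrix,
                            initial_probs = rep(1 / K, K),
                            oscillations = NULL, seed = 1L) {
  K <- as.integer(K); N <- as.integer(N)
  if (K < 1L || N < 1L) stopf("K and N must be >= 1")
  if (length(means) != K || length(covariances) != K)
    stopf("means and covariances must have one entry per state")
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(K, K)))
    stopf("transition_matrix must be %d x %d", K, K)
  rs <- rowSums(transition_matrix)
  if (any(transition_matrix < 0) || any(abs(rs - 1) > 1e-12))
    stopf("transition_matrix rows must be non-negative and sum to 1 (max dev %.3g)",
          max(abs(rs - 1)))
  if (length(initial_probs) != K || any(initial_probs < 0) ||
      abs(sum(initial_probs) - 1) > 1e-12)
    stopf("initial_probs must be a length-%d simplex vector", K)
  for (k in seq_len(K)) {
    if (length(means[[k]]) != N)
      stopf("state %d mean has length %d, expected %d", k,
            length(means[[k]]), N)
    if (!all(dim(as.matrix(covariances[[k]])) == c(N, N)) ||
        !is_spd(as.matrix(covariances[[k]])))
      stopf("state %d covariance is not symmetric positive-definite", k)
  }
  if (!is.null(oscillations)) {
    if (length(oscillations) != K)
      stopf("oscillations must have one entry per state")
    for (k in seq_len(K)) {
      o <- oscillations[[k]]
      if (is.null(o)) next
      if (!all(c("channels", "freq", "amplitude") %in% names(o)))
        stopf("oscillation entry for state %d needs channels/freq/amplitude", k)
      if (any(o$channels < 1) || any(o$channels > N))
        stopf("oscillation channels for state %d out of range", k)
    }
  }
  structure(list(K = K, N = N, means = lapply(means, as.numeric),
                 covariances = lapply(covariances, as.matrix),
                 transition_matrix = transition_matrix,
                 initial_probs = as.numeric(initial_probs),
                 oscillations = oscillations, seed = as.integer(seed)),
            class = "generative_spec")
}

#' The two-node, three-state illustration chain
#'
#' Convenience constructor for the bivariate example used throughout the
#' package: three states with identity emission covariance and means
#' (0, 1), (-1, -1) and (1, 0), and a sticky transition matrix.
#'
#' @param stickiness diagonal transition probability (off-diagonal mass
#'   split evenly).
#' @param seed integer seed.
#' @return A [generative_spec()].
#' @export
figure_chain_spec <- function(stickiness = 0.98, seed = 1L) {
  K <- 3L
  A <- matrix((1 - stickiness) / (K - 1), K, K)
  diag(A) <- stickiness
  generative_spec(
    K = K, N = 2L,
    means = list(c(0, 1), c(-1, -1), c(1, 0)),
    covariances = replicate(K, diag(2), simplify = FALSE),
    transition_matrix = A, seed = seed)
}

# Draw a state path of length n from the chain in `spec`.
#' @noRd
draw_state_path <- function(spec, n_samples) {
  path <- integer(n_samples)
  path[1] <- sample.int(spec$K, 1L, prob = spec$initial_probs)
  if (n_samples > 1L) {
    u <- runif(n_samples - 1L)
    cumA <- t(apply(spec$transition_matrix, 1L, cumsum))
    for (t in 2:n_samples) {
      path[t] <- findInterval(u[t - 1L], cumA[path[t - 1L], ]) + 1L
    }
  }
  path
}

#' Simulate data from a Gaussian-emission hidden Markov chain
#'
#' At each sample the emission is drawn from the multivariate normal of the
#' currently active state; the state sequence follows the Markov chain in
#' `spec`. A fixed seed gives bit-identical output.
#'
#' @param spec a [generative_spec()].
#' @param n_samples number of samples to draw (>= 1).
#' @return A list with `data` (n_samples x N matrix) and `true_path`
#'   (integer state labels).
#' @export
simulate_gaussian_hmm <- function(spec, n_samples) {
  stopifnot(inherits(spec, "generative_spec"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stopf("n_samples must be >= 1")
  set.seed(spec$seed)
  path <- draw_state_path(spec, n_samples)
  z <- matrix(rnorm(n_samples * spec$N), n_samples, spec$N)
  data <- matrix(0, n_samples, spec$N)
  for (k in seq_len(spec$K)) {
    idx <- which(path == k)
    if (length(idx))
      data[idx, ] <- mvn_transform(z[idx, , drop = FALSE],
                                   spec$means[[k]], spec$covariances[[k]])
  }
  list(data = data, true_path = path)
}

#' Simulate multichannel state-dependent oscillatory bursts
#'
#' While a state is active, the channels listed in its oscillation entry
#' carry a sinusoid of the stated frequency and amplitude on top of unit
#' white noise; all other channels carry noise only. The phase is
#' re-randomised on each state entry, so successive visits are independent
#' bursts. This is the fixture for the time-delay-embedded model, whose
#' states differ in spectral content rather than mean.
#'
#' @param spec a [generative_spec()] whose `oscillations` field has an
#'   entry for every state.
#' @param n_samples number of samples.
#' @param fs sampling rate in Hz; must exceed twice the highest oscillation
#'   frequency.
#' @return A list with `data`, `true_path` and `fs`.
#' @export
simulate_oscillatory_states <- function(spec, n_samples, fs) {
  stopifnot(inherits(spec, "generative_spec"))
  if (is.null(spec$oscillations))
    stopf("spec has no oscillation entries")
  fmax <- max(vapply(spec$oscillations,
                     function(o) if (is.null(o)) 0 else o$freq, 0))
  if (fmax >= fs / 2)
    stopf("oscillation frequency %.3g Hz is at or above Nyquist (fs = %.3g)",
          fmax, fs)
  n_samples <- as.integer(n_samples)
  set.seed(spec$seed)
  path <- draw_state_path(spec, n_samples)
  data <- matrix(rnorm(n_samples * spec$N), n_samples, spec$N)
  runs <- rle_runs(path)
  for (i in seq_len(nrow(runs))) {
    o <- spec$oscillations[[runs$value[i]]]
    if (is.null(o) || o$amplitude == 0) next
    tt <- seq(runs$start[i], runs$end[i])
    phase <- runif(1, 0, 2 * pi)
    wave <- o$amplitude * sin(2 * pi * o$freq * (tt - 1) / fs + phase)
    data[tt, o$channels] <- data[tt, o$channels] + wave
  }
  list(data = data, true_path = path, fs = fs)
}

#' Task-session specification
#'
#' Describes the trigger structure of a simulated task session: the nine
#' condition labels (three face types crossed with three repeat levels, as
#' in a face-perception paradigm), trials per condition, the inter-trial
#' interval range, and per-condition occupancy-boost profiles. A boost
#' profile is a time-course of transition bias toward one state applied
#' after each event of that condition, producing a known event-locked
#' occupancy increase.
#'
#' @param n_trials_per_condition trials per condition label.
#' @param conditions character vector of condition labels; defaults to the
#'   nine face-type x repeat labels.
#' @param iti_range two integers: min/max inter-trial interval in samples.
#' @param boosts named list mapping condition labels to a list with
#'   `state` (boosted state index) and `profile` (numeric vector in `[0, 1]`,
#'   one bias value per post-event sample). Conditions not named get no
#'   boost.
#' @param fs sampling rate in Hz.
#' @return An object of class `task_session_spec`.
#' @export
task_session_spec <- function(n_trials_per_condition = 10L,
                              conditions = default_conditions(),
                              iti_range = c(250L, 400L),
                              boosts = list(), fs = 250) {
  if (length(conditions) != length(unique(conditions)))
    stopf("condition labels must be unique")
  for (nm in names(boosts)) {
    if (!nm %in% conditions) stopf("boost for unknown condition '%s'", nm)
    if (!all(is.finite(boosts[[nm]]$profile)))
      stopf("boost profile for '%s' must be finite", nm)
  }
  structure(list(n_trials_per_condition = as.integer(n_trials_per_condition),
                 conditions = conditions,
                 iti_range = as.integer(iti_range),
                 boosts = boosts, fs = fs),
            class = "task_session_spec")
}

#' Default nine-condition label set
#'
#' Three face types (Famous, Unfamiliar, Scrambled) crossed with three
#' repeat levels (First, Immediate, Last).
#' @return Character vector of nine labels.
#' @export
default_conditions <- function() {
  as.vector(outer(c("Famous", "Unfamiliar", "Scrambled"),
                  c("First", "Immediate", "Last"), paste, sep = "_"))
}

#' Simulate a task session with event-locked occupancy modulation
#'
#' Generates Gaussian-emission chain data in which, for a window after each
#' event, the transition probabilities are biased toward the condition's
#' boosted state: at post-event offset u with bias b(u), the transition row
#' becomes `(1 - b) * A[s, ] + b * e_k`. Between events the data remain purely
#' Markov-generated. Events are laid out with inter-trial intervals drawn
#' uniformly from the specified range and conditions in randomised order.
#'
#' @param gen a [generative_spec()].
#' @param task a [task_session_spec()].
#' @param n_samples session length in samples; all events (with their
#'   boost windows) must fit.
#' @return A list with `data`, `true_path`, `events` (data frame with
#'   0-based `onset_sample` and `condition`) and `fs`.
#' @export
simulate_task_session <- function(gen, task, n_samples) {
  stopifnot(inherits(gen, "generative_spec"),
            inherits(task, "task_session_spec"))
  n_samples <- as.integer(n_samples)
  set.seed(gen$seed)

  labels <- sample(rep(task$conditions, task$n_trials_per_condition))
  n_ev <- length(labels)
  iti <- sample(seq(task$iti_range[1], task$iti_range[2]), n_ev,
                replace = TRUE)
  onsets1 <- cumsum(iti)  # 1-based onset samples
  max_boost <- max(c(0L, vapply(task$boosts,
                                function(b) length(b$profile), 0L)))
  if (max(onsets1) + max_boost > n_samples)
    stopf("events (with boost windows) extend beyond n_samples = %d; need >= %d",
          n_samples, max(onsets1) + max_boost)

  # per-sample bias: which state is boosted and by how much
  bias_state <- integer(n_samples)
  bias_val <- numeric(n_samples)
  overlap <- FALSE
  for (i in seq_len(n_ev)) {
    b <- task$boosts[[labels[i]]]
    if (is.null(b)) next
    idx <- onsets1[i] + seq_along(b$profile) - 1L
    if (any(bias_val[idx] > 0)) overlap <- TRUE
    bias_state[idx] <- b$state
    bias_val[idx] <- b$profile
  }
  if (overlap) message("overlapping boost windows; later events take precedence")

  path <- integer(n_samples)
  path[1] <- sample.int(gen$K, 1L, prob = gen$initial_probs)
  u <- runif(n_samples)
  for (t in seq_len(n_samples)[-1]) {
    p <- gen$transition_matrix[path[t - 1L], ]
    if (bias_val[t] > 0) {
      p <- (1 - bias_val[t]) * p
      p[bias_state[t]] <- p[bias_state[t]] + bias_val[t]
    }
    path[t] <- findInterval(u[t], cumsum(p)) + 1L
  }

  z <- matrix(rnorm(n_samples * gen$N), n_samples, gen$N)
  data <- matrix(0, n_samples, gen$N)
  for (k in seq_len(gen$K)) {
    idx <- which(path == k)
    if (length(idx))
      data[idx, ] <- mvn_transform(z[idx, , drop = FALSE],
                                   gen$means[[k]], gen$covariances[[k]])
  }
  events <- data.frame(onset_sample = onsets1 - 1L,  # 0-based
                       condition = labels, stringsAsFactors = FALSE)
  list(data = data, true_path = path, events = events, fs = task$fs)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `data` as a TSV matrix, `true_path` as a one-column TSV, events
#' as a BIDS-style events TSV (`onset_sample`, `condition`), and a JSON
#' sidecar holding `fs` and `seed`.
#'
#' @param sim output of one of the `simulate_*` generators.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(data = file.path(dir, paste0(prefix, "_data.tsv")),
             path = file.path(dir, paste0(prefix, "_true_path.tsv")),
             meta = file.path(dir, paste0(prefix, "_meta.json")))
  write.table(sim$data, paths["data"], sep = "\t", row.names = FALSE,
              col.names = FALSE)
  write.table(data.frame(state = sim$true_path), paths["path"], sep = "\t",
              row.names = FALSE)
  if (!is.null(sim$events)) {
    paths["events"] <- file.path(dir, paste0(prefix, "_events.tsv"))
    write.table(sim$events, paths["events"], sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  jsonlite::write_json(list(fs = sim$fs %||% NA, n_samples = nrow(sim$data),
                            n_channels = ncol(sim$data)),
                       paths["meta"], auto_unbox = TRUE)
  invisible(paths)
}
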