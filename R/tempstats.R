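#' Fractional occupancy per session and state
#'
#' The proportion of time spent in each state, computed as the mean of the
#' posterior probabilities (`gamma`) within each session. Posteriors are
#' used rather than the hard path because they retain information when two
#' or more states are nearly equally probable; the two agree exactly when
#' `gamma` is 0/1.
#'
#' @param stc a [state_tc()].
#' @param sessions per-sample session labels; defaults to the
#'   `sample_index` sessions carried by `stc`, or a single session.
#' @return sessions x K matrix of occupancies; rows sum to 1.
#' @export
fractional_occupancy <- function(stc, sessions = NULL) {
  stopifnot(inherits(stc, "state_tc"))
  if (is.null(sessions)) {
    sessions <- if (!is.null(stc$sample_index)) stc$sample_index$session
                else rep(1L, nrow(stc$gamma))
  }
  if (length(sessions) != nrow(stc$gamma))
    stopf("session labels must cover all %d samples", nrow(stc$gamma))
  ids <- unique(sessions)
  fo <- t(vapply(ids, function(s) {
    rows <- sessions == s
    if (!any(rows)) stopf("empty session %s", s)
    colMeans(stc$gamma[rows, , drop = FALSE])
  }, numeric(ncol(stc$gamma))))
  rownames(fo) <- as.character(ids)
  fo
}

# Runs of the hard path within each segment, annotated with segment and
# edge-contact flags.
#' @noRd
segment_runs <- function(stc) {
  offs <- cumsum(c(0L, stc$T))
  out <- list()
  for (s in seq_along(stc$T)) {
    sl <- (offs[s] + 1L):offs[s + 1L]
    r <- rle_runs(stc$vpath[sl])
    r$segment <- s
    r$edge <- r$start == 1L | r$end == length(sl)
    out[[s]] <- r
  }
  do.call(rbind, out)
}

#' State lifetimes (dwell times)
#'
#' Durations of uninterrupted visits to each state, from run-length
#' encoding of the Viterbi path. Runs never cross segment boundaries.
#' Runs truncated by a segment edge are included (dropping them biases the
#' lifetime distribution downward for persistent states) but marked in the
#' `edge` attribute; set `drop_edge = TRUE` to exclude them.
#'
#' @param stc a [state_tc()] with known `fs`.
#' @param drop_edge exclude runs touching a segment edge.
#' @return List (one element per state) of visit durations in
#'   milliseconds, each with an `edge` logical attribute.
#' @export
state_lifetimes <- function(stc, drop_edge = FALSE) {
  stopifnot(inherits(stc, "state_tc"))
  if (is.na(stc$fs)) stopf("sampling rate unknown")
  K <- ncol(stc$gamma)
  runs <- segment_runs(stc)
  if (drop_edge) runs <- runs[!runs$edge, , drop = FALSE]
  lapply(seq_len(K), function(k) {
    r <- runs[runs$value == k, , drop = FALSE]
    structure(r$length / stc$fs * 1000, edge = r$edge)
  })
}

#' State interval times
#'
#' Gaps between consecutive visits to the same state, within a segment.
#'
#' @param stc a [state_tc()] with known `fs`.
#' @return List (one element per state) of interval durations in
#'   milliseconds.
#' @export
state_intervals <- function(stc) {
  stopifnot(inherits(stc, "state_tc"))
  if (is.na(stc$fs)) stopf("sampling rate unknown")
  K <- ncol(stc$gamma)
  runs <- segment_runs(stc)
  lapply(seq_len(K), function(k) {
    gaps <- numeric(0)
    for (s in unique(runs$segment)) {
      r <- runs[runs$segment == s & runs$value == k, , drop = FALSE]
      if (nrow(r) > 1L)
        gaps <- c(gaps, r$start[-1L] - r$end[-nrow(r)] - 1L)
    }
    gaps / stc$fs * 1000
  })
}

#' Summarise the temporal statistics of a fitted state time-course
#'
#' @param stc a [state_tc()].
#' @param sessions optional per-sample session labels.
#' @return A list of class `temporal_stats` with `fractional_occupancy`
#'   (sessions x K), `lifetimes`, `intervals`, `mean_lifetime`, and `fs`.
#' @export
temporal_stats <- function(stc, sessions = NULL) {
  lt <- state_lifetimes(stc)
  structure(list(
    fractional_occupancy = fractional_occupancy(stc, sessions),
    lifetimes = lt,
    intervals = state_intervals(stc),
    mean_lifetime = vapply(lt, function(x)
      if (length(x)) mean(x) else NA_real_, 0),
    fs = stc$fs), class = "temporal_stats")
}

#' Diagnostic checks for artifact-driven states
#'
#' States describing artifacts or session-specific noise tend to show
#' unusual temporal statistics. Two checks are applied: (a) states whose
#' overall fractional occupancy or mean lifetime is an outlier relative to
#' the other states (two-sided GESD); and (b) session-dominated states,
#' where a state's occupancy in one session exceeds a multiple of its
#' median across sessions — the signature of a single session or
#' participant being described by a single state. Neither threshold is
#' canonical; both are surfaced as arguments.
#'
#' @param stats a [temporal_stats()] computed over at least 2 sessions.
#' @param alpha GESD significance level for the across-state outlier check.
#' @param dominance_multiple session-dominance threshold on
#'   occupancy / median occupancy.
#' @return A list with `state_outliers` (data frame: state, metric,
#'   value), `session_dominance` (data frame: state, session, occupancy,
#'   median_occupancy) and `clean` (TRUE when nothing was flagged).
#' @export
validate_states <- function(stats, alpha = 0.05, dominance_multiple = 5) {
  stopifnot(inherits(stats, "temporal_stats"))
  fo <- stats$fractional_occupancy
  if (nrow(fo) < 2L) stopf("validation needs >= 2 sessions")
  K <- ncol(fo)

  outliers <- data.frame(state = integer(0), metric = character(0),
                         value = numeric(0))
  if (K >= 3L) {
    overall <- colMeans(fo)
    for (metric in c("fractional_occupancy", "mean_lifetime")) {
      vals <- if (metric == "fractional_occupancy") overall
              else stats$mean_lifetime
      if (any(!is.finite(vals))) next
      bad <- gesd(vals, alpha = alpha, max_out = max(1L, floor(0.2 * K)))
      if (length(bad))
        outliers <- rbind(outliers,
                          data.frame(state = bad, metric = metric,
                                     value = vals[bad]))
    }
  }

  med <- apply(fo, 2, median)
  dom <- which(fo > dominance_multiple * rep(med, each = nrow(fo)) &
                 fo > 1 / K, arr.ind = TRUE)
  session_dominance <- data.frame(
    state = as.integer(dom[, 2]),
    session = rownames(fo)[dom[, 1]] %||% as.character(dom[, 1]),
    occupancy = fo[dom], median_occupancy = med[dom[, 2]])

  list(state_outliers = outliers, session_dominance = session_dominance,
       clean = nrow(outliers) == 0L && nrow(session_dominance) == 0L)
}

#' Write temporal statistics as a tidy TSV
#'
#' One row per (session, state, metric, value); list metrics (lifetimes,
#' intervals) are summarised by their mean.
#'
#' @param stats a [temporal_stats()].
#' @param path output file.
#' @return Invisibly, the tidy data frame written.
#' @export
write_temporal_stats <- function(stats, path) {
  fo <- stats$fractional_occupancy
  rows <- list()
  for (s in seq_len(nrow(fo))) for (k in seq_len(ncol(fo))) {
    rows[[length(rows) + 1L]] <- data.frame(
      session = rownames(fo)[s], state = k, metric = "fractional_occupancy",
      value = fo[s, k])
  }
  for (k in seq_along(stats$lifetimes)) {
    rows[[length(rows) + 1L]] <- data.frame(
      session = "all", state = k, metric = "mean_lifetime_ms",
      value = stats$mean_lifetime[k])
    iv <- stats$intervals[[k]]
    rows[[length(rows) + 1L]] <- data.frame(
      session = "all", state = k, metric = "mean_interval_ms",
      value = if (length(iv)) mean(iv) else NA_real_)
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
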