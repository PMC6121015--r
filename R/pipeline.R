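#' Read, validate and write pipeline configuration
#'
#' The pipeline is driven by a nested configuration (YAML on disk or a
#' named list) with sections `output_dir`, `seed`, `simulate` or `input`,
#' `prep`, `hmm`, `evoked`, `spectra`. Every parameter is validated
#' against its module's preconditions before any computation starts, and
#' configurations round-trip losslessly through YAML.
#'
#' @param x path to a YAML file, or a named list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    seed = 1L,
    prep = list(representation = "envelope", band = c(2, 40),
                smooth_ms = 100, lags = c(-7, 7),
                gesd = list(window_s = 1, alpha = 0.05, max_prop = 0.2)),
    hmm = list(K = 6L, obs_kind = NULL, n_runs = 5L, max_iter = 100L,
               tol = 1e-6, batch_size = "full"),
    evoked = list(window_ms = c(-200, 600), baseline_ms = c(-130, -30),
                  n_perm = 1000L, alpha = 0.05),
    spectra = list(band = c(1, 40), window_s = 2,
                   n_replicates = 500L, n_repeats = 20L))
  for (sec in names(defaults)) {
    if (is.list(defaults[[sec]])) {
      cfg[[sec]] <- utils::modifyList(defaults[[sec]], cfg[[sec]] %||% list())
    } else if (is.null(cfg[[sec]])) cfg[[sec]] <- defaults[[sec]]
  }
  # validation before any computation
  if (is.null(cfg$output_dir)) stopf("config needs output_dir")
  if (!cfg$prep$representation %in% c("envelope", "embedded"))
    stopf("prep$representation must be envelope or embedded")
  if (cfg$hmm$K < 1L) stopf("hmm$K must be >= 1")
  if (cfg$hmm$tol <= 0) stopf("hmm$tol must be > 0")
  if (cfg$evoked$n_perm < 20L) stopf("evoked$n_perm must be >= 20")
  if (cfg$prep$gesd$max_prop <= 0 || cfg$prep$gesd$max_prop >= 1)
    stopf("gesd$max_prop must be in (0, 1)")
  if (is.null(cfg$hmm$obs_kind))
    cfg$hmm$obs_kind <- if (cfg$prep$representation == "envelope")
      "mean_and_cov" else "zero_mean_cov"
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path output YAML path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Simulate a demo dataset from a named preset
#'
#' Presets: `"figure1"` (the two-node, three-state Gaussian chain),
#' `"bursts"` (two oscillatory-burst states at 10 and 25 Hz over four
#' channels), and `"task"` (nine-condition sessions with an event-locked
#' occupancy boost). Writes data, ground-truth path and events (task
#' preset) as TSV.
#'
#' @param preset preset name.
#' @param dir output directory.
#' @param n_samples samples per session.
#' @param n_sessions number of sessions.
#' @param seed integer seed.
#' @return Invisibly, the list of simulated sessions.
#' @export
simulate_cmd <- function(preset = c("figure1", "bursts", "task"), dir,
                         n_samples = 10000L, n_sessions = 1L, seed = 1L) {
  preset <- match.arg(preset)
  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    sseed <- stage_seed(seed, paste0("sim", s))
    sim <- switch(preset,
      figure1 = simulate_gaussian_hmm(figure_chain_spec(seed = sseed),
                                      n_samples),
      bursts = simulate_oscillatory_states(
        burst_chain_spec(seed = sseed), n_samples, fs = 250),
      task = {
        gen <- burst_chain_spec(seed = sseed)
        # as many trials per condition as fit at the maximum inter-trial
        # interval, capped at 6
        ntc <- max(1L, min(6L, (n_samples - 100L) %/% (400L * 9L)))
        task <- task_session_spec(
          n_trials_per_condition = ntc,
          boosts = stats::setNames(rep(list(list(
            state = 2L, profile = rep(0.35, 50))), 3),
            paste0("Famous_", c("First", "Immediate", "Last"))))
        simulate_task_session(gen, task, n_samples)
      })
    sim$fs <- sim$fs %||% 250
    write_simulation(sim, dir, prefix = sprintf("%s_session%02d", preset, s))
    sessions[[s]] <- sim
  }
  invisible(sessions)
}

#' Two-state oscillatory-burst chain over four channels
#'
#' State 1 carries a 10 Hz sinusoid on channels 1-2, state 2 a 25 Hz
#' sinusoid on channels 3-4, each on top of unit white noise, with sticky
#' transitions. The standard fixture for the spectrally resolved model.
#'
#' @param stickiness diagonal transition probability.
#' @param amplitude burst amplitude.
#' @param seed integer seed.
#' @return A [generative_spec()].
#' @export
burst_chain_spec <- function(stickiness = 0.99, amplitude = 2, seed = 1L) {
  A <- matrix(1 - stickiness, 2, 2); diag(A) <- stickiness
  generative_spec(
    K = 2L, N = 4L,
    means = replicate(2, rep(0, 4), simplify = FALSE),
    covariances = replicate(2, diag(4), simplify = FALSE),
    transition_matrix = A,
    oscillations = list(
      list(channels = 1:2, freq = 10, amplitude = amplitude),
      list(channels = 3:4, freq = 25, amplitude = amplitude)),
    seed = seed)
}

# Raw data rows aligned with a state time-course via its sample_index.
#' @noRd
aligned_raw <- function(sessions, stc) {
  si <- stc$sample_index
  out <- matrix(0, nrow(si), ncol(sessions[[1]]$data))
  ids <- vapply(sessions, function(s) s$session_id, sessions[[1]]$session_id)
  for (i in seq_along(sessions)) {
    rows <- which(si$session == ids[i])
    out[rows, ] <- sessions[[i]]$data[si$sample[rows] + 1L, ]
  }
  out
}

#' Run the full pipeline from a configuration
#'
#' Executes: simulate or load -> bad-segment detection -> representation
#' (envelope, or embedding + PCA) -> HMM fit (multi-run, lowest free
#' energy kept) -> temporal statistics and validation -> task-evoked GLM
#' with sign-flip permutations (when events exist) -> state spectra and
#' reconstructed time-frequency response. Every artifact is written as
#' TSV/JSON under `output_dir` together with a manifest recording the
#' configuration snapshot, seeds, free energies and validation flags. A
#' stage failure aborts with the stage name; earlier outputs are kept.
#'
#' @param config a [pipeline_config()], list, or YAML path.
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), started = format(Sys.time()))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  sessions <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sims <- simulate_cmd(cfg$simulate$preset %||% "task", cfg$output_dir,
                           n_samples = cfg$simulate$n_samples %||% 10000L,
                           n_sessions = cfg$simulate$n_sessions %||% 2L,
                           seed = stage_seed(cfg$seed, "simulate"))
      lapply(seq_along(sims), function(i)
        parcel_ts(sims[[i]]$data, fs = sims[[i]]$fs %||% 250,
                  session_id = i, events = sims[[i]]$events))
    } else {
      lapply(seq_along(cfg$input$data), function(i) {
        dat <- as.matrix(read.delim(cfg$input$data[[i]], header = FALSE))
        ev <- if (!is.null(cfg$input$events))
          read.delim(cfg$input$events[[i]]) else NULL
        parcel_ts(dat, fs = cfg$input$fs, session_id = i, events = ev)
      })
    }
  })

  dataset <- stage("prep", {
    sessions <- lapply(sessions, function(ts) {
      ts$bad_mask <- detect_bad_segments(
        ts, window_s = cfg$prep$gesd$window_s, alpha = cfg$prep$gesd$alpha,
        max_prop = cfg$prep$gesd$max_prop)
      ts
    })
    if (cfg$prep$representation == "envelope") {
      prepare_envelope(sessions, band = cfg$prep$band,
                       smooth_ms = cfg$prep$smooth_ms)
    } else {
      lags <- seq(cfg$prep$lags[1], cfg$prep$lags[length(cfg$prep$lags)])
      signs <- if (length(sessions) > 1L)
        align_signs(lapply(sessions, `[[`, "data"),
                    seed = stage_seed(cfg$seed, "signs")) else NULL
      prepare_tde(sessions, lags = lags, n_pca = cfg$prep$n_pca,
                  signs = signs)
    }
  })

  fitres <- stage("fit", {
    conf <- hmm_config(K = cfg$hmm$K, obs_kind = cfg$hmm$obs_kind,
                       max_iter = cfg$hmm$max_iter, tol = cfg$hmm$tol,
                       n_runs = cfg$hmm$n_runs,
                       seed = stage_seed(cfg$seed, "hmm"),
                       batch_size = cfg$hmm$batch_size)
    fit_hmm(dataset, conf)
  })
  manifest$free_energies <- fitres$fit$run_free_energies
  manifest$effective_K <- fitres$fit$effective_K
  write.table(fitres$stc$gamma, file.path(cfg$output_dir, "gamma.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(data.frame(vpath = fitres$stc$vpath),
              file.path(cfg$output_dir, "vpath.tsv"), sep = "\t",
              row.names = FALSE)
  write.table(fitres$fit$transition_matrix,
              file.path(cfg$output_dir, "transition_matrix.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)

  stats <- stage("tempstats", temporal_stats(fitres$stc))
  write_temporal_stats(stats, file.path(cfg$output_dir,
                                        "temporal_stats.tsv"))
  if (nrow(stats$fractional_occupancy) >= 2L) {
    manifest$validation <- validate_states(stats)
    manifest$validation$state_outliers <- NULL  # keep manifest scalar-ish
    manifest$validation_clean <- validate_states(stats)$clean
  }

  have_events <- any(vapply(sessions, function(s) !is.null(s$events), TRUE))
  evoked_res <- NULL
  if (have_events) {
    evoked_res <- stage("evoked", {
      firsts <- list()
      for (ts in sessions) {
        if (is.null(ts$events)) next
        ev <- ts$events; ev$session <- ts$session_id
        ep <- epoch_gamma(fitres$stc, ev, window_ms = cfg$evoked$window_ms,
                          subject = ts$session_id)
        ep <- baseline_normalise(ep, cfg$evoked$baseline_ms)
        firsts[[length(firsts) + 1L]] <- first_level_glm(ep)
      }
      grp <- group_glm(firsts)
      ms <- sign_flip_maxstat(firsts, n_perm = cfg$evoked$n_perm,
                              alpha = cfg$evoked$alpha,
                              seed = stage_seed(cfg$seed, "perm"))
      write_evoked_results(grp, ms,
                           file.path(cfg$output_dir, "evoked_glm.tsv"))
      list(first_levels = firsts, group = grp, maxstat = ms)
    })
  }

  spectra_res <- stage("spectra", {
    raw <- aligned_raw(sessions, fitres$stc)
    sp <- statewise_multitaper(raw, fitres$stc, fs = sessions[[1]]$fs,
                               band = cfg$spectra$band,
                               window_s = cfg$spectra$window_s)
    for (k in seq_len(dim(sp$psd)[1])) {
      write.table(t(sp$psd[k, , ]),
                  file.path(cfg$output_dir, sprintf("psd_state%d.tsv", k)),
                  sep = "\t", row.names = FALSE, col.names = FALSE)
    }
    sp
  })

  tf <- NULL
  if (!is.null(evoked_res)) {
    tf <- stage("reconstruct_tf", {
      occ <- apply(evoked_res$first_levels[[1]]$cope[1, , , drop = FALSE],
                   c(2, 3), identity)
      mean_psd <- apply(spectra_res$psd, c(1, 3), mean)
      rtf <- reconstruct_tf(occ, mean_psd)
      write.table(rtf, file.path(cfg$output_dir, "reconstructed_tf.tsv"),
                  sep = "\t", row.names = FALSE, col.names = FALSE)
      rtf
    })
  }

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(dataset = dataset, fit = fitres$fit, stc = fitres$stc,
                 stats = stats, evoked = evoked_res,
                 spectra = spectra_res, tf = tf))
}

#' Summarise a completed pipeline run
#'
#' Reads the TSV artifacts in a results directory and returns summary
#' tables: per-state temporal statistics, significant evoked windows per
#' contrast, and the free energies from the manifest. Missing optional
#' stages produce a notice rather than an error.
#'
#' @param results_dir directory written by [run_pipeline()].
#' @return A list of data frames.
#' @export
report_cmd <- function(results_dir) {
  if (!dir.exists(results_dir) || !length(list.files(results_dir)))
    stopf("no results found in '%s'", results_dir)
  out <- list()
  mf <- file.path(results_dir, "manifest.json")
  if (file.exists(mf)) out$manifest <- jsonlite::read_json(mf)
  tsf <- file.path(results_dir, "temporal_stats.tsv")
  if (file.exists(tsf)) out$temporal_stats <- read.delim(tsf)
  ef <- file.path(results_dir, "evoked_glm.tsv")
  if (file.exists(ef)) {
    ev <- read.delim(ef)
    sig <- ev[ev$significant, c("contrast", "state", "time_ms", "stat")]
    out$significant_windows <- sig
  } else message("no evoked stage output; partial report")
  if (!length(list.files(results_dir, pattern = "^psd_state")))
    message("no spectra stage output; partial report")
  out
}
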