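# statewave

Unsupervised segmentation of parcellated electrophysiological recordings
(MEG/EEG source time-courses) into recurring whole-brain network states
with hidden Markov models, and statistically valid group-level task
analysis of the resulting state dynamics.

## The problem

Task-relevant brain dynamics unfold on millisecond time-scales, faster
than sliding-window connectivity methods can resolve. A hidden Markov
model (HMM) instead describes the recording as a sequence of hidden
states X_t ∈ {1, …, K}, each with its own multivariate-Gaussian
observation model over N parcels; state-wise connectivity is estimated by
pooling all visits to a state, so each individual visit can last only
tens of milliseconds. Crucially the states are inferred from the
continuous data with no knowledge of task timings; task structure is then
recovered by epoching the posterior state probabilities.

Two data representations are supported:

* **AE-HMM** — states live on Hilbert amplitude envelopes
  (band-passed, smoothed, z-scored); the observation model fits a mean
  vector and covariance per state (power and power-correlation
  networks).
* **TDE-HMM** — states live on a time-delay embedding of the raw signals
  (lags −7…7, reduced to 4N principal components); the observation
  model fits a covariance only, capturing state-specific spectra and
  phase-locking.

Inference is variational Bayes with conjugate priors (Dirichlet over
transition rows and the initial distribution; normal–inverse-Wishart over
emissions), run independently within each continuous good segment, with
an optional stochastic batched mode for large datasets. The variational
free energy (an approximation to negative log model evidence) drives
convergence and selection among seeded runs. Downstream modules provide
state temporal statistics (fractional occupancy, lifetimes, intervals),
artifact-state diagnostics, task-evoked occupancy inference via a
two-level GLM with sign-flip max-statistic permutations, state-weighted
multitaper spectra and coherence, NNMF spectral modes, GMM connection
thresholding, and HMM-reconstructed time-frequency responses.

A synthetic-data module generates ground-truthed fixtures for every stage
(Gaussian mean-shift chains, state-dependent oscillatory bursts, and
nine-condition task sessions with event-locked occupancy boosts), so the
whole pipeline is testable without any external recordings.

## Worked example

```r
library(statewave)

# simulate the two-node, three-state illustration chain
spec <- figure_chain_spec(stickiness = 0.98, seed = 7)
sim <- simulate_gaussian_hmm(spec, 10000)

# wrap as a single-segment dataset and fit a 3-state HMM, best of 5 runs
ds <- segmented_dataset(sim$data, 10000L, 1L,
                        data.frame(session = 1L, sample = 0:9999),
                        meta = list(fs = 250))
res <- fit_hmm(ds, hmm_config(K = 3, n_runs = 5, seed = 11))

means <- t(sapply(res$fit$states, `[[`, "mean"))
perm <- match_states(means, do.call(rbind, spec$means))
round(means[perm, ], 3)
#>        [,1]   [,2]
#> [1,]  0.002  1.009
#> [2,] -0.973 -1.028
#> [3,]  0.995  0.001

mean(res$stc$vpath == perm[sim$true_path])   # hard-path accuracy
#> [1] 0.9815

st <- temporal_stats(res$stc)
round(st$fractional_occupancy, 3)
#>    [,1]  [,2]  [,3]
#> 1 0.366 0.289 0.345
round(st$mean_lifetime, 1)                   # ms at 250 Hz
#> [1] 236.0 193.3 205.6
```

The matched state means recover the generating values (0, 1), (−1, −1)
and (1, 0) to within a few hundredths, the decoded path matches the
ground truth at 98%, and the temporal statistics reflect the sticky
transition structure (mean dwell times of ~200 ms at a 0.98 diagonal).

A YAML-driven end-to-end run (simulate → preprocess → fit → statistics →
evoked GLM → spectra) is available through `run_pipeline()` or the thin
CLI at `inst/cli/statewave.R`:

```sh
Rscript inst/cli/statewave.R simulate --preset task --out demo_sim
Rscript inst/cli/statewave.R run --config demo.yaml
Rscript inst/cli/statewave.R report --results demo_out
```

## Reproducibility notes

All random draws flow through R's default Mersenne-Twister generator via
`set.seed()`; every generator and fit takes an explicit integer seed, and
pipeline stages derive their seeds deterministically from the single
configured seed. Matrices are serialised as TSV with JSON/YAML sidecars,
so every artifact is diffable.
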