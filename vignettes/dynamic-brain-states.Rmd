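---
title: "Modelling dynamic brain-network states with variational HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dynamic brain-network states with variational HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statewave)
```

## The model

statewave describes a parcellated electrophysiological recording
$Y \in \mathbb{R}^{S \times D}$ as generated by a hidden Markov chain:
at each sample a hidden state $X_t \in \{1, \dots, K\}$ is active, states
evolve with a row-stochastic transition matrix $A$ (and initial
distribution $\pi$), and the observation while state $k$ is active is
drawn from a multivariate normal $\mathcal{N}(\mu_k, \Sigma_k)$. States
are mutually exclusive at the hard-assignment level, but the Bayesian
inference returns soft posterior probabilities (`gamma`), which need not
be; the hard Viterbi path (`vpath`) is computed separately.

Two observation-model variants correspond to two data representations:

* `mean_and_cov` on amplitude envelopes: states differ in mean envelope
  (power) and envelope covariance (amplitude-correlation networks).
* `zero_mean_cov` on time-delay-embedded signals: band-passed,
  normalised oscillatory signals are zero-mean by construction, so the
  mean is fixed at zero and each state is a covariance over the
  lag-expanded space — equivalently a state-specific multi-channel
  spectrum and set of cross-spectra.

## Inference

Inference is variational Bayes with a structured mean-field posterior
$q(Z)\,q(\theta)$ and conjugate priors:

* transition rows and initial distribution: Dirichlet with concentration
  1 plus a diagonal boost of 10 ("stickiness"), encoding the prior
  expectation that brain states persist for many samples;
* emissions: normal–inverse-Wishart (inverse-Wishart only for the
  zero-mean model) with scale matrix equal to the empirical data
  covariance and $\nu_0 = D + 2$ degrees of freedom, so the prior
  expected covariance equals the empirical covariance; the prior mean is
  the data mean with precision scaling $\kappa_0 = 0.1$ (weak).

The E-step runs a scaled forward–backward recursion *independently
within each continuous good segment* (the segment lengths `T` are part
of the dataset container), so the model never explains a transition
across a discontinuity — a bad-segment excision or a session boundary.
Expected-log parameters ($\exp \mathbb{E}[\log A]$ etc.) are used in the
recursion, as required for a valid bound. The M-step applies the
standard conjugate updates. The free energy (negative evidence lower
bound) is computed after every E-step as
$F = -\sum_{\text{seg}} \log \tilde{Z} + \mathrm{KL}(q(\theta)\,\|\,p(\theta))$
and is non-increasing across full-batch iterations; the package tests
assert this property, and for $K = 1$ the free energy is verified to
equal the closed-form normal–inverse-Wishart log evidence exactly.

For datasets with many segments, a stochastic mode processes a random
batch of segments per iteration and blends the implied full-data
posterior into the current one with step size
$\rho_i = (i + 1)^{-0.6}$ — the free-energy trace is then a noisy
estimate and only the full-batch trace is guaranteed monotone.

Initialisation uses a short k-means on the observations (on smoothed
squared amplitudes for the zero-mean model), perturbed per run seed.
Because the optimisation is non-convex, `fit_hmm` supports `n_runs`
independent seeded runs and keeps the lowest final free energy;
`select_best_run` exposes the same rule for externally managed runs.
Excess states are emptied by the variational optimisation itself;
`effective_K` reports how many states retain at least $K \cdot D$
samples of expected occupancy. We deliberately do not hard-zero
low-occupancy states mid-inference, which could break the monotone
free-energy guarantee.

## Preprocessing

* **Bad segments** are found by the generalized extreme Studentized
  deviate test on the standard deviation of 1 s windows (all channels
  pooled), two-sided so both high-variance artifacts and flat dropouts
  are caught, significance 0.05, at most 20% of windows flagged. A
  trailing partial window is tested on its own if at least half a window
  long, otherwise merged into the previous window, so no data goes
  untested.
* **Leakage correction** finds the mutually orthogonal time-courses
  closest (Frobenius) to the originals, by iterating an
  orthogonal-Procrustes solve with per-column scaling (tolerance 1e-10,
  at most 100 iterations); single-pass symmetric orthogonalisation is
  the test oracle and upper bound on displacement.
* **Envelopes**: zero-phase order-5 Butterworth band-pass (2–40 Hz
  default), analytic-signal magnitude, 100 ms moving average, then
  per-channel z-scoring computed over good samples only (bad samples are
  later removed, so they must not contaminate the statistics).
* **Embedding**: lags −7…7 (30 ms at 250 Hz in each direction), columns
  channel-major/lag-minor, each embedded row timestamped by its lag-0
  sample so state time-courses stay aligned to the original time axis
  for epoching. PCA to 4N components by default; fewer components bias
  the model toward low frequencies (they dominate variance), which a
  test demonstrates by comparing reconstructed band energies at 2N vs
  4N.
* **Sign alignment** across sessions maximises the summed magnitude of
  the group-mean lagged covariance (lags 0–3 by default, configurable)
  by greedy single-channel flips with 10 seeded restarts, anchored to
  all-+1 in the first session.

## Temporal statistics and validation

Fractional occupancy is computed from the posteriors (more sensitive
when states are nearly tied); lifetimes and intervals from the Viterbi
path, whose mutually exclusive runs are well defined. Runs truncated by
a segment edge are kept but flagged (dropping them biases lifetime
distributions downward); an exact accounting identity — per state,
lifetimes + intervals + edge gaps tile each segment — is asserted in the
tests. Validation heuristics flag states whose occupancy or mean
lifetime is a GESD outlier across states, and state/session pairs where
occupancy exceeds 5 times the state's median across sessions (a single
session described by a single state indicates a normalisation or
artifact problem). Neither threshold is canonical; both are arguments.

## Task-evoked analysis

Posterior probabilities are epoched around event onsets (trials touching
missing samples or segment boundaries are dropped and counted) and
baseline-normalised by *subtracting* the per-trial baseline mean
(−130 to −30 ms default): occupancies already share the unit scale, and
dividing by near-zero baselines would explode. The first-level GLM uses
a constant plus three demeaned condition indicators (Famous, Unfamiliar,
Scrambled; trials pooled across repeat levels); the demeaned indicators
sum to zero, so the design is rank 3 by construction and the
minimum-norm pseudo-inverse solution is used — the mean,
faces−scrambled and famous−unfamiliar contrasts are all estimable
(orthogonal to the null-space direction). The group level is an
inverse-variance-weighted mean with a one-step method-of-moments
between-subject variance (the first-level VARCOPEs enter as
within-subject variances). Significance uses sign-flip permutations with
the maximum absolute statistic over all timepoints and states per
contrast; the identity flip is included in the null so p-values are
bounded below by 1/n_perm, and inference is two-sided by default because
the differential contrasts are signed. A calibration test (200 null
datasets, 15 subjects, 1000 permutations, 50 timepoints × 6 states)
verifies family-wise error control at the nominal 5%.

## Spectra

State spectra are estimated post hoc by a multitaper (DPSS tapers from
the tridiagonal eigenproblem; defaults 2 s windows, 50% overlap,
time-bandwidth 3, 5 tapers — all configurable) with *window-level*
posterior weighting: each window's cross-spectral matrix is weighted by
the window-mean `gamma` of each state. Sample-level weighting inside a
tapered window would bias the spectrum. This weighting conserves total
power exactly: the occupancy-weighted sum of state PSDs equals the
unweighted whole-data PSD, an identity the tests assert at 1e-6.

NNMF spectral modes use alternating least squares (best of
`n_replicates` random starts per repeat), but the *final* repeat is
selected by unimodality — the repeat whose unit-maximum mode spectra are
best fit by single Gaussian bumps — not by reconstruction error, so the
retained modes are interpretable as separate frequency bands. Note an
identifiability caveat the tests make explicit: with strictly positive
loadings everywhere, an exact factorisation of disjoint bands is *not*
unique (one band can mix into another's mode at zero cost); when some
rows load on a single band (a separability condition that holds when
some parcels express a single rhythm), the factorisation is essentially
unique and the recovered modes separate the bands.

Coherence networks are thresholded by a two-component univariate
Gaussian mixture (BIC-compared against one component; connections kept
when more probably drawn from the higher-mean component), returning an
empty mask when one Gaussian suffices.

`reconstruct_tf` forms the rank-K time-frequency response
$\mathrm{TF}(t, f) = \sum_k \mathrm{occ}(t, k)\,\mathrm{psd}(k, f)$, and
`wavelet_tf` provides the 5-cycle Morlet comparator. When comparing the
two, their resolutions must be matched: at 10 Hz a 5-cycle wavelet has
~2 Hz spectral width, so the comparison fixture uses 1 s multitaper
windows (3 Hz bandwidth) and burst durations (1.5 s) long relative to
the wavelet's temporal smearing; with very short windows or bursts the
two estimators' different time-frequency trade-offs cap the attainable
pixel-wise correlation regardless of correctness.

## Synthetic data: what it does and does not show

The generators emulate the statistical structure each stage assumes:
Markov state sequences with Gaussian emissions; oscillatory bursts with
phase re-randomised at every state entry (visits are independent
events); and task sessions where events transiently bias the transition
probabilities toward a state — occupancy modulation arises through the
chain, not by forcing states, so the data remain Markov-generated
between events. Default study conditions used by the tests: the
two-node, three-state chain with means (0, 1), (−1, −1), (1, 0),
identity covariances and 0.98-sticky transitions at 10^4 samples; the
four-channel burst chain with 10 Hz (channels 1–2) and 25 Hz (channels
3–4) states at 250 Hz for 5 minutes; nine task conditions (three face
types × three repeats).

What passing these tests does **not** show: robustness to
non-Gaussian/heavy-tailed emissions, 1/f backgrounds, volume-conduction
leakage beyond the zero-lag model, head motion or physiological
artifacts, inter-subject spatial variability, or forward-modelled
sensor-space effects. Sensor-space preprocessing (Maxfilter, ICA
denoising, beamforming, atlas construction) is out of scope; the
package starts from parcel time-courses.

## Numerical choices and problem sizes

Forward–backward uses per-step scaling with row-max subtraction of log
densities (underflow-safe without log-space recursions); Viterbi is in
log space with ties broken to the lowest state index. Covariance work
is done through Cholesky factors. Free-energy convergence uses a
relative tolerance of 1e-6 by default. The test-suite problem sizes
(10^4–10^5-sample chains, 75 000-sample burst recordings, 200-dataset
permutation calibration at 1000 permutations) were chosen so each check
has clear statistical resolution while the whole suite runs comfortably
on a single CPU.

## Known limitations

The number of states K is fixed, not inferred; free energy tends to
decrease monotonically with K, so model choice in practice combines
free-energy comparison with robustness checks across K. The
autoregressive observation model and the infinite HMM are out of scope.
The stochastic mode trades inference noise for memory/speed and its
free-energy trace is not monotone. GESD assumes approximate normality
of the window statistics; heavy-tailed clean data can be over-flagged.
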