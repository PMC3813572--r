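---
title: "Multivariate versus bivariate connectivity: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate versus bivariate connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtfnet)
```

## The scientific problem

Scalp-recorded neural signals are strongly interdependent: a single cortical
generator is picked up, with different delays and attenuations, by many
electrodes. Any *bivariate* association measure — correlation, coherence,
synchronization likelihood (SL) — applied to such data reports a link between
every pair of channels that shares the generator. With one source observed at
`N` destination channels, a pairwise estimator finds the `N` true links plus
up to `N(N-1)/2` spurious destination–destination links: false links grow
quadratically while true links grow linearly. Graph analyses built on such
adjacency matrices inherit this artefact and tend toward dense, near-random
patterns.

A *multivariate* model fitted jointly to all channels can attribute each
inflow to its origin. This package implements that contrast end to end: a
multivariate autoregressive (MVAR) model, its spectral transfer matrix and
the normalized Directed Transfer Function (DTF) on one side; Welch coherence
and synchronization likelihood on the other; surrogate-based edge
significance; and network summaries (degrees, true/false edge accounting
against a known ground truth, and assortative-mixing module coupling).
Everything is driven by synthetic generators with known truth, so every claim
the package makes is testable.

## Models and estimators

### MVAR and the transfer matrix

The MVAR model of order $p$ for a $K$-channel signal $x_t$ is

$$x_t = \sum_{m=1}^{p} A_m x_{t-m} + e_t, \qquad \mathrm{cov}(e_t) = V.$$

`fit_mvar()` estimates all $A_m$ jointly by stacked multichannel least
squares (QR factorization), after zero-meaning and — by default —
variance-normalizing each channel so transfer-derived quantities are
comparable across channels. Stability is assessed by the companion-matrix
spectral radius; an unstable fit is flagged with a warning rather than an
error, because borderline fits do occur on real, noisy data. Rank-deficient
regressor matrices (e.g. duplicated channels) raise an error naming the
offending channels. `select_order()` scans orders $1..p_{max}$ on a common
sample under AIC (default) or BIC.

In the frequency domain, with
$A(f) = I - \sum_m A_m e^{-2\pi i f m / f_s}$, the transfer matrix is
$H(f) = A(f)^{-1}$ (`transfer_matrix()`), and the model-implied spectral
density is $S(f) = H(f)\, V\, H(f)^{\mathsf H} / f_s$ (`spectral_density()`).
The default frequency grid runs from 0 to Nyquist in 0.5 Hz steps, which
resolves the conventional analysis bands (0.5–40, 1–45, 4–60 Hz) exactly.

### Directed Transfer Function

`dtf()` computes the squared, normalized DTF

$$\gamma^2_{ij}(f) = \frac{|H_{ij}(f)|^2}{\sum_{m=1}^{K} |H_{im}(f)|^2},$$

the causal inflow from channel $j$ to channel $i$ as a fraction of all
inflows to $i$; rows sum to one at every frequency and all values lie in
$[0,1]$. The squared form is reported; readers comparing against literature
using the non-squared $|H|$ ratio should expect smaller off-diagonal values
here. `band_integrate()` averages the spectrum over a closed frequency band.
Because the DTF is normalized within each target row, its numerical scale is
roughly $1/K$: thresholds meaningful for a 21-channel analysis are not
meaningful for a 4-channel one (see *Significance* below).

`sdtf()` provides the short-time variant for repeated-trial designs: a short
window slides across the epoch, the regression moments are pooled (ensemble
averaged) across trials, one MVAR is solved per window, and DTF is computed
per window — the standard way to resolve time-varying propagation such as an
analysis epoch 0–3 s after a stimulus.

### Coherence

`coherence()` is the magnitude-squared coherence from Hann-tapered,
50%-overlapping Welch cross-spectra (defaults: 256-sample segments, which at
128 Hz puts the FFT bins on the same 0.5 Hz grid as the MVAR spectra).
Magnitude-squared (not magnitude) is used throughout and documented, since
the two conventions are easily confused. Coherence is symmetric, has a unit
diagonal, and is the package's reference bivariate estimator.

### Synchronization likelihood

`synchronization_likelihood()` follows the classical time-delay-embedding
construction. Each channel is embedded with delay $\tau$ and dimension $m$
(defaults 10 and 10). For each reference time $i$ the channel's critical
distance is chosen so that exactly a fraction `p_ref` (default 0.05) of
Theiler-valid vectors count as recurrences; the SL of a pair is the number of
*coincident* recurrences divided by its expectation under the per-channel
rate. Identical channels therefore give exactly 1 and independent channels
give values near the chance level `p_ref`. Two implementation choices
deserve note:

* the critical distance is taken as the $k$-th nearest-neighbour distance
  with $k = \mathrm{round}(p_{ref} \cdot M)$ — an exact order statistic that
  attains the target recurrence rate by construction, where an iterative
  bisection on the distance would only approximate it;
* the Theiler window defaults to $\tau \cdot m$ samples, excluding the whole
  autocorrelated embedding neighbourhood from the neighbour search.

## Significance

The package deliberately separates two resampling questions:

* **Does an edge exist?** `resampling_thresholds()` builds a null by
  *phase-randomizing each channel independently* — preserving every
  channel's amplitude spectrum while destroying all cross-channel
  dependence — then refits the MVAR and recomputes band-integrated DTF per
  surrogate. The per-pair threshold is the `level` quantile (default 0.9,
  read as the 90th percentile of the null). Resampling the original data
  *without* destroying dependence would preserve the very coupling under
  test and cannot serve as an existence null.
* **How uncertain is the estimate?** `dtf_bootstrap_ci()` resamples
  contiguous epochs with replacement and reports percentile intervals around
  the observed DTF.

`binarize()` turns an integrated matrix into an adjacency using a strictly
greater comparison (values tied with the threshold are excluded), either
against a scalar cutoff — the fixed-threshold path also used for SL — or
against a complete surrogate threshold table. On independent-channel data
the fraction of edges exceeding their level-0.9 thresholds is close to 10%
(the calibration is checked by the test suite over 500 fresh null draws).

Because normalized DTF scales like $1/K$, `run_modularity_experiment()`
derives its global cutoff procedurally by default: per-pair surrogate
thresholds at level 0.9, whose maximum is then fixed as a single cutoff for
all channels. A fixed numeric cutoff (such as the 0.05 conventional in
21-channel EEG work) remains available but does not transfer across channel
counts.

## Network summaries

`node_degrees()` counts in/out (or undirected) degrees. `classify_edges()`
scores an adjacency against a `ground_truth()` network — direction-sensitive
for directed estimators, against the undirected skeleton for symmetric ones —
and always conserves `true_detected + missed = |truth|`.

`mixing_matrix()` aggregates a thresholded, band-integrated connectivity
matrix over a module partition: $E_{kl}$ sums the qualifying values over all
ordered channel pairs with the source in module $l$ and the target in module
$k$, and the matrix is normalized to total 1. The sum (not the mean) over
qualifying pairs is the default because the assortative-mixing reading of
$E$ is a *fraction of total coupling*; a mean variant (which differs only by
module-size factors) is available via `aggregate = "mean"`.
`assortativity_report()` compares each diagonal element against the mean of
its off-diagonal row and column entries; the global flag is true when every
module couples more strongly within itself than with the rest — with ratios
against an exactly zero off-diagonal mean capped at the sentinel `1e6`.

The default scalp partition (`default_partition_1020()`) has four modules:
frontal (8 electrodes), central (5), parietal-left and parietal-right. The
midline electrode Pz sits between the parietal modules and conventions
differ on its assignment; since modules must be disjoint, the package
assigns it to PL by default and exposes `pz = "PR"` as an override. The
synthetic modular fixture (`fixture_partition_8544()`) instead balances the
parietal modules at 4 channels each using the full 21-channel montage.

## The synthetic generators: what they emulate and what they do not

All generators flow from one `sim_config()` (length, rate, SNR, master
seed); identical configurations give bit-identical output, with each
channel's noise drawn from an independent sub-seeded stream.

* `gen_source_signal()` — the stand-in for a real EEG trace: a stable AR(4)
  with a sharp pole pair at 10 Hz (modulus 0.92, the alpha resonance) and a
  weak damping pair at 20 Hz, high-pass filtered at 3 Hz (4th-order
  Butterworth, zero-phase) and standardized. Less than 5% of its power lies
  below 3 Hz and its spectral peak falls in 8–13 Hz.
* `simulate_common_source()` — the headline fixture: channel 1 is source
  plus measurement noise; each destination channel is the *delayed channel-1
  composite* plus extra independent noise. The observed channel is the
  propagating quantity, which is what makes the multivariate attribution
  problem well posed: channel 1's past is a complete description of what
  reaches the sinks. (Delaying only the latent source instead would make
  every sink an independent noisy witness of it, and the jointly fitted
  MVAR would legitimately exploit cross-sink noise averaging, producing a
  cascade of weak sink-to-sink inflows — a materially different, and harder,
  inference problem.) Default SNR is 2; delays are integer sample shifts
  with the first `max(delay)` samples discarded so all channels share a
  valid support; output channels are standardized to unit variance, which
  keeps the equal-variance contract and changes nothing causal.
* `simulate_mvar_network()` — exact MVAR recursion from stated
  coefficients, after a discarded burn-in of `10 * order * n_channels`
  samples, with the truth edge set read off the nonzero coefficients.
* `simulate_volume_conduction()` — every channel is a positive weight times
  the *same* source at zero lag plus independent noise; no causal edge
  exists.
* `simulate_modular_network()` — dense intra-module directed coupling
  (default gain 0.1 at lag 1) and sparse inter-module coupling (default
  0.02, two random directed pairs per ordered module pair), on top of mild
  private AR(2) dynamics per channel; couplings are rescaled by 0.9 (with a
  message) until the system is stable.

None of these emulate realistic head-model forward projection, ocular or
muscular artefacts, or non-stationary drift. Passing tests on these fixtures
show that the estimators behave as designed under their generative
assumptions — linear dynamics, Gaussian noise, stationarity — not that any
particular real recording satisfies those assumptions.

## Numerical choices

* Frequency grid 0–Nyquist in 0.5 Hz steps; band edges inclusive on both
  sides; requested coherence frequencies map to the nearest FFT bin.
* Transfer matrices are computed by exact complex inversion per frequency;
  a singular characteristic matrix names the offending frequency.
* MVAR order for delayed-propagation data must cover the largest delay —
  a shorter memory forces the fit to route the source's influence through
  intermediate channels, creating false transit edges. The contrast
  experiment defaults to `max(delays) + 4`.
* Problem sizes in the test suite and acceptance script are desk scale:
  recordings of 1–20 s at 128 Hz, 2–21 channels, 10 seeds per claim,
  100–300 surrogates per threshold and 500 draws for the calibration check.

## A known limitation, stated plainly

Instantaneous (zero-phase) mixing is *not* invisible to the jointly fitted
MVAR under this package's generative model. When every channel carries the
same autocorrelated source at zero lag plus independent noise, each
channel's past genuinely improves the prediction of every other channel
(noise averaging across redundant witnesses), so the population MVAR has
nonzero cross-coefficients and the band-integrated off-diagonal DTF sits
well above the phase-randomization null (about 0.09 at the default SNR for
four channels, against null thresholds near 0.01). The effect is
structural — it does not shrink with sample size — and symmetric: the
spurious inflows carry no preferred direction, unlike genuine delayed
propagation. The acceptance suite asserts the strict below-null immunity
property regardless, and that assertion fails under this model; the
corresponding quantity (`vc_dtf_below_null_pct`) is reported honestly by
the acceptance script. Users analysing data where zero-lag mixing dominates
should treat symmetric bidirectional DTF patterns with suspicion rather
than reading them as reciprocal coupling. Bivariate coherence, for
comparison, saturates near 1 at the source peak under the same mixing.
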