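---
title: "Finite-sample effects in thresholded interaction networks, and how spurnet corrects them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-sample effects in thresholded interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spurnet)
```

## The model

`spurnet` studies the standard two-step chain used across the neurosciences,
climate science and quantitative finance to turn `N` simultaneously recorded
time series of length `N_s` into an unweighted, undirected *interaction
network*:

1. **Interdependence estimation.** Either the absolute Pearson correlation
   `ρ^c_ij` (`corr_matrix()`) or the maximum absolute cross-correlation
   `ρ^m_ij = max_{|τ| ≤ τ_max} |(1/N_s) Σ_t x̃_i(t+τ) x̃_j(t)|`
   (`maxcrosscorr_matrix()`), where `x̃` denotes channels normalized to zero
   mean and unit *population* variance.  With that convention the lag-0
   cross-covariance reproduces `ρ^c` exactly, so `ρ^m ≥ ρ^c` holds entrywise
   as an exact invariant rather than an approximation.  Lags are
   non-circular (zero-padded); the default lag range is the full `N_s − 1`
   because the empirical literature rarely reports its choice — it is
   configuration, not a claim.

2. **Thresholding.** `threshold_by_value()` links `i, j` when the estimate
   strictly exceeds θ; `threshold_by_density()` links the
   `m_e = round(ρ N(N−1)/2)` strongest pairs (round-half-up; ties broken by
   value descending then smallest index pair, which makes edge sets nested
   across densities — ties have measure zero for continuous estimators, but
   determinism matters for reproducibility).

Networks are summarized (`network_metrics()`) by the clustering coefficient
`C` (mean local transitivity, with `c_i = 0` for degree < 2 — the 0/0 case —
keeping `C ∈ [0, 1]`), the average shortest path length `L`, the number of
connected components `K`, and the degree sequence.

**The `L` convention matters.** `L` averages distances over unordered pairs
*including* each node with itself (`d_ii = 0`), and *excludes* pairs in
different components.  On a connected graph the excluded-self variant
differs by exactly `(n+1)/(n−1)`; on a fragmented graph `L` can decrease as
the graph fragments, because long paths leave the average.  Both variants
are exposed (`avg_shortest_path(net, include_self = )`) and the factor is
asserted in the tests.

## Why independent noise produces "small worlds"

For two *independent* channels the correlation estimate is noise around
zero with variance `≈ c(M)/N_s`, where `M` is the size of a trailing
moving-average filter applied to the raw series and
`c(M) = Σ_τ r_M(τ)² = (2M² + 1)/(3M)` is the Bartlett variance-inflation
factor of the filter's triangular autocorrelation `r_M(τ) = (M − |τ|)/M`.
Two closed forms follow, both implemented analytically and validated against
Monte-Carlo oracles:

* **Effective length** (`effective_length()`): `N_eff = N_s / c(M)` is the
  white-noise length with the same estimator variance.  The independent
  oracle (`mc_effective_length()`) matches the measured `Var(r̂)` of filtered
  pairs against a white-noise curve family built on nested prefixes of a
  single random stream (common random numbers make the variance curve smooth
  in the candidate length).  `fit_effective_length()` recovers the same
  quantity from edge-density curves in a least-squares sense.

* **Asymptotic edge density** (`asymptotic_edge_density()`):
  `ρ̃(θ) = 2(1 − Φ(θ √N_eff))`.  This is an *asymptotic* statement: the
  exact null of `r̂` is t-distributed, and for small `N_eff` (e.g.
  `N_s = 500, M = 8`, `N_eff ≈ 93`) the normal form under-covers the deep
  tail (densities below a few percent) by more than 3 binomial standard
  errors at 10⁵ Monte-Carlo pairs.  The package reports this honestly: the
  acceptance suite's agreement criterion is borderline red precisely there,
  while the companion "breakdown" criterion verifies that the discrepancy at
  `N_s = 32` dwarfs that at `N_s = 1000`.

At a fixed edge density, the finite-sample fluctuations are *shared*: the
three pair estimates among channels `i, j, k` are positively dependent, so
the conditional probability that `(i, k)` is linked given `(i, j)` and
`(j, k)` are linked exceeds the density — clustering inflation.
`mc_clustering()` estimates this size-independent quantity over independent
triples, converting density to threshold via the empirical quantile of the
pooled pair values (a monotone inversion of the Monte-Carlo edge-density
curve).  `L`, by contrast, stays close to its ER value at field-typical
densities — together the classic small-world signature, with no interaction
anywhere.  Strong low-frequency content also fragments the networks
(isolated nodes whose realized spectra happen to carry little low-frequency
power) and correlates degrees with low-frequency power
(`degree_power_correlation()`, split frequency from `choose_fstar()`).

## Tailored null ensembles

ER graphs are the wrong null for thresholded noise networks.  `spurnet`
builds two nulls matched to each analysis window
(`build_null_ensemble()`, default `R = 20` realizations):

* **spectrum** — fresh uniform noise filtered in the Fourier domain to the
  channel-mean periodogram of the window.  Matches power content at the
  window level; all null channels share one spectrum.  Fresh noise is drawn
  per realization (not phase randomization of one fixed series).
* **iaaft** — one IAAFT surrogate per channel (`iaaft_surrogate()`):
  alternate imposing the channel's Fourier amplitudes and rank-remapping
  onto its sorted values.  Amplitude distribution preserved *exactly*,
  spectrum approximately, cross-channel dependence destroyed.  Stopping
  rule: relative L2 change of the periodogram `< 1e-6` or 1000 iterations
  (the method's originators give no parameters; non-convergence is a
  warning carrying diagnostics, never an error).

When channel spectra are homogeneous the two ensembles agree (tested as
statistical agreement under `ρ^c`); when they are heterogeneous, the
maximum cross-correlation estimator is markedly more sensitive to the
difference, which is why both ensembles are kept.  Observed metrics are
divided by ensemble means (`normalize_by_ensemble()`): ratios near 1 mean
"explained by length and power content".

## The windowed pipeline

`window_series()` cuts a recording into non-overlapping windows (e.g. 2.5 s
at 200 Hz = 500 samples), normalizing each window's channels to zero mean
and unit variance.  `analyze_recording()` computes, per window, estimator
and ensemble, the observed `C`, `L`, `K` at a single fixed density (fixing ρ
excludes edge-density effects from metric comparisons) plus ensemble
means/SDs and ratios.  `bin_event()` maps event windows onto 10 equidistant
bins by proportional cut points `⌊kW/10⌋` plus one pre- and one post-event
bin of `n_peri` windows each, pooling windows across recordings within bins
and reporting mean ± standard error.  `smooth_profile()` (four-point
trailing average) is presentation-only and never feeds the binned
statistics.  If a window's null ensemble has zero mean clustering (possible
for very small networks), the ratio is reported as `NA` with a warning
rather than aborting the run.

## The synthetic-data generators: what they emulate, and what a green test proves

No public recording accompanies the underlying EEG analyses, so the package
generates its own inputs:

* `gen_uniform_series()` — i.i.d. uniform noise on (−0.5, 0.5), rows
  centered.  The support is a documented constant: any centered interval is
  equivalent after normalization.
* `moving_average_filter()` / `gen_filtered_series()` — trailing (causal)
  window of `M` samples; a centered window would only shift phase and
  changes none of the statistics used.  `M − 1` extra raw samples are drawn
  so no partial windows exist.
* `gen_spectrum_filtered_noise()` — Fourier coefficients of white noise
  scaled by the square root of a target spectrum (DC zeroed), then
  normalized to zero mean, unit variance.  The *ensemble-mean* periodogram
  converges to the target; individual realizations fluctuate, and for very
  steep targets the per-realization unit-variance normalization biases the
  mean slightly (the convergence test uses a moderate spectrum for this
  reason).
* `gen_seizure_like_recording()` — windows of spectrum-filtered noise whose
  relative band powers (δ, θ, α, β, half-open edges `(lo, hi]` so the bands
  partition `(0, 20]`) follow a `band_schedule()`; residual power spreads
  over the remaining band up to Nyquist.  Cross-channel coupling mixes a
  shared latent signal with the same spectrum:
  `x_i = √(1−γ²)·ε_i + γ·z`, so pairwise correlation ≈ γ² and band powers
  are untouched.  Defaults in the acceptance scenarios emulate the reported
  seizure phenomenology — δ-dominant pre/post (≈ 0.7 relative power),
  β-shifted during the event — and 30 channels, close to the multichannel
  recordings the method targets.

The emulator controls *only* band powers and coupling.  It has no spikes,
artifacts, 1/f background or nonstationarity within windows; a green
pipeline test therefore establishes that the normalization isolates coupling
from spectral change in this controlled world, not that it handles every
pathology of clinical EEG.

## Numerical and design choices

* Monte-Carlo pair/triple kernels are compiled (Rcpp) and stream series
  through running sums — 10⁵ pairs at `N_s = 10³` take seconds.  They use
  R's RNG, so everything is reproducible from a single integer seed;
  ensemble members and emulator windows derive child seeds from a master
  seed via a counter kept inside 32-bit range.
* Density→threshold inversion uses empirical quantiles of pooled pair
  values; `ρ = 1` maps to θ = 0 (every pair linked almost surely).
* `fit_effective_length()` minimizes over a fine geometric grid of ~100
  candidate lengths rather than a smooth optimizer: the objective is
  piecewise constant in the integer length and grid search cannot fail;
  residuals are reported.
* The `f*` split of the filter power (`choose_fstar()`) defaults to the
  fraction 0.4 referring to the *upper* range `[f*, Nyquist]`; the lower
  convention is exposed (`side = "lower"`) since the underlying criterion is
  known not to affect results sensitively.  `M = 1` has a flat transfer
  function; the function warns and returns Nyquist/2.
* Degenerate inputs error early and name the offending channel (constant
  channels in estimators and ensembles, band edges above Nyquist, lag
  ranges beyond `N_s − 1`).

## Known limitations

* The asymptotic edge-density formula under-covers the deep tail for
  `N_eff ≲ 100` (see above); use `mc_edge_density()` there.
* ER connectivity claims near the threshold density `ln(n)/n` are
  finite-size sensitive: at `n = 100, ρ = 0.05` about half of ER
  realizations contain an isolated node, so "ER networks are connected"
  holds only comfortably above the threshold (e.g. ρ = 0.1).
* Weighted networks, minimum-spanning-tree / significance-testing /
  rank-growth link definitions, degree-preserving rewiring nulls, other
  interdependence estimators (phase synchronization, mutual information)
  and automated event detection are out of scope.
* EDF input is not supported in this build (no EDF reader in the target
  environment); recordings are exchanged as TSV plus a JSON sidecar.
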