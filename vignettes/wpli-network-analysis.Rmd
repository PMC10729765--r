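---
title: "Band-resolved wPLI brain networks: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-resolved wPLI brain networks: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wplinet compares resting-state functional brain networks between two groups
of subjects from multichannel scalp EEG. This vignette is the package's own
account of the methods: the connectivity estimator and its assumptions, the
graph metrics, the statistical layer, the synthetic-data generator that
provides ground truth, and the numerical and design choices a reader of the
code will want spelled out.

## The analysis model

Each subject contributes one continuous multichannel recording (the
reference geometry is the 19 scalp electrodes of the 10–20 system sampled
at 500 Hz). The pipeline is, in order:

1. **Channel selection** against a requested montage, tolerant of EDF label
   dialects (`"EEG Fp1-REF"` matches `Fp1`).
2. **Broadband filtering** to 0.5–45 Hz with a 4th-order Butterworth
   bandpass applied forward and backward (`signal::filtfilt`), i.e.
   zero-phase with an effective 8th-order magnitude response.
3. **Common average reference**: the instantaneous channel mean is
   subtracted from every channel.
4. **Band decomposition** into delta (0.5–4 Hz), theta (4–8), alpha (8–13),
   beta (13–30) and gamma (30–45), with the broadband signal retained as a
   sixth "full" band.
5. **Epoching** into non-overlapping 2-s windows starting at the first
   sample; a trailing remainder is dropped. At 500 Hz a 20-min recording
   yields exactly 600 epochs of 1000 samples.
6. **Connectivity**: the weighted phase lag index (wPLI) of every channel
   pair, per epoch, averaged over epochs to one symmetric matrix per
   subject per band.
7. **Network metrics**: average degree, weighted clustering coefficient,
   characteristic path length and global efficiency of each matrix.
8. **Group statistics**: edgewise Welch t-tests with Benjamini–Hochberg FDR
   control per band, rank-sum tests on each network metric, and a
   top-fraction cut of the strongest differential edges.

Steps 2–3 commute (both are linear and the filter is zero-phase), which the
test suite asserts numerically; the order above is fixed as configuration,
not as a mathematical necessity.

## The wPLI estimator

For two analytic signals $a_i(t), a_j(t)$ the instantaneous cross-spectrum
is $Y(t) = a_i(t)\,\overline{a_j(t)}$ and

$$\mathrm{wPLI} \;=\; \frac{\bigl|\,E[\,\mathrm{Im}\,Y\,]\,\bigr|}
{E\bigl[\,|\mathrm{Im}\,Y|\,\bigr]} \;\in\; [0, 1].$$

Weighting each phase-difference sign by $|\mathrm{Im}\,Y|$ makes the index
insensitive to zero-lag (volume-conduction-like) coupling: a source mixed
instantaneously into both channels contributes $\mathrm{Im}\,Y = 0$ terms.
The estimator choices that the formula leaves open are resolved as follows:

* **Expectation domain.** $E[\cdot]$ is taken over time samples within one
  epoch, on Hilbert analytic signals of the band-filtered data; the
  subject-level value is the mean over epochs. An alternative reading
  (expectation over epochs per frequency bin, from tapered FFT
  cross-spectra) is noted as a possible extension and not implemented.
* **0/0 guard.** When every $\mathrm{Im}\,Y$ term vanishes (e.g. identical
  channels) the index is defined as 0: zero evidence of lagged
  synchronization.
* **Edge trimming.** The first and last 5 % of samples of each epoch are
  excluded from the expectation, suppressing the Hilbert transform's edge
  artifacts (`edge_trim = 0.05` in `wpli_matrix()`).
* **Estimator bias.** Under independent signals the wPLI is a positively
  biased estimate of zero; the bias scales like the inverse square root of
  the number of effectively independent samples per epoch, i.e. with the
  epoch-duration × bandwidth product. This is why the null wPLI falls as
  epochs lengthen (2 s → 4 s → 8 s) yet barely moves when the sampling
  rate changes at fixed epoch length — a pattern `sensitivity_harness()`
  reproduces and the acceptance tests assert. It also means per-epoch null
  values in narrow bands (delta at 2 s: ≈ 0.3–0.4) are far from zero;
  group comparisons are unaffected because both groups carry the same
  bias.

## Graph metrics

All four metrics operate on the symmetric, non-negative, zero-diagonal
wPLI matrix $W$ with $N$ nodes, without any density thresholding (the
top-10 % device in the statistics layer is presentational, not a network
construction step):

* **Average degree** $D = \frac{1}{N}\sum_{ij} w_{ij}$ — mean node
  strength.
* **Clustering coefficient.** The binary triangle formula degenerates on a
  dense weighted matrix (every graph is near-complete), so the default is
  the weighted geometric-mean-of-triangles coefficient on max-normalized
  weights, the Brain Connectivity Toolbox convention:
  $C_i = \sum_{jk}(\hat w_{ij}\hat w_{ik}\hat w_{jk})^{1/3} / (k_i(k_i-1))$
  with $\hat w = w / \max w$. The literal binary coefficient on a
  thresholded graph remains available (`weighted = FALSE`). Max-normalizing
  makes CC scale-invariant; it also means CC responds to the *contrast*
  between the strongest edge and the rest, so planting a few very strong
  edges can lower CC even as mean connectivity rises.
* **Paths.** Edge length is $1/w_{ij}$ (no edge for $w_{ij}=0$); all-pairs
  shortest paths are Dijkstra via igraph, cross-checked against a
  Floyd–Warshall oracle in the tests. The alternative $-\log w$ length map
  is documented but not used.
* **Characteristic path length** $\mathrm{CPL} =
  \frac{1}{N(N-1)}\sum_{i\neq j} l_{ij}$. A disconnected pair makes CPL
  infinite; the package reports `Inf` with a warning rather than silently
  averaging finite pairs (which changes the estimand), and offers
  `finite_pairs = TRUE` for comparability.
* **Global efficiency** $\mathrm{GE} =
  \frac{1}{N(N-1)}\sum_{i\neq j} 1/l_{ij}$ with $1/\infty = 0$, so GE is
  robust to disconnection. On a uniform complete graph
  $\mathrm{GE}\cdot\mathrm{CPL} = 1$ exactly, which the tests assert; the
  inequality $\mathrm{GE} \ge 1/\mathrm{CPL}$ is not asserted in general.

## Group statistics

* **Edgewise tests.** Welch's unequal-variance t-test per edge, two-sided.
  Welch is chosen because the reference design is unbalanced (10 vs 5
  subjects) and no variance homogeneity is assumed. The aggregation level
  is configurable: `"subject"` (one epoch-mean wPLI per subject per edge;
  the default, defensible at small n) or `"epoch"` (pooling per-epoch
  values). Degenerate edges (zero variance in both groups, equal means)
  are reported as $t = 0, p = 1$ with a flag.
* **Multiplicity.** Benjamini–Hochberg step-up within each band's edge
  family (each band is its own analysis); rejection at adjusted
  $p \le q = 0.05$.
* **Top-fraction edges.** Among FDR-significant edges, the
  $\lceil 0.10 \times \text{edges} \rceil$ smallest adjusted p values
  (ties by $|t|$) are kept for reporting/plotting; if fewer are
  significant, all are kept.
* **Network metrics.** Wilcoxon–Mann–Whitney rank-sum per (band, metric),
  two-sided at $\alpha = 0.05$. The null distribution is exact — full
  enumeration over group labelings, valid under ties — whenever both
  groups have ≤ 8 subjects or the pooled size is ≤ 10; otherwise a normal
  approximation with mid-ranks, tie-corrected variance and continuity
  correction is used. At 10 vs 5 the approximation and enumeration agree
  to within about 0.015.

## The synthetic-data generator

Clinical scalp-EEG cohorts of the motivating kind (here, 10
drug-resistant-epilepsy patients vs 5 healthy controls) are rarely
publicly deposited, so every quantitative claim the package makes is
exercised on simulated cohorts with planted ground truth. Each simulated channel is

$$x_c(t) \;=\; s_{\mathrm{uV}}\Bigl[\; n_c(t) \;+\;
\sum_{b} A_b\, u_{c,b}(t) \Bigr]$$

where $n_c$ is $1/f$ background noise (white noise spectrally shaped with
exponent 1, unit variance) and $u_{c,b}$ is a unit-variance narrowband
Gaussian process (white noise Fourier-masked to band $b$). A coupling in
band $b$ between channels $i, j$ replaces the private processes by
$\sqrt{1-s}\,u + \sqrt{s}\,g$, where $g$ is a shared narrowband source and
channel $j$'s copy of $g$ is rotated by a fixed phase lag in the analytic
domain. The analytic-domain rotation (rather than a sample delay) keeps
the lag constant across the band, which makes the limiting wPLI values
exact: 0 at strength 0, → 1 at strength 1 for lags away from 0 and π.

Defaults, chosen once as a realistic operating point and then left alone:

* per-band amplitudes $A_b$ = 1.0, 0.8, 0.8, 0.6, 0.5 (delta…gamma),
  echoing the decline of spectral power with frequency; noise amplitude 1;
  output scale 20 µV;
* coupling lag π/2 (maximal imaginary cross-spectrum);
* group effects: six disjoint coupled pairs per band with strengths
  (group A vs B) of 0.15 vs 0.55 in delta, 0.35 vs 0.35 in theta, and
  0.55 vs 0.15 in alpha, beta and gamma. This plants the direction
  pattern the pipeline is designed to detect — connectivity down in
  delta, unchanged in theta, up in alpha/beta/gamma in group A — with
  effect sizes large enough to be resolvable at 10 vs 5 subjects. No
  empirical effect sizes exist to copy, so these are the package's own
  calibration, not measured clinical values.
* geometry presets: `"study"` (19 channels, 500 Hz, 20 min) mirrors the
  reference acquisition; `"fast"` (8 channels, 250 Hz, 2 min) is the
  default and keeps a full two-group run around 20 s on one core. The
  test-suite problem sizes quoted below all use the fast preset or
  smaller.

Per-subject sub-seeds are derived deterministically from the master seed
and the subject counter, so any subject can be regenerated in isolation
and whole cohorts are bitwise reproducible.

What the generator deliberately does **not** emulate: volume conduction
through a head model (couplings are planted directly between electrodes),
EMG/eye-blink artifacts, epileptiform discharges, non-stationarity, or
between-subject heterogeneity of coupling strength (within a group, only
the noise realization differs across subjects). Passing tests therefore
demonstrate that the estimator, metrics and statistics recover planted
effects of this idealized kind — they do not certify performance on
clinical recordings, where artifact screening (an expert, human-in-the-loop
step that this package exposes only as a hook between loading and
filtering) and much larger between-subject variability dominate.

## Numerical choices and degenerate inputs

* Butterworth order 4 per pass; at 500 Hz the delta band (0.5–4 Hz) is the
  numerically hardest design and remains stable in transfer-function form.
  The analytic two-pass gain is exposed as `bandpass_gain()` and the tests
  compare measured steady-state amplitudes against it (the broadband
  filter attenuates a 50 Hz tone to a gain of ≈ 0.29, not to zero — an
  8th-order roll-off, not a brick wall).
* EDF output is 16-bit with per-channel physical scaling; round-trip error
  is bounded by one quantization step, `(max − min)/65535`.
* The analytic signal is computed per epoch by FFT (negative frequencies
  zeroed); epochs are short (≤ 8 s), so no chunking is needed.
* Rank-sum enumeration is capped at `choose(16, 8) = 12870` labelings;
  beyond that the normal approximation takes over.
* Degenerate cases: single-channel re-referencing, epochs longer than the
  recording, bands at or above Nyquist, empty epoch stacks, zero-variance
  edges, all-identical rank-sum inputs, and disconnected networks all
  raise errors, flags or warnings rather than returning silent numbers.

## Known limitations

* The weighted-CC direction under max-normalization can oppose the mean
  connectivity direction when planted couplings dominate the matrix
  maximum (see above); degree, CPL and GE do not share this sensitivity.
* CPL on a disconnected network is `Inf` by design; downstream rank-sum
  tests still work (ranks tolerate infinities) but medians become
  non-informative if many subjects disconnect.
* The epoch-level aggregation option treats epochs as exchangeable
  observations, understating between-subject variance; it exists because
  pooled epoch counts are the natural reading of some published analyses,
  and the output labels the level used.
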