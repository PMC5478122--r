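---
title: "Supervised spectral filters for iEEG seizure forecasting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised spectral filters for iEEG seizure forecasting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Seizure forecasting asks whether the minutes-to-hours before a seizure (the
*preictal* state) are electrophysiologically distinguishable from baseline
(*interictal*) activity. The data are long intracranial EEG (iEEG)
recordings cut into ten-minute multichannel clips, heavily imbalanced toward
interictal, with the clip as the unit of prediction: the system must emit
one preictal probability per clip.

The standard spectral feature is the power-band filter (PBF): average the
FFT magnitude bins inside each canonical band — delta (0.1–4 Hz), theta
(4–8), alpha (8–12), beta (12–30), low gamma (30–70), high gamma (70–180) —
giving six features per channel per window. PBF is unsupervised: if the
class difference lives in a narrow sub-band, uniform averaging dilutes it by
the width of the band. `seizecast` implements a family of *supervised* band
filters that learn, from labeled training windows, a weight vector over each
band's bins that emphasizes the discriminative frequencies.

# The pipeline

Each clip is sliced into 60-second Hamming-tapered windows with a 30-second
step (19 windows for a 600 s clip), each window zero-padded to the next
power of two and Fourier transformed; the `fft_length/2` positive-frequency
magnitude bins (DC excluded) are log-compressed with `log1p`. A filter bank
reduces each window to one feature per (channel, band). A K-nearest-neighbour
classifier with K = 40 converts each window's feature vector into a preictal
posterior by exponential distance weighting,

$$\Pr(G=1\mid x) \;=\; \frac{\sum_{y \in \mathcal K_1} e^{-\lVert y-x\rVert^2/2}}
  {\sum_{y \in \mathcal K} e^{-\lVert y-x\rVert^2/2}},$$

and the window posteriors $p_1,\dots,p_n$ of a clip are aggregated through
the complemented geometric mean of complements,

$$\Pr(\text{preictal}\mid \text{clip}) \;=\; 1 - \Bigl(\prod_{t=1}^n (1-p_t)\Bigr)^{1/n},$$

which is sensitivity-oriented: any window posterior of 1 forces the clip
probability to 1, and the output always lies between the smallest and
largest window posterior.

# The filter objectives

Write $Z$ for the feature vector of an interictal window and $Y$ for a
preictal window, restricted to one band's bins (one channel by default). All
supervised filters return a unit vector $u$; the filtered feature is
$u \cdot x$.

* **DM** (difference of means): maximize $E[u\cdot(Z-Y)]$; closed form
  $u = (E[Z]-E[Y]) / \lVert E[Z]-E[Y]\rVert$.
* **VAR** (variance difference): maximize
  $\operatorname{Var}(u\cdot Z)-\operatorname{Var}(u\cdot Y)$, the quadratic
  form of $S = E[ZZ^\top]-E[YY^\top]-E[Z]E[Z]^\top+E[Y]E[Y]^\top$.
* **TVM** (trade-off variance–mean): maximize
  $(E[u\cdot Z - u\cdot Y])^2 + \operatorname{Var}(u\cdot Z) - \operatorname{Var}(u\cdot Y)$,
  the quadratic form of
  $E[ZZ^\top]-E[YY^\top]+(E[Y]-E[Z])E[Y]^\top+E[Y](E[Y]-E[Z])^\top$.
* **DS** (difference of second moments): maximize
  $E[(u\cdot Z)^2-(u\cdot Y)^2]$, the quadratic form of
  $E[ZZ^\top]-E[YY^\top]$.
* **SqD** (paired squared difference): maximize $E[(u\cdot(Z-Y))^2]$, the
  quadratic form of $E[(Z-Y)(Z-Y)^\top]$.

For a band with thousands of bins these matrices are never materialized:
`filter_matvec()` computes $Mv$ through the stored class sample matrices as
$(1/n)X^\top(Xv)$ plus rank-one mean terms, and `power_iteration()` runs on
that operator. For SqD the default expands the paired expectation under
independent pairing,
$E[ZZ^\top]+E[YY^\top]-E[Z]E[Y]^\top-E[Y]E[Z]^\top$, which is deterministic;
the streaming sampled-pair form (each preictal window paired with a randomly
drawn interictal window, reshuffled every sweep, averaged over a few sweeps)
is available via `pair_stream("sampled_pairs")` and agrees with the
independent-moment route on independent classes (a property the test suite
checks at $|\cos| \ge 0.99$).

## Which eigenpair, and why

VAR, TVM and DS are indefinite quadratic forms, so "the" eigenvector is a
real design decision. Raw power iteration converges to the
**largest-magnitude** eigenpair, and that is what `seizecast` reports by
default. The reason is substantive, not numerical: these objectives measure
a *class contrast*, and the direction of strongest contrast can carry a
negative eigenvalue — for DS this happens precisely when preictal power
exceeds interictal power in the informative bins, which is the typical
planted-effect (and physiologically interesting) situation. Selecting the
algebraically largest eigenvalue instead would discard that direction in
favour of whatever weak positive-noise direction exists, destroying the
filter's ability to localize the effect. A rank-two analysis of the DS
matrix under a narrow-band mean shift makes this concrete: with planted
indicator $p$ and log-magnitude mean $\mu$, the signal part of the matrix is
$-[\delta\mu(p\mathbf 1^\top + \mathbf 1 p^\top) + \delta^2 pp^\top]$, whose
dominant eigenvector (negative eigenvalue) mixes $p$ with the flat
direction, while its positive eigenvalue belongs to a vector nearly
orthogonal to $p$. The algebraic convention is still available as
`power_iteration(ensure = "algebraic")`, which re-runs the iteration on the
shifted operator $M + |\lambda| I$ when the dominant eigenvalue is negative.
The sign of the returned vector is fixed by making its largest-magnitude
component positive (ties broken by the lowest index); DM keeps its natural
sign because its objective is linear, not quadratic.

Numerical controls: convergence is declared when
$1-|u^{(k)}\cdot u^{(k-1)}| < \texttt{tol}$ (the absolute inner product, so
an alternating sign under a negative eigenvalue still converges), with
`tol = 1e-9` and `max_iter = 1000` as estimation defaults — tight enough
that the oracle tests agree with dense eigendecomposition to
$|\cos|\ge 0.999$ and $10^{-6}$ relative eigenvalue error on problems up to
d = 40. A vanishing matrix–vector product from the all-ones start raises a
"degenerate operator" error rather than returning an arbitrary direction.

## Log compression order

The pipeline description admits two orders: compress bins with `log1p` and
then filter (the default, `log_order = "pre"`), or filter raw magnitude bins
and log-compress the weighted sum (`log_order = "post"`). Signed supervised
weights can produce negative weighted sums, outside the domain of `log1p`,
so the post order clamps its input to $> -1 + 10^{-12}$ before compressing.
Both orders are implemented; neither is asserted to be canonical, and the
filter bank records which one it was trained with so `apply_filters()` stays
consistent at prediction time. A `spectrum = "power"` switch squares the
magnitudes first.

# Classification choices

Features are standardized with training-set statistics before distances
(constant features get scale 1): the posterior's $e^{-d^2/2}$ kernel is
scale-sensitive and the bands differ by orders of magnitude in raw level.
This is an artifact decision, toggleable via `standardize = FALSE`, not a
reconstruction of the original system. Ties at the K-th neighbour distance
are broken by stable training-row order; neighbour weights are computed
after subtracting the smallest squared distance, so the ratio is unchanged
but cannot underflow to 0/0. Aggregation is computed in log space as
`1 - exp(mean(log1p(-p)))`.

Cross-validation is leave-one-seizure-out: one fold per preictal one-hour
sequence, with interictal sequences dealt round-robin (ascending sequence
id) into the validation sets so every fold scores both classes and no
validation window ever contributes to its own fold's training windows.
Filters are always estimated per subject, within the fold's training split,
so supervision never leaks across subjects or folds.

# Evaluation

AUC is computed as the tie-corrected Mann–Whitney statistic (ties credit
1/2), which the test suite verifies equals the trapezoidal area under the
empirical ROC curve to $10^{-12}$. Paired model comparisons use DeLong's
placement-value method: per-scorer placements are computed by the midrank
identity, their empirical covariances across positives and negatives give
the variance of the AUC difference, and the statistic is referred to a
standard normal, two-sided by default. Identical score vectors return
p = 1 by convention; exactly separable scorers with unequal AUCs have zero
placement variance and are refused with an error rather than given an
infinite statistic. No multiple-testing correction is applied across
comparisons; p-values are reported as-is.

# The synthetic generator

Real contest data is access-gated and multi-gigabyte, so validation runs on
synthetic subjects with *planted* class structure. Clips are synthesized by
spectral shaping: each channel's half-spectrum is complex Gaussian with
standard deviation set by a target amplitude spectrum — a $1/f^2$ baseline
power law plus a white floor — and inverse transformed to a real signal.
This gives exact control of planted band power and a direct correspondence
with the pipeline's FFT features (the expected clip periodogram *is* the
target spectrum, which the fidelity test exploits). Preictal clips multiply
power by a configured factor on configured narrow frequency intervals and
channel subsets; a `variance_only` flag instead draws a mean-one lognormal
per-clip factor (log-s.d. `log(factor)/2`), leaving expected power equal but
inflating across-clip spread — the structure VAR's objective targets.

Conditions were fixed a priori to mirror the study setting: 400 Hz dog-like
sampling, six-clip one-hour sequences, default imbalance 2 preictal vs 27
interictal sequences (93.1% interictal), clip-level log-amplitude gain
jitter with s.d. 0.2 emulating electrode/state nonstationarity, and one
planted effect of factor 4 on 38–42 Hz — a 4 Hz sliver occupying a tenth of
the low-gamma band, exactly the situation where uniform averaging dilutes
and supervised weighting should win. The gain jitter matters: without it,
even a diluted mean shift is detectable from a single window and the PBF
baseline saturates; with it, clip-level amplitude variation dominates the
uniform band average while a concentrated filter retains a usable
signal-to-noise ratio.

What the generator does *not* emulate: seizure morphology, spikes and
artifacts, inter-channel correlation beyond shared effects, nonstationarity
within a clip, and electrode drift. Passing tests therefore demonstrate that
the estimators recover planted spectral structure and that the pipeline's
ordering of methods behaves as claimed under controlled conditions — not
that any particular AUC level transfers to real iEEG.

## Problem sizes used in the checks

The benchmark preset (`synth_config_small()`) uses 8 channels, 120 s clips
(3 windows each under the 60/30 spec), 2 preictal + 6 interictal sequences,
holding out the last preictal sequence and every third interictal sequence;
20 generator seeds are averaged per method, with power iteration run at
`tol = 1e-6`, `max_iter = 60` — past the point where the planted-direction
eigengap has converged, trading the last digits of eigenvector accuracy for
wall-clock time. The planted-band recovery check keeps the full 600 s clips
(19 windows each) so the moment estimates are dominated by structure rather
than sampling noise. DeLong calibration uses 2000 replicates of two
correlated scorers sharing a latent trait (25 positives, 35 negatives).

## A note on the recovery ceiling

Because the DS objective uses *uncentered* second moments of log-compressed
magnitudes, its leading eigenvector mixes the planted direction with the
spectral mean profile: the cross term $\delta\mu(p\mathbf 1^\top+\mathbf 1p^\top)$
above bounds the fraction of squared weight that can sit on the planted bins
at roughly $1/(1+(d/k-1)/R^2)$ with $R=\sqrt{d/k}+1+\delta/2\mu$ — about
0.6–0.7 for a 4 Hz plant inside low gamma ($k/d \approx 0.1$) at realistic
log-magnitude levels, even with noiseless moments. The recovery score
reported by the acceptance machinery should be read against that ceiling:
well above the shuffled-label control and the uniform baseline $k/d$, but
structurally below 1. Centering the features before DS would remove the
coupling, but would change the estimator into VAR's covariance difference —
DS is, by construction, the uncentered simplification, so the package keeps
it faithful rather than "fixing" it.

# Known limitations

* The MAT v5 support is deliberately minimal (numeric/char/cell/struct,
  zlib-compressed elements); exotic MAT constructs (sparse, objects, v7.3
  HDF5) are out of scope.
* Supervised filters assume two classes; multi-class extensions and
  shrinkage/regularized covariance variants are not implemented.
* The KNN stage loads all training window features in memory; for contest
  scale data that is a few thousand windows by a few hundred features, well
  within reach, but no out-of-core path exists.
* AUC levels on synthetic data depend on the planted conditions and are not
  comparable to published contest figures, which require the gated dataset.
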