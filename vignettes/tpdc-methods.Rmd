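---
title: "Directed reading-network connectivity from fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed reading-network connectivity from fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpdc)
```

## Scope

`tpdc` implements an analysis chain for resting-state functional
near-infrared spectroscopy (fNIRS) in paediatric cochlear-implant (CI)
cohorts: preprocessing of two-wavelength light intensities into
region-of-interest (ROI) haemoglobin series, estimation of directed
functional connectivity among seven reading-network regions (IFG, STG, MTG,
FFG, SMG, IPL, ANG) by temporal partial directed coherence (TPDC),
bootstrap and time-reversal significance testing, and a cohort-level layer
(PCA of clinical intervention variables, per-connection mediation models
with Benjamini-Hochberg correction, group comparisons, reading
regressions). Because identifiable patient data cannot be shared, the
package ships a synthetic-data module that generates ground-truth
recordings and cohorts with the statistical structure the analysis assumes;
every stage is tested against those known answers.

## Preprocessing model

Light intensities $\Phi_{ij}^{\lambda}(t)$ per source $i$, detector $j$ and
wavelength $\lambda \in \{760, 850\}$ nm are converted to delta optical
density $\Delta OD_{ij}^{\lambda}(t) = \ln[\Phi_{ref} / \Phi_{ij}^{\lambda}(t)]$.
The reference is the channel's temporal mean by default — robust to startup
transients — with the literal first sample available by option.

Motion artifacts are handled in two stages. Detection flags samples where
the moving standard deviation of the channel's fast component (signal minus
a running median) exceeds 13.5 reference SDs, where its pointwise amplitude
exceeds 5 reference SDs, or where the first difference jumps by more than 5
reference SDs (the derivative criterion is what catches baseline steps,
which a running median silently follows). The reference SD is a MAD-based
robust scale floored at 10% of the channel SD so that smooth high-amplitude
physiology is never flagged. Correction first measures each flagged
segment's net level change against its largest internal jump — a step
artifact changes the level by about its single jump, while a spike returns
to baseline — and removes step offsets from everything after the segment;
flagged samples are then replaced by a smoothing-spline prediction from the
surrounding clean data. We found the obvious alternative (refitting the
segment itself and rejoining on mean levels) fails in two ways: a smoothing
spline of the segment keeps sharp spikes in its residual, and mean-level
rejoining turns detector false alarms into a random walk of the baseline.

The wavelet stage decomposes each channel with a periodized orthogonal
discrete wavelet transform (db2, 4 levels by default; exact reconstruction
is asserted in tests) and zeroes detail coefficients whose standardized
magnitude lies in the outer $\alpha = 0.1$ tail of a Gaussian fit
(median/MAD location and scale). Note that this rule removes about 44% of
the detail energy of *Gaussian* data; it is appropriate for haemodynamic
signals precisely because they carry little genuine energy at detail-band
frequencies (above about 0.24 Hz at the default sampling rate), so what it
removes is artifact and noise.

The modified Beer-Lambert law converts the two-wavelength $\Delta OD$ of a
source-detector pair into oxy/deoxyhaemoglobin (HbO/HbR) concentration
changes (µM) through a $2 \times 2$ extinction-coefficient inversion scaled
by the source-detector distance (3 cm default) and the age-dependent
differential path length factor $DPF(a) = 4.99 + 0.067\,a^{0.814}$, so
$DPF(0) = 4.99$ exactly. Extinction coefficients are the Gratzer/Prahl
compilation values shipped as a versioned CSV; any table with the same
columns can be substituted.

Channels are then linearly detrended and zero-centred (no band-pass
filtering anywhere in the pipeline, which avoids filter-induced spurious
connectivity), the shared systemic component is regressed out, and the 40
network channels are pooled into 7 ROIs per hemisphere (8/6/8/6/4/4/4
channels for IFG/STG/MTG/FFG/SMG/IPL/ANG) by plain averaging.

**Systemic regression.** The montage has no short-separation channels, so
the nonneural (systemic) component must be estimated spatially. The naive
estimate — the cross-channel mean — provably leaks the focal neural signal:
40 of 122 channels share the 7 ROI latents, so the mean is partly neural,
and regressing it out removes a common latent mode from every channel. The
package therefore estimates the regressor from the montage channels
*outside* the ROI map when at least 8 exist (they sample scalp systemics
but no network signal, the closest analogue of short-channel regression);
otherwise it falls back to a robust cross-channel median, with the plain
mean available by option. Residuals are exactly orthogonal to the
regressor.

## Time-varying MVAR and TPDC

The ROI series $x(t)$ is modelled as a time-varying multivariate
autoregression
$$x(t) = \sum_{r=1}^{P} a_r(t)\, x(t-r) + \eta(t),$$
with zero-mean Gaussian innovations. The model order is selected by
Schwarz's Bayesian criterion over stationary least-squares fits on a common
effective sample (ARFIT-style), and per-channel augmented Dickey-Fuller
tests (hand-implemented against MacKinnon response-surface critical values)
warn — but do not abort — on channels that fail to reject a unit root.

Coefficients are tracked by a dual estimator of two coupled
predictor-corrector (Kalman) filters: a state filter predicts each sample
from the current coefficient estimates and corrects it against the
observation, and a weight filter treats the stacked coefficients as a
random walk measured through the state filter's lagged estimates.
Hyperparameters, all explicit and logged: coefficient process-noise
variance $10^{-4}$; observation noise set to the innovation variance of the
stationary least-squares fit; initial weight covariance $0.01 I$; burn-in
$10 P$ samples.

**Initialisation.** The weight filter starts at the stationary
least-squares solution rather than at zero. This matters: haemodynamic-band
series are slow (near-unit-root) and cross-correlated, so within the
filter's effective memory the regressor process is nearly rank-deficient,
and a cold-started filter with nonzero process noise demonstrably never
finishes converging inside a seven-minute recording. Warm-starting makes
the filter a tracker of time variation *around* the stationary solution —
which is also the regime in which its time-averages agree with least
squares (asserted within $\pm 0.05$ per coefficient in the tests) while a
planted coefficient step of 0.6 is still tracked within a few hundred
samples. A cold start remains available (`coef_init = "zero"`).

From $a_r(t)$ the partial directed coherence at frequency $\lambda$ is
$$\bar{A}(\lambda, t) = I - \sum_{r=1}^{P} a_r(t) e^{-i 2\pi \lambda r / f_s},
\qquad
|\pi_{i \leftarrow j}(\lambda, t)| =
\frac{|\bar{A}_{ij}(\lambda, t)|}{\sqrt{\sum_k |\bar{A}_{kj}(\lambda, t)|^2}},$$
so $\sum_i |\pi_{i \leftarrow j}|^2 = 1$ for every source column at every
frequency and time (asserted to $10^{-6}$). The square root in the
denominator is the standard PDC normalization consistent with
$0 \le |\pi|^2 \le 1$. The spectrum is evaluated on 64 evenly spaced
frequencies spanning $(0, f_s/2]$ and averaged over the grid points inside
the neurovascular band 0.009-0.08 Hz — band restriction by averaging, never
by pre-filtering — and over all post-burn-in time points, yielding a
directed $7 \times 7$ matrix per hemisphere. Left and right hemispheres are
averaged at the matrix level by default (preserving within-hemisphere
dynamics; series-level averaging is available), giving 42 ordered
connections per subject.

## Significance: windowed-shuffle bootstrap and time reversal

The null distribution for each connection comes from cutting the series of
length $N$ into $K = 20$ nonoverlapping windows of length $V$ ($N = KV$;
trailing samples are dropped with a log message), randomly permuting each
channel's window order *independently* — which destroys cross-channel
coupling while preserving each channel's within-window autocorrelation —
refitting a stationary MVAR to the shuffled series, and recomputing the
band-averaged PDC. One fit per iteration yields null values for all 42
connections, equivalent to running the per-connection shuffle separately.
The threshold is the 99th percentile of 1000 iterations (both
configurable; short runs widen the Monte-Carlo tolerance, e.g. the
effective null exceedance rate with 500 iterations is about 1.2% rather
than 1.0% because the percentile is estimated from finitely many draws).
Crucially, the *same* statistic function is applied to the observed series
and to every surrogate, so under the null the declared-significant rate
matches the nominal tail mass by exchangeability; the stationary statistic
is the default (matching the stationary refit used for the surrogates),
with the full dual-EKF statistic available.

Bootstrap-significant connections then face a time-reversal test. A
genuinely lagged interaction inverts its net direction when the time axis
is reversed, while instantaneous mixing artifacts (common input, volume
conduction) are direction-symmetric in both orientations. The decision
statistic for $j \to i$ is the change in directional asymmetry,
$D = (f_{ij} - f_{ji}) - (r_{ij} - r_{ji})$, with $f$ and $r$ the forward
and reversed matrices. Its null spread comes from time-symmetrized
surrogates: windows are jointly permuted and each window is time-reversed
with probability 1/2 (all channels together), preserving the symmetric
cross-correlation that mixing artifacts produce while destroying genuine
directionality. A connection passes when $D$ exceeds the surrogate 95th
percentile. In simulations, planted lagged edges pass in essentially all
runs and common-input artifacts are rejected in about 90%.

## Cohort layer

The ten clinical variables of the CI group (ages at first hearing aid and
implants, deafness durations, inter-implant interval, age at testing, head
size, hearing age) are standardized and eigen-decomposed; components with
eigenvalue above 1 are retained and promax-rotated (a reported *pattern*
matrix implies oblique rotation; varimax and unrotated are options).
Subject scores use the regression method with an eigen-truncated
pseudoinverse so nearly collinear tables still score. Mediation models are
the saturated linear path system $m = a x + e_1$, $y = b m + c' x + e_2$,
estimated by least squares (identical to maximum likelihood here, so the
identity total $=$ direct $+$ indirect holds to machine precision), with a
percentile bootstrap over subjects for the indirect effect $a \cdot b$
(5000 resamples by default). One model is fitted per retained component
$\times$ 42 connections $\times$ 6 RISE subtests, and Benjamini-Hochberg
correction is applied within each component's family of 252 tests. Group
reading comparisons use Welch's t-test and the Mann-Whitney U-test;
reading regressions are ordinary least squares.

## The synthetic-data generator

The generator defines the study conditions the tests assume, and its
defaults were fixed once:

* **Networks and latents.** Seven ROIs with lag-1 directed edges drawn at
  density 0.15 and couplings in 0.3-0.6 (shrunk, if needed, until the MVAR
  companion matrix is stable), each region carrying a slow autoregressive
  pole of 0.98 so that roughly 90% of latent power lies below 0.24 Hz —
  the band-limitation real haemodynamics exhibit, and the condition under
  which the $\alpha = 0.1$ wavelet stage does not erode genuine signal.
  Edges can be constant, ramped or stepped in time.
* **Recordings.** 122 source-detector pairs at 7.8125 Hz (typical
  continuous-wave instrumentation; the analysis never depends on this
  choice), 40 of them mapped to the ROIs. Channel HbO is the unit-variance
  ROI latent scaled to 0.5 µM plus channel noise (0.2 relative), a shared
  low-frequency systemic component and a ~0.1 Hz Mayer-wave oscillation
  (relative amplitudes 0.5 and 0.4, per-channel gain spread ±15%), and
  injected motion spikes (0.3/min at 12 SD) and baseline shifts (0.1/min at
  6 SD). HbR is an anticorrelated scaled copy. The forward Beer-Lambert
  model with the same extinction table produces strictly positive
  two-wavelength intensities, so the preprocessing chain inverts it exactly
  when artifacts are disabled, and recovers the detrended latent with mean
  correlation above 0.95 at default artifact levels.
* **Cohorts.** 50 CI and 25 TH subjects by default. Clinical variables are
  drawn with three latent blocks (primary intervention, secondary
  intervention, development) at within-block loading 0.8, centred on the
  reported demographics (age at first implant 1.98 ± 0.98 y, hearing-aid
  fit 1.00 ± 0.85 y, bilateral implantation 3.42 ± 2.57 y, age at testing
  12.2 ± 2.9 y); derived chart entries carry ~2-week reporting jitter so
  the table is full rank, and hearing age equals age at testing minus the
  age at the first hearing intervention up to that jitter. Connection
  strengths are `mu + a * factor + noise` with per-connection baselines in
  0.2-0.5 (TH baselines 0.15 higher), and reading scores are built as
  `250 + offset + b * m + noise` with the residual variance topped up so
  every subtest has SD 15 on the RISE scale before clamping to
  `[190, 310]`; planted paths too large for that variance raise an error
  rather than silently rescaling. Group offsets (-2.5 CI, +5 TH) cancel at
  the default 2:1 ratio so the grand mean is 250, and TH scores carry a
  +2.5 points/year age slope. Because the source cohort's per-subject
  connectivity distributions are unpublished, all planted effect sizes are
  calibration choices of this generator, not estimates of the real data.

What passing tests do *not* show about real data: the generator's latents
are linear Gaussian MVARs with exactly lag-1 coupling, its systemic
component has homogeneous spatial structure, and its artifacts are
idealized spikes and steps; real fNIRS has nonlinear neurovascular
coupling, spatially structured scalp physiology, and motion artifacts of
mixed morphology. The pipeline's behaviour on such data is supported by
the cited methodology literature, not by these tests.

## Numerical choices and degenerate inputs

Simulation discards a 200-sample burn-in; stability is always verified via
the companion spectral radius. The DWT requires lengths divisible by
$2^{levels}$ and symmetric-extends internally. Constant channels are zeroed
with a warning at the detrending stage; single-channel inputs skip systemic
regression with a warning; an all-zero source column in
$\bar{A}(\lambda)$ raises a normalization error. Bootstrap shuffling
requires at least two windows, and window lengths must exceed ten times the
model order. All stochastic operations take explicit integer seeds, derive
stage seeds deterministically from them, and restore the caller's RNG
state, so identical configurations are bit-reproducible.

Problem sizes used by the test suite (chosen to exercise each property at
comfortable Monte-Carlo resolution): coefficient-recovery checks at
n = 10000, edge-ranking at n = 3000 over 20 network seeds, bootstrap
calibration with 500 iterations over 20 white-noise runs, time-reversal
behaviour over 20 seeds at n = 2000, mediation recovery over 50 seeds at
n = 500, and cohort scaling at 5000 subjects.

## Known limitations

* The dual-EKF tracks slow coefficient drift well but, by design of its
  warm start, attributes as much variation as possible to the stationary
  component; abrupt regime changes shorter than a few hundred samples are
  smoothed.
* PDC's column normalization makes source columns with no outgoing
  influence sensitive to estimation noise (the column norm is then small);
  the bootstrap threshold absorbs this per connection, but raw TPDC
  magnitudes should not be compared across source regions.
* The mediation layer is the saturated single-mediator linear path model;
  it does not fit latent-variable structural models, covariates are off by
  default, and indirect-effect detection through a 252-test BH family
  requires effects considerably stronger than the per-model detection
  threshold.
* SNIRF (HDF5) I/O is not included; recordings exchange as long-format CSV
  with a JSON metadata sidecar.
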