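---
title: "Time-domain smoothing for in-line NIR moisture monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-domain smoothing for in-line NIR moisture monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procspec)
```

## The measurement problem

In-line diffuse-reflectance NIR spectra of a fluidized-bed drying process
(lg(1/R) units, a fixed wavelength grid, one spectrum every few seconds)
carry the moisture signal through two channels at once: the water
absorption bands around 1440 and 1930 nm, and a *wavelength-flat*
background component proportional to moisture — the refractive or
"watermark" effect, caused by water on particle surfaces deepening the
light penetration into the powder bed. The same flat signature is shared
by the turbulence-driven *scatter effect*, a stochastic whole-spectrum
intensity fluctuation with no chemical meaning.

Scatter-corrective preprocessing (MSC, SNV, derivatives) is designed to
remove exactly that flat/multiplicative family of variation. When the flat
component is informative, as here, scatter correction throws the
information away. The alternative implemented by this package is a moving
average applied to each spectral variable **along the time axis**: noise
that is white in time averages out, while every wavelength keeps its own
systematic trajectory, flat background included.

## The smoother

For an odd window width $k$, each element $x_{ij}$ of the time x
wavelength matrix is replaced by the centered mean of the $k$ surrounding
points of variable $j$. The $(k-1)/2$ points nearest either end of the
series are smoothed with a *reduced symmetric window* of $(l-1)\cdot 2+1$
points, where $l$ is the ordinal from the nearer end — so the first and
last points pass through unchanged, the second uses a 3-point window, and
so on. This reading keeps every window centered (no phase shift), and it
is the only symmetric interpretation of a "reduced window" at the ends;
it is verified in the tests against a literal loop implementation.

Two properties matter operationally:

* **Delay.** A centered window can only be emitted once its trailing half
  has been acquired: the in-line delay is $(k-1)/2 \cdot dt$ and the full
  window spans $(k-1)\,dt$ of process time. For $k = 15$ at 5-s
  acquisition that is a 35-s delay and a 70-s span — about one material
  circulation period in a typical dryer, which is also why windows of this
  order are physically sensible: the average approximates a bulk sample
  rather than whatever happened to pass the probe window.
* **Batch boundaries.** Smoothing is always per batch; batches are
  separate physical processes and are never mixed
  (`pairCampaign()` applies the smoother batch-wise before pairing).

A note on the delay arithmetic: for a centered window of $k$ points the
delay is $(k-1)/2$ points — 7 points, i.e. 35 s, for $k=15$ at 5 s — and
the package reports exactly that.

## Pairing, validation, and leakage

Reference LOD samples are paired with the spectrum nearest in time
(ties broken toward the *earlier* spectrum: that datum was already
observed, the later one not yet). Pairing distances above a configurable
`maxGap` (default 60 s, about 12 acquisition steps) raise a warning.

Three validation schemes are provided: leave-one-sample-out CV,
leave-a-batch-out CV (folds are whole batches; for batch processes this is
the conservative, honest scheme), and validation by a preselected external
batch set. Preprocessing placement follows one rule: operations that learn
parameters from samples (the MSC reference spectrum) are re-estimated
inside every training fold; the time smoother is a per-batch stream
operation that uses no reference values, so it is applied once, before
pairing, and cannot leak across folds.

$R^2$ for any scheme is computed against the evaluated set's own mean
(the plain coefficient-of-determination definition); this choice is
documented because other conventions (calibration-mean $SS_{tot}$) exist.

## PLS, PCA and their numerics

The regression core is PLS1 by NIPALS with mean centering and no variance
scaling (autoscaling spectra that share one unit is nonstandard and would
inflate noise channels). Weights, loadings and y-loadings are stored per
component; the regression vector for $a$ components is
$W_a (P_a' W_a)^{-1} q_a$, so a single fit serves every model size up to
$A$ — the latent-variable scan truncates per fold instead of refitting.
For one response the NIPALS inner loop is a single analytic step, so no
iteration tolerance is needed; degenerate components are detected by
comparing the weight and score norms against the *original* centered data
scale (relative thresholds of $10^{-24}$ on squared norms), which
distinguishes "response fully explained" and "rank exhausted" from merely
small components. At full rank PLS predictions coincide with ordinary
least squares; the tests assert this against `lm()` and a brute-force
NIPALS oracle.

PCA is computed by SVD (via `prcomp`) on column-centered data. Component
signs are fixed deterministically — the loading element of largest
magnitude is made positive — so scores, loadings and downstream plots are
reproducible. Explained variances are reported relative to total centered
variance. PCA of *augmented* data (several batches stacked on a common
wavelength grid, centered by the grand column means) places all batch
trajectories in one factor space; `scoresVsTime()` exports per-batch score
trajectories for plotting.

## Window scan and dynamic focusing

`windowScan()` evaluates the full pipeline for every odd $k$ in a range
(the default 3–101 gives exactly 50 candidates) and selects the *smallest*
$k$ within a 2 % relative RMSE tolerance of the minimum. The asymmetric
rule encodes the operational preference for light smoothing: RMSE flattens
with growing $k$ while the reporting delay keeps increasing linearly.

Prediction error depends strongly on the moisture level, so per-range
models (`< 20 %`, `< 15 %`, `< 10 %`, built by strict `lod < threshold`
restriction of the training data) are combined into a `ModelCascade`.
During monitoring the active model switches one stage drier once the
*prediction* (no reference is available in-line) has stayed below the next
threshold for `debounce = 3` consecutive points. The debounce guards
against single-point noise dips at a threshold; switching is one-way
because drying is monotone and a brief excursion back above a threshold
does not make the wetter-range model preferable again. All stages share
one smoother width and, by default, one latent-variable count — exposing
per-stage $A$ would be trivial, but the default mirrors the common
practice of a single validated model complexity across ranges.

At the start of a stream the reduced end-windows are exactly the causal
windows available (only $l-1$ future points are needed at ordinal $l$), so
the offline smoother and the streaming monitor produce identical values;
each point is emitted at `time + (k-1)/2 * dt`, reported in the
`availableAt` column.

## The synthetic campaign generator

No industrial drying campaign is publicly available at the geometry this
methodology targets, so the package ships a generator whose defaults
emulate the study conditions end to end: 256 channels linear over
1091.8–2106.5 nm (the source instrument's grid; whether the physical grid
was exactly linear is unknown, a linear grid is assumed), 5-s acquisition,
396–1213 spectra per batch, 25-batch campaigns with 8 validation batches,
5–26 reference samples per batch, and reference noise SD 0.06 % — the
reproducibility of typical halogen LOD analyzers.

The generative model per batch:

* moisture $m(t) = m_{end} + (m_0 - m_{end}) e^{-t/\tau}$, with
  $m_0 \in [24.5, 26.5]$, $m_{end} \in [2.2, 3.0]$ and
  $\tau \in [600, 1500]$ s drawn per batch (reference LODs then span
  roughly 2.4–26 %, and each batch differs as real runs do). A single
  exponential is the simplest monotone trajectory with a time constant;
  constant-rate drying phases are deliberately not modelled.
* clean spectrum $A_0(\lambda, t) = b(\lambda) + \alpha\, m(t) +
  m(t) \sum_b A_b e^{-(\lambda-c_b)^2 / 2w_b^2}$: a fixed smooth baseline,
  the wavelength-flat watermark term ($\alpha = 0.006$ lg(1/R) per % LOD),
  and Gaussian water bands at 1440 nm ($A=0.004$, $w=35$ nm) and 1930 nm
  ($A=0.012$, $w=50$ nm; the long-wave band about three times stronger).
* observation $A = f_t A_0 + o_t + \varepsilon$ with
  $f_t \sim \mathrm{lognormal}(0, \sigma_f = 0.05)$ (positive
  multiplicative scatter), $o_t \sim N(0, \sigma_o = 0.02)$ and iid
  channel noise $\sigma_\varepsilon = 5\times10^{-4}$.

The scatter is modelled as multiplicative-plus-offset *in absorbance
units* on purpose: MSC and SNV are exactly the corrections for that
family, so the comparison between time smoothing and scatter correction is
as favorable to the latter as the mechanism allows. $\sigma_f$ and
$\sigma_o$ are not recoverable from published figures; they were fixed
once so that the wavelength-wise correlation of raw intensity with
moisture bottoms out around 0.8 in a typical batch and exceeds 0.95 after
47-point smoothing, the qualitative signature reported for real campaigns.
Probe-fouling spikes are not generated (fouling was reported to have a
minor effect); particle-size dynamics and radiative-transfer physics are
out of scope.

What passing on this generator does and does not show: it demonstrates
that the pipeline *mechanically* reproduces the phenomenon — scatter
correction destroys flat moisture information that time smoothing
preserves, leave-a-batch-out errors fall when ranges are restricted, the
cascade walks its stages — under a data-generating process built to
contain those effects. It cannot certify accuracy figures for any real
dryer; real spectra contain chemistry, nonlinearities and event artifacts
the generator omits.

## Problem sizes used by the test and acceptance runs

The simulation-backed checks run on *desk-scale* campaigns: 25 batches of
150–300 spectra with the drying time constant scaled in proportion
($\tau \in [180, 420]$ s), preserving the duration/$\tau$ ratio (≈3.8) of
the full-scale defaults and hence the trajectory shape and the share of
dry-range samples. Structural conclusions (error orderings, stage
behaviour, scan contracts) are scale-invariant in this design; absolute
RMSE values naturally depend on the scale and are reported as computed.

## Known limitations

* PLS1 only (single response); no PLS2, kernel or sparse variants.
* No automatic outlier detection for reference samples — a manual
  `excluded` flag is honored instead, because outlier rejection rules are
  process-specific.
* The Savitzky–Golay derivative is expressed per channel index, not per
  nm; on the linear grids used here the two differ by a constant factor.
* Wide-CSV is the only on-disk spectra format (vendor formats such as
  JCAMP-DX are out of scope); manifests are plain YAML.
* The cascade's switching uses predictions, so a grossly miscalibrated
  full-range model can switch early or late; the debounce mitigates noise,
  not bias.
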