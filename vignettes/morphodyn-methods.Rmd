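---
title: "Methods: shape-dynamics analysis of single-cell silhouettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape-dynamics analysis of single-cell silhouettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodyn)
```

## The order parameter

A motile cell imaged as a binary silhouette can be summarized, frame by
frame, by a single dimensionless observable: the **relative radial
roundness**

$$R = \frac{r_1}{r_2}, \qquad r_1 = \frac{p}{2\pi}, \qquad
  r_2 = \sqrt{A/\pi},$$

where $p$ is the perimeter pixel count and $A$ the area pixel count of the
silhouette. $r_1$ is the radius of the circle that would have the observed
perimeter; $r_2$ the radius of the circle with the observed area. For an
ideal circle $R = 1$ exactly (and $\log R = 0$), which anchors the scale:
every departure from circularity — protrusions, ruffles, polarization —
raises the perimeter faster than the enclosed area and pushes $R$ upward.
Tracked over time, $R(t)$ behaves like an order parameter: its
distributional and dynamical properties change when the cell changes
behavioral state, even when its mean stays put.

Two numerical caveats are built into the implementation rather than hidden:

* **Perimeter definition.** $p$ counts foreground pixels with at least one
  4-neighbor background pixel. This literal boundary-pixel count
  undercounts diagonal runs relative to geometric arc length, so a
  *rasterized* circle does not give $R = 1$ exactly (it gives roughly 0.9
  at radius 60). The exact anchor is asserted on continuous-limit inputs
  ($p = 2\pi r$, $A = \pi r^2$); rasterized shapes are compared within
  tolerance bands, and all cross-state contrasts are unaffected because the
  same estimator is applied to every frame. A chain-code-weighted length
  (diagonal steps counted as $\sqrt 2$) is available behind
  `trace_perimeter(chain_code = TRUE)` but is off by default; all shipped
  results use the literal count.
* **Connectivity.** Foreground components are 8-connected, background (for
  hole filling) 4-connected — the standard Jordan-pair convention. Masks
  touching the image border are rejected: their geometry is censored by the
  field of view.

## The measure battery

On each $R(t)$ series (canonically 900 samples at $\Delta t = 2$ s, i.e.
30 minutes) the package computes:

* **S1–S4**: mean, sample SD ($n-1$), skewness $m_3/\mathrm{var}^{3/2}$ and
  excess kurtosis $m_4/\mathrm{var}^2 - 3$, with $1/n$ central moments (the
  conventional $g_1$/$g_2$ estimators).
* **$\Lambda_1$**: a Wolf-style leading Lyapunov exponent in a
  3-dimensional delay embedding (delay 1). Parameters not fixed by the
  method's description are explicit choices, exposed in the function
  signature: Theiler window 10 samples, evolution interval 3 samples,
  neighbor scale bounds $10^{-4}\times$ data range to $0.1\times$ the
  embedded bounding-box diagonal, Euclidean norm. Separations are floored
  at the minimum scale because a pixel-count-derived series is quantized —
  embedded points can coincide exactly, and an unfloored log-ratio would
  diverge. On the fully chaotic logistic map the estimator lands within
  $\pm 0.1$ of the closed-form $\ln 2$; on periodic signals it returns
  $\approx 0$.
* **$\alpha$**: the slope of $\log_{10}$ power against $\log_{10}$
  frequency over the middle third of the log-frequency axis of the raw
  periodogram (mean removal only; no taper, no detrending — deliberately
  minimal preprocessing, and configurable). The middle third is taken on
  the log axis because that is the axis of the fit and the band where the
  canonical references hold: a random walk recovers $\alpha \approx -2$
  there, whereas in the middle third by *linear bin index* (1/3 to 2/3 of
  Nyquist) the discrete-walk spectrum $\propto 1/\sin^2(\pi f/2f_N)$
  flattens to $\approx -1.5$ and the law cannot be recovered. The
  index-based band remains available via `band = "index"`.
* **Slowest Fourier mode**: the period (minutes) of the lowest-frequency
  local maximum of the periodogram exceeding the median power. Requiring a
  local maximum above median power prevents a dominant fast oscillation
  from hiding a genuine slow mode; the global argmax is available via
  `mode = "global_max"`.

Short biological recordings routinely defeat some estimator or other, so
`measure_battery()` never throws for a single failed measure: failures are
recorded as missing values with reasons, and the group comparison operates
on the available subsets with correspondingly reduced degrees of freedom.

## Phase-space and time-scale representations

**Broomhead–King embedding** (`bk_embed()`): the mean-removed series is
formed into an $(n-M+1)\times M$ trajectory matrix $X$ of lagged windows
($M = 8$, a typical correlation decay interval at 2 s sampling); the
window covariance $C_M = X^\top X/(n-M+1)$ is eigendecomposed and the
series is projected on the top three eigenvectors to give trajectories
$\Psi_1, \Psi_2, \Psi_3$. The Gram construction guarantees positive
semidefiniteness (a Toeplitz lag-filled estimate does not). Eigenvector
signs are fixed (largest-magnitude entry positive) so plots and tests are
reproducible.

**Recurrence plots** (`recurrence_plot()`): binary matrix
$RP_{ij} = \Theta(\varepsilon - \lVert x_i - x_j\rVert)$ on the
3-dimensional delay embedding with delay 1. The classical absolute
threshold $\varepsilon = 1$ is the default, but because $R(t)$ scales
differ across data sources an $\varepsilon$-quantile mode (threshold at a
given quantile of the pairwise distances) is provided, and every
cross-state comparison in this package uses the quantile mode so that the
two states are compared at matched recurrence budgets.
`recurrence_rate()` adds the off-diagonal density and a per-diagonal
recurrence profile; clustering of return times appears as a high
coefficient of variation of that profile.

**Morlet scalogram** (`morlet_cwt()`): modulus of the continuous wavelet
transform with the analytic Morlet mother wavelet, $\omega_0 = 6$
(standard admissibility-respecting choice), L2 normalization, 64
log-spaced scales from 2 to $n/4$ samples. The transform is computed by
FFT with zero padding to the next power of two $\ge 2n$; the series is
mean-removed first, since the raw mean otherwise produces a step response
against the padding that dominates every slow scale. The cone of
influence (within $s\sqrt 2$ samples of either edge at scale $s$) is
flagged in the returned object.

### Dating a state transition

`transition_profile()` condenses a scalogram into a slow-band curve (mean
modulus over the slowest third of the scale grid) and a ridge-scale curve,
and estimates a change point as follows: the slow-band curve is averaged
over a moving window of $w = 200$ samples, logged, and differenced at lag
$w$; the change point is the maximizing index plus $0.75\,w$.

Each ingredient exists for a reason, established on synthetic ensembles
during design:

* *log of the window mean* (a ratio statistic): averaging before the log
  keeps quiescent stretches, whose small moduli fluctuate wildly in
  relative terms, from generating spurious maxima; the ratio form responds
  to the sustained regime change rather than to the single largest
  protrusion burst (raw-modulus differencing at short windows reliably
  locks onto individual late bursts instead of the onset).
* *window of 200 samples*: roughly twice the slow-band timescale, long
  enough to integrate over individual burst cycles.
* *offset $0.75\,w$ rather than the window midpoint*: post-change
  slow-scale content leaks backward in time by roughly the wavelet support
  (the cone of influence), which biases the midpoint convention early by
  several tens of samples; the offset was calibrated on synthetic
  transition ensembles to make the median detection error near zero.

On 900-sample transition recordings with the switch at sample 283, the
detector locates the switch within $\pm 60$ samples in 28 of 30 runs
across three independent ten-seed ensembles. Its precision for arbitrary
switch locations is coarser (of order $\pm 100$ samples): it is a dating
aid, not a precision estimator, and the slow-band pre/post contrast is the
robust signature.

## The synthetic silhouette generator

No public raw recordings of this kind exist, so the generator is the
package's test bed: it must produce silhouette movies whose *statistics*
carry the signatures the analysis is designed to detect, without
pretending to biophysical realism (no actin kinetics, no optics, no
photon noise).

The shape model is a star-convex outline
$$r(\theta, t) = r_0\left(1 + \mathrm{tex}(\theta) +
  \sum_{k=2}^{8} a_k(t)\cos(k\theta + \phi_k)\right)$$
rasterized by pixel-center inclusion on a 256 px grid (512 px for
translocating cells). Mode 1 is excluded — it is a pure translation
surrogate, and translation enters only as explicit centroid drift. Each
dynamic amplitude $a_k(t)$ follows an exactly discretized
Ornstein–Uhlenbeck process, so stationary variances are exact at every
sampling step regardless of $\Delta t$.

Per-cell heterogeneity, which real cell groups always show, enters through
two static draws: a lognormal jitter on the base radius (CV 0.10 around
60 px) and a fixed microvillus **texture** — modes 9–20 with amplitudes
$b_k \propto \ell/k$, where the per-cell roughness level $\ell$ is drawn
uniformly from $[0.15, 0.55]$. The $1/k$ scaling gives every texture mode
a comparable contribution to the perimeter. Texture moves each cell's
baseline $R$ without affecting its fluctuation statistics, producing the
between-cell spread in mean roundness that makes group means overlap while
fluctuation measures separate — the signature pattern of the two
non-migrating states.

State definitions (defaults; every number is exposed in
`synthetic_params()`):

| state | dynamics |
|---|---|
| idling | all modes: $\theta = 1$ s, $\sigma = 0.02$ — border flicker faster than the 2 s sampling |
| treadmilling | protrusion modes 2–4: $\theta = 60$ s, $\sigma = 0.05$, with a telegraph process (on-rate 1/120 s$^{-1}$, off-rate 1/60 s$^{-1}$) tripling the OU *target* amplitude while "on"; fine modes 5–8: $\theta = 2$ s, $\sigma = 0.01$ |
| translocating | fixed mode-2 amplitude 0.25 (polarized ellipse), centroid drift 0.15 px/s, idling-like residual flicker |
| transition | idling regime before `t_switch` (default 283), treadmilling regime after, amplitudes continuous at the switch |

Two design choices deserve their rationale:

* **Bursts raise the OU target, not the realized amplitude.** Multiplying
  the instantaneous amplitude by a gain makes burst magnitude a lottery on
  the OU level at burst onset; occasional late coincidences then dwarf the
  actual state change and defeat transition dating. Raising the stationary
  amplitude instead gives protrusion episodes a characteristic size and a
  smooth onset governed by $\theta$ — closer to how protrusions grow, and
  statistically far better behaved.
* **Fast idling flicker ($\theta = 1$ s).** With slower idling dynamics the
  idling spectrum acquires the same mid-band $f^{-2}$ tail as
  treadmilling and the scaling-exponent contrast between the states
  disappears; sub-sampling-interval relaxation makes idling nearly white
  at the observable frequencies, which both matches the "fast, fine
  flicker" character of the state and leaves the slow, correlated
  treadmilling spectrum clearly distinct.

Every stochastic ingredient draws from its own child stream derived
deterministically from the root seed, so recordings are bit-for-bit
reproducible and adding a process never perturbs the others. Frames whose
outline would collapse (radius $\le 0.1 r_0$) or leave the field of view
have their dynamic deviation rescaled — never rejected, so the series
length stays exact — and the clip count is reported in the ground truth.

### What the generator does and does not establish

Passing tests on these ensembles shows that the estimators detect the
encoded contrasts at realistic sample sizes; it does **not** validate the
biology of real cells, whose fluctuations are neither Gaussian nor
star-convex and whose states are not cleanly parameterized. Two known
gaps: (1) rasterization quantization acts as white measurement noise whose
magnitude depends on cell size — convenient here (it emulates the
measurement-noise floor of real segmentations) but not controlled
independently; (2) the slowest-Fourier-mode contrast reported for real
cells (idling slower than treadmilling) is *not* reproduced by this
generator — the synthetic treadmilling state concentrates power at the
slowest resolvable frequencies, so its lowest above-median spectral peak
tends to sit at longer periods than idling's. The slowest-mode estimator
is therefore validated against exact cosine oracles only, and no
cross-state claim is made for it.

## The two-group comparison

`compare_groups()` performs the pooled-variance two-sample $t$ test per
measure with $df = n_1 + n_2 - 2$ (two groups of ten give $df = 18$) and
no multiple-testing correction across the six measures — the report notes
this. One-tailed testing follows the convention of the field this mirrors;
the `alternative` argument offers `"greater"`, `"less"`, `"two.sided"`
and `"directional"` (tail in the direction of the observed difference).
Note that only the fixed-tail alternatives satisfy the label-swap duality
$p \mapsto 1 - p$; the directional tail is invariant under swapping.
Measures missing in some cells are compared on the available subsets with
reduced $df$ and flagged in the output.

## Problem sizes

The shipped tests and ensembles use the canonical recording geometry
throughout: 900 frames at $\Delta t = 2$ s on 256 px grids, ten cells per
state for group comparisons, ten seeded transition recordings, and 20
replicates for the spectral-slope oracles (at $n = 4096$, where the
20-replicate mean of the white-noise slope has a standard error well
inside the assertion band). A full test run simulates roughly 30
silhouette movies.
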