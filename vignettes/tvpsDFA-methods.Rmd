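---
title: "Measuring long-range temporal correlations of time-varying phase synchrony"
author: "tvpsDFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring long-range temporal correlations of time-varying phase synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvpsDFA)
```

## The measurement problem

Phase synchrony between two narrow-band neural signals is usually
summarized by a single coupling number. This package instead treats
synchrony as a *process*: the instantaneous rate of change of the
unwrapped phase difference (the TV-PS series) is a bounded time series
whose temporal structure can be quantified. If that structure is
scale-free — its detrended fluctuations grow as a power of the window
length — the synchrony dynamics show long-range temporal correlations
(LRTCs), a signature of systems operating near criticality. The DFA
exponent $\alpha$ summarizes the structure: $\alpha = 0.5$ for an
uncorrelated process, $0.5 < \alpha < 1$ for persistent LRTCs.

The chain is: band-pass filter each region's source signal, extract and
unwrap the Hilbert phase, difference two regions' phases, differentiate,
run DFA, validate the scale-invariance assumption with model selection
(ML-DFA), and finally compare the subject-by-edge exponent matrices
between groups with the network-based statistic (NBS).

## Band filtering

Six canonical bands are fixed (`bandDefinitions()`): delta 2–4, theta
4–8, alpha 8–13, beta 14–30, low-gamma 30–55, high-gamma 65–80 Hz. FIR
orders follow the three-cycles rule, $\lceil 3 f_s / f_{\mathrm{low}}
\rceil$ samples, so a filter always spans three cycles of the slowest
component it must pass — 375, 188, 94, 54, 25 and 12 samples at
$f_s = 250$ Hz. Ceiling rounding is the unique convention consistent
with all of those printed orders (187.5 → 188, 11.54 → 12).

Two choices are ours:

* **Zero-phase application** (forward–backward filtering). Phase
  analysis cannot tolerate a frequency-dependent group delay, and
  zero-phase FIR filtering is standard EEG practice.
* **Transition bands anchored outside the pass band.** A Hamming-window
  FIR of order $N$ has a transition width of roughly $3.3 f_s / N$ Hz.
  At the short orders the three-cycles rule produces for high bands,
  placing the −6 dB cutoffs *at* the band edges would erode most of the
  nominal pass band (order 94 at 8–13 Hz gives an 8.8 Hz transition).
  We therefore place the cutoffs half a transition width outside the
  edges, so the nominal band is passed at unit gain and attenuation
  begins at the edges. In-band tones survive within 5%; a 10 Hz tone is
  attenuated by far more than 20 dB by the delta filter.

## Phase extraction and the TV-PS series

The analytic signal is computed by the FFT method (positive frequencies
doubled, negative zeroed); the instantaneous phase is
$\phi(t) = \operatorname{atan2}(X_H(t), X(t))$, wrapped to $[-\pi,\pi]$,
then unwrapped by adding $\pm 2\pi$ at jumps of $\pi$ or more. For a
pair $(a, b)$ the TV-PS series is the first forward difference of
$\Delta\phi(t) = \phi_a(t) - \phi_b(t)$ in radians per sample. Two
conventions:

* **No $f_s$ rescaling of the derivative.** DFA exponents are invariant
  to global scaling, so radians/sample and radians/second give identical
  results; we keep the unscaled difference.
* **Edge trimming.** Both the FIR filter and the FFT Hilbert transform
  distort the series ends. By default one filter order is discarded at
  each end of the phase-difference series before differencing
  (configurable via `edgeTrim`).

The cumulative sum of the TV-PS values plus the initial phase difference
reconstructs the unwrapped phase difference exactly; this identity is
enforced by tests to machine precision.

## DFA

The profile is the cumulative sum of the *mean-removed* series. Plain
cumulative summation of a series with non-zero mean adds a deterministic
ramp that swamps the fluctuation structure; mean removal is the standard
DFA convention and is assumed here.

Windows: `nTau = 15` lengths (a configurable default; the count is a
density choice, not a statistical parameter), equidistant in
$\log_{10}\tau$ between 1 s and 15 s (2 s floor for delta and theta,
whose cycles are too long for 1 s windows), converted to integer sample
counts, deduplicated, each at least 4 samples. Window $k$ of length
$\tau$ starts at sample $\lfloor k\tau/2 \rfloor$ (50% overlap); a
trailing partial window is dropped, and a window length must fit at
least twice. Each window is detrended by its own least-squares line
(DFA-1), and $F(\tau)$ is the mean of the per-window population standard
deviations (divisor $\tau$). The exponent is the OLS slope of
$\log_{10} F$ on $\log_{10} \tau$, reported with the $R^2$ of that fit.
A 20 s maximum window is available through `runConfig(tauMaxS = 20)` as
a sensitivity check. No $R^2$-based exclusion is applied: ML-DFA is the
sole gatekeeper of scale-invariance.

## ML-DFA: validating scale-invariance

A power law in $F(\tau)$ means a straight fluctuation plot. We fit 13
candidate shapes to the $(\log_{10}\tau, \log_{10}F)$ points —
polynomials of degree 1–5, root laws $a + b\,u^{1/k}$ for
$k \in \{2,3,4\}$ (on the abscissa shifted to start at zero, so
fractional powers are defined), an exponential $a + b e^{cu}$, a
logarithm $a + b\ln(x - c)$ with $c$ constrained below $\min x$, and
continuous piecewise-linear splines with 2–4 sections, breakpoints
chosen by exhaustive search over the interior plot abscissae. The
nonlinear parameters $c$ are profiled on a deterministic grid with local
refinement. Scale-invariance is accepted if and only if the line attains
the strictly lowest AIC; ties (within $10^{-9}$) count against
acceptance. Spline parameter counts are their $k + 1$ regression
coefficients.

**The likelihood behind the AIC is a deliberate design decision.** The
obvious choice — Gaussian iid residuals, $\mathrm{AIC} = n\ln(rss/n) +
2k$ — is badly miscalibrated for fluctuation plots: the 15 points are
computed from overlapping windows of one underlying series, so their
deviations from the true power law are smooth and strongly correlated.
Under an iid assumption those wiggles look like structure, and a
flexible model (a spline with a free breakpoint, a cubic) essentially
always wins: on exactly scale-free fractional Gaussian noise the linear
model then wins almost never, which would make the validation step
reject the very signals it is meant to certify. Small-sample AIC
corrections do not repair this.

We therefore score fits by a normalized-curve likelihood: the plot is
mapped onto $[0,1]$ vertically, the data heights (plus an offset of 0.1)
are treated as a probability mass over the window lengths, and a fitted
curve is scored by the cross-entropy of its similarly normalized
heights, scaled by an effective observation count $N_{\mathrm{eff}}$;
$\mathrm{AIC} = 2k - 2 N_{\mathrm{eff}} \sum_i p_i \ln q_i$. This
measures whole-curve *shape* mismatch rather than pointwise residuals,
in the spirit of the normalized-likelihood formulation of the original
ML-DFA literature. $N_{\mathrm{eff}} = 300$ and the 0.1 offset were
fixed once by calibration on reference plots with known truth:
fractional Gaussian noise of length $2^{14}$ (exactly scale-free, H =
0.5 and 0.75) must be accepted in well over 90% of realizations, while
strongly oscillatory series (a sinusoid-modulated synchrony process,
whose characteristic scale bends the plot) must be rejected as reliably.
The behaviour is flat over a broad range around the chosen constants
($N_{\mathrm{eff}}$ 200–500); outside it either acceptance of true power
laws or rejection of crossover shapes degrades.

## NBS group inference

For each band, the subject × edge matrix of DFA exponents is tested for
a group difference with the network-based statistic:

1. Per edge, a GLM with intercept, nuisance covariates (age) and the
   group indicator; the statistic is the partial F test of the group
   column (df 1). For a directional hypothesis, edges whose adjusted
   contrast has the wrong sign are screened out before thresholding.
   Nuisance columns that add no rank (e.g. a constant) are dropped, so a
   degenerate covariate reproduces the no-covariate analysis exactly.
2. Edges with uncorrected $p < 0.005$ form a graph; its connected
   components are scored by extent (edge count) or intensity (sum of F).
   Membership is identical under both size modes by construction.
3. The null distribution of the maximal component size comes from
   random reallocations of subjects to two groups of the original sizes
   (5000 by default). Covariates travel with their subjects — the
   standard GLM label-permutation scheme; the alternative (Freedman–Lane
   residual permutation) is deliberately not used, to keep the scheme
   exactly the simple group reallocation described for this analysis. A
   permutation with no supra-threshold edge contributes a maximal size
   of 0.
4. $p_{\mathrm{FWER}} = (1 + \#\{\text{null} \ge \text{observed}\}) /
   (1 + n_{\mathrm{perm}})$, which includes the observed statistic and
   therefore never reaches 0.

Both one-sided alternatives (group1 > group2 and the reverse) are run as
separate tests per band.

## The synthetic generator

The generator emulates the study design the analysis is meant for: two
groups (default 27 + 25 subjects, mirroring a typical
control-vs-patient cohort), ages drawn uniformly from 5–18 years (no
age effect unless `ageSlope` is set — age then acts purely as a
nuisance covariate), ~5-minute recordings (300 s) at 250 Hz, 84 ROIs.

Each subject's ROI signals are unit-amplitude cosines at the carrier
band's midpoint. All ROIs share a common carrier phase including a slow
random jitter (sd 0.02 rad/sample) — shared components cancel exactly in
phase differences, so the planted structure lives only in the pairwise
relations. Each ROI additionally carries its own phase walk: the
cumulative sum of fractional Gaussian noise scaled to 0.05 rad/sample.
The scale is chosen so the implied instantaneous frequency deviation
(~2 Hz sd) stays inside every band's half-width after filtering; the
fGn itself is generated by circulant embedding, so its finite-sample
covariance is exactly the closed form — generator bias cannot masquerade
as estimator bias in recovery tests. A small additive white noise
(amplitude 0.05) gives every band non-degenerate content, so
off-carrier bands measure an uncorrelated ($\alpha \approx 0.5$),
group-equal synchrony rather than numerical garbage.

Because the difference of two independent fGn(H) walks is again fGn(H),
every ROI pair inherits the baseline Hurst exponent. Planted effects are
arranged along a spanning forest of the effect edges: each child ROI's
walk is its parent's walk plus an edge-specific walk, drawn with the
effect Hurst exponent in group 2 and the baseline exponent in group 1.
Planted pairs therefore carry exactly the effect exponent in group 2.
One consequence is unavoidable: phase differences compose, so a pair
that bridges two planted walks (e.g. two children of one planted parent)
also inherits the reduced exponent. Planted *components* are recovered
larger than planted; tests assert overlap with the planted edges rather
than equality.

What the generator does **not** emulate: broadband 1/f spectra, volume
conduction and source leakage, the inverse solution, artifacts,
non-stationarity, or amplitude dynamics. Passing recovery tests on this
generator therefore validates the estimator chain — not the claim that
real EEG meets the chain's assumptions.

One physical limitation matters for interpretation: a carrier at
$f_c$ cannot carry phase modulation faster than itself, so per-sample
phase increments are never recoverable from the oscillation. The
generator's planted increments and the measured TV-PS agree closely
(correlation > 0.95, matching distributions) once aggregated to 0.1 s —
far below the smallest DFA window, so everything DFA sees is faithful.

## Numerical choices and degenerate inputs

* Window lengths are deduplicated after rounding and must be ≥ 4
  samples; at least 6 distinct lengths are required for a fit.
* A zero fluctuation at any window length (exactly linear profile —
  e.g. a constant series) raises a degenerate-series error rather than
  producing $-\infty$ in log space.
* Constant signals have no phase and are rejected; an all-zero series
  errors at phase extraction.
* AIC ties resolve against acceptance (conservative).
* All generators draw from a locally seeded Mersenne-Twister stream and
  restore the caller's RNG state; every result is bit-reproducible from
  its seed.

## Problem sizes used by the test-suite

The validation suite runs at desk scale, chosen so each check has clear
statistical margins: fGn references of length $2^{13}$–$2^{14}$;
oscillator pairs of 120–300 s at 250 Hz; cohorts of 8–16 subjects with
8–10 ROIs and 60 s recordings for end-to-end network recovery; NBS
calibration on 20 replicate null cohorts (2 × 10 subjects, 500
permutations). The NBS power replicates plant the study's own contrast —
exponent 0.75 vs 0.55 with the ~0.08 estimation noise of 60-s series
(d ≈ 2.5) — at which ≥ 80% recovery has a comfortable margin; at a
1-pooled-SD contrast with 16 subjects per group the same pipeline's
power is only ~50%, which is a property of the primary p < 0.005
threshold, not of this implementation.

## Known limitations

* The ML-DFA likelihood constants are calibrated for plots with ~10–20
  log-spaced points from series of $10^4$-sample order; radically
  different plot geometries may need recalibration.
* The exponential and logarithmic candidate parameterizations are fixed
  functional forms; the originating ML-DFA literature names the model
  families without formulas, so other parameterizations are defensible.
* Group inference assumes exchangeability of subjects under the null;
  strong group differences in nuisance distributions (e.g. age) are
  handled by the GLM but not by the permutation scheme itself.
* DFA-1 only; multifractal and higher-order detrending are out of
  scope, as are amplitude-envelope LRTCs and magnitude-based
  connectivity measures.
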