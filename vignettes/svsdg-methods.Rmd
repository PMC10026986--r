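---
title: "Methods: directional brain-heart interplay under graded mental stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional brain-heart interplay under graded mental stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`svsdg` quantifies the *directional* functional interplay between cortical
oscillations and cardiac autonomic activity during a graded mental-stress
protocol (a short rest followed by three increasingly demanding stressor
blocks). The chain is:

1. **Autonomic indices from heartbeat dynamics.** RR intervals are
   convolved with a discrete orthonormal Laguerre basis; a Kalman filter
   tracks the time-varying expansion coefficients; fixed published kernels
   map the coefficients onto a sympathetic activity index (SAI) and a
   parasympathetic activity index (PAI).
2. **EEG band power.** Zero-phase Butterworth band-pass (0.5--45 Hz,
   order 4), Hann-tapered STFT (2-s windows, 50% overlap, so 1-s / 0.5-Hz
   resolution), and integration over the five canonical bands
   ($\delta$ 1--4, $\theta$ 4--8, $\alpha$ 8--12, $\beta$ 12--30,
   $\gamma$ 30--45 Hz, half-open intervals).
3. **Directional couplings (SV-SDG).** Brain$\to$heart: the heart-rate
   modulation $m(t)$ about a 15-s sliding baseline is regressed (no
   intercept, 15-s windows) on SAI and PAI, giving control coefficients
   $C_{SAI}(t), C_{PAI}(t)$; the coupling from band $F$ is
   $C_X(t)/EEG_F(t-1)$. Heart$\to$brain: band power follows an adaptive
   Markov model $EEG_F(t)=\kappa_F EEG_F(t-1)+\Psi_F(t-1)+\varepsilon_F$;
   the drive is identified with the pointwise lag-1 residual and the
   coupling is $\Psi_F(t)/X(t)$.
4. **Condensation and statistics.** Each coupling series is z-scored over
   the whole protocol and condensed per condition into its median absolute
   deviation (MAD, no consistency constant) --- variability, not median, is
   the discriminative quantity. Friedman tests across the four conditions
   (per channel, Bonferroni $\alpha/9$), pairwise Wilcoxon signed-rank
   tests, MRMR feature ranking of the $2\times2\times5\times9=180$
   features, and subject-stratified five-fold CV models (Gaussian-kernel
   ridge regression of the 0/1/4/5 stress encoding; kernel naive Bayes for
   low/high stress).

A forward simulator (`generate_protocol_dataset()`) emulates the protocol
with *known* planted couplings so that every stage is testable without any
recordings.

## The autonomic model

The heartbeat model is
$RR(k) = g_0(k) + \sum_{j=0}^{8} g_{1,j}(k) L_j(k) + \varepsilon_{RR}(k)$
with $L_j(k)=\sum_{n=0}^{k-1}\phi_j(n)RR(k-n-1)$ and $\phi_j$ the discrete
Laguerre family with discount $\alpha$. The coefficients follow a random
walk and are tracked by a Kalman filter with a time-varying observation
row $[1, L_0(k),\dots,L_8(k)]$. SAI weights the first two time-varying
coefficients and divides by $RR(k)$; PAI weights the remaining seven and
multiplies by $2RR(k)$ (RR in **seconds** throughout --- the kernels then
place both indices in the tens, which is what makes the $2RR$ scaling
meaningful).

Key parameter choices (all exposed as arguments):

* $\alpha = 0.2$, orders 0--8. The index ranges of the model fix nine
  functions; $\alpha$ is not printed in the source material and 0.2 is the
  conventional choice in the point-process HRV literature (memory
  concentrated over the last 10--20 beats).
* Warm-up: batch least squares over the first 50 beats (20 in the pipeline
  default, because the rest block is only 60 s long); state covariance
  `p0_scale * r_init * I` with `p0_scale = 10`.
* `q = 1e-5` per coefficient by default; observation noise re-estimated
  from a 30-beat innovation window (`adapt_r = TRUE`).
* Filtered (never smoothed) estimates are reported: every downstream
  directional claim then rests on causal quantities only.

### What is and is not identifiable

Three identifiability properties shape both the tests and sensible use:

* **Constant-coefficient recovery needs excitation.** All nine Laguerre
  transfer functions share the same DC gain ($|\sum_n \phi_j(n)| = 1.618$
  at $\alpha=0.2$), so with a quasi-constant RR series the regressors are
  almost collinear and only combinations of coefficients are determined.
  The recovery benchmarks therefore seed the generator with a rich binary
  interval history (excluded from the fit via `skip_beats`) whose decaying
  transient excites every regressor direction; with small R-peak timing
  jitter the filter recovers each coefficient to a few percent within 500
  beats, and the `q = 0` filter with a diffuse prior reproduces batch
  least squares to machine precision.
* **Per-coordinate trajectories are only identified up to excited
  directions.** A slow sinusoidal drift in a single coefficient is
  observationally near-equivalent to an intercept drift (same mean
  channel) and, in closed loop, largely absorbed by the feedback of the
  generated intervals. No filter setting attributes it reliably to the
  right coordinate (best correlation $\approx 0.7$, erratic). The tracking
  test therefore asserts the identifiable consequence: on time-varying
  data the $q>0$ filter attains clearly lower innovation variance than a
  frozen-coefficient fit.
* **Innovations are white** (lag-1 autocorrelation well below 0.2) on
  well-specified data, which is the standard filter-consistency check.

## The coupling model

The modulation is estimated by interpolating the instantaneous rate
$1/RR$ (assigned at interval midpoints) to the 1-s grid and removing a
15-s centred running mean. The windowed no-intercept regression of $m$ on
SAI and PAI masks (never aborts on) windows whose two-column design is
ill-conditioned (condition number $>10^8$); denominators in the coupling
ratios are guarded at $10^{-6}$ of the series median and masked, not
clipped, so ratios are never silently distorted. Masked points carry a
`valid` flag and are excluded from every condensation.

Two properties of the model *as printed* deserve emphasis:

* The no-intercept fit of $m$ (a zero-mean fluctuation) on regressors
  with positive operating levels is biased: part of each window's fit is
  spent cancelling the regressor means. The simulator therefore drives
  its planted modulation with the *fluctuation* parts of the latent
  autonomic series --- operating levels belong in the baseline rate
  $\mu$ --- which is the parameterisation under which the planted
  control coefficients are recoverable (correlation 0.93--0.97 at default
  noise). Applied to real or Kalman-estimated series the fit uses the raw
  series, exactly as specified.
* The lag-1 no-intercept slope $\hat\kappa_F$ identifies the
  autoregressive constant only on (near-)zero-mean fluctuation series.
  On raw band power with operating mean $M$ and fluctuation variance
  $\sigma^2$ the slope converges to
  $\kappa + (1-\kappa)M^2/(M^2+\sigma^2) \approx 1$, with the mean
  returned through $\Psi_F$. The ratio $\Psi_F/X$ still carries the
  heart-drive fluctuations (which is why the condition-wise variability
  analysis works on raw power), but the $\kappa$ and drive-gain recovery
  oracles run on mean-removed series, where the estimator is consistent.
  `fit_heart_to_brain()` accepts a plain `list(grid, values)` for exactly
  this use.
* $\Psi_F$ is identified with the pointwise lag-1 residual, i.e. the
  innovation $\varepsilon_F$ is absorbed into the drive --- the only rule
  computable from the model equation alone. A permutation-surrogate test
  bounds the resulting bias: with zero planted drive the coupling MAD
  stays within the 95th percentile of 100 shuffled surrogates.
* The brain$\to$heart ratio divides by the lagged band power while the
  heart$\to$brain ratio divides by the unlagged autonomic series; the
  asymmetry is retained as printed.

## The simulator and what passing tests show

`generate_protocol_dataset()` emulates 37 subjects, 1-min rest plus three
5-min stressors, 9 channels, 5 bands. Its latent autonomic fluctuations
are narrowband: an LF rhythm at 0.10 Hz (sympathetic-like) and an HF
rhythm at 0.18 Hz (vagal-like), standardized and placed around positive
operating levels (10±6 and 14±8 a.u.). Narrow distinct bands keep the two
regressors separable inside a 15-s window and inside the pass-band between
the baseline-removal cut-off (~0.07 Hz) and the beat-rate sampling limit;
the HF rhythm sits at 0.18 Hz rather than higher because sampling at the
~1.1 Hz beat rate attenuates and lags faster rhythms.

Condition effects are planted on the **variances** of the coupling
trajectories, not their means: the control coefficients drift slowly
(~50-s correlation time) around fixed means with variance increasing from
rest to stressor 3, and the heart-to-brain drive gains fluctuate (~10-s
correlation time) with condition-dependent variance. The $\delta$ band
carries no drive at all and serves as the built-in null for
false-positive control; $\alpha$ carries the strongest drive. One master
seed expands into per-subject, per-condition, per-stream child seeds, so
enlarging the cohort never perturbs existing subjects. Negative generated
power is floored at $10^{-6}\,\mu V^2$ with a logged count.

Monte-Carlo power (100 replicate cohorts of 10 subjects, shortened
stressors of 90 s): Friedman-on-MAD detects the planted $\alpha$-band
variability effect at the Bonferroni-corrected threshold in every
replicate, with no false flags on the null $\delta$ band. The test-suite
problem sizes (2--10 subjects, 60--300-s blocks, 100 replicates) are
chosen so the whole suite runs in well under a minute apart from the power
study; they are stated here as the package's own validation choices.

What the simulator does **not** emulate: real EEG artifacts (ocular,
muscular, cardiac-field), non-stationary baselines, ectopic beats,
inter-subject differences in spectral shape, or any true physiologic
coupling mechanism. Passing recovery tests shows the estimation chain is
self-consistent at realistic signal-to-noise, not that real recordings
satisfy the model.

Recovery of the planted couplings is validated against the **stored
latent ground truth**. The Kalman-estimated SAI and PAI of a coupled RR
series are both near-affine functions of the modulation itself
(SAI $\approx \Psi s_0/RR$, PAI $\approx 2\Psi p_0 RR$), so no method
could split them back into the two planted latents --- the pipeline's
estimated indices are the *observable* autonomic summary, while recovery
tests use the latents retained precisely for that purpose.

## Multivariate analysis choices

* MI uses 10 equal-width bins per continuous variable, base-2 logs;
  "zero" relevance/redundancy means below $10^{-12}$ bits.
* Relevance is the candidate's own $I(x,y)$ (the standard MRMR reading;
  the literal averaged-over-$S$ variant is available via
  `literal_relevance`). The zero-redundancy screen uses the
  $1/|S|^2$-scaled sum; the MIQ denominator uses the $1/|S|$-scaled sum.
  Zero-relevance features are appended in seeded-random order.
* Cross-validation folds are stratified by subject (all four conditions
  of a subject share a fold), preventing subject-identity leakage; MRMR
  selection is re-run inside every training fold by default (one-shot
  selection available).
* Kernel ridge regression uses the median-pairwise-distance bandwidth, a
  centred target and per-sample loss normalisation (ridge term
  $n\lambda$), with $\lambda = 0.027$; the naive Bayes classifier uses
  per-feature Gaussian KDEs with Silverman bandwidths and training-fold
  priors. Under label-free features the regression returns the target's
  standard deviation as RMSE and the classifier sits in the binomial
  chance band --- both asserted in the suite.
* MAD is plain `median(|x - median(x)|)`; the Friedman statistic uses
  average-rank tie correction with the $\chi^2_{k-1}$ reference (exact
  permutation available for $n \le 8$); Wilcoxon signed-rank p-values are
  exact (full sign enumeration via dynamic programming over doubled
  ranks) up to $n = 25$ and tie-and-continuity-corrected normal beyond.

## Degenerate inputs and numerical guards

* RR series outside (0.2, 3.0) s, non-monotone beat times, or beat-time /
  interval inconsistencies beyond 1 ns are rejected at load with line
  numbers.
* All-tied Friedman tables return statistic 0, p = 1; all-zero paired
  differences return p = 1 with a warning; conditions with fewer than 10
  valid points condense to NA with a warning.
* The integrate-and-fire generator integrates $\mu + m(t)$ by trapezoid
  on a 10-ms grid and locates unit-threshold crossings by linear
  interpolation, making constant-rate output exact; a non-positive
  instantaneous rate aborts with the first offending time.
* Single-class training folds are redrawn once with a new seed, then
  error.

## Known limitations

* $C$ coefficients, $\kappa_F$ and $\Psi_F$ inherit the identifiability
  caveats above; compare conditions within subject (as the statistics
  here do) rather than interpreting absolute values.
* The chain starts at RR intervals and band power (or raw EEG series for
  band-power extraction); R-peak detection, ectopic-beat correction and
  ICA/wavelet artifact removal are out of scope.
* Group-level findings from the original recordings are not reproduction
  targets; the package validates the machinery on simulated cohorts.
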