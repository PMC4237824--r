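---
title: "Scan-rescan reproducibility of DCE vessel-wall kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan-rescan reproducibility of DCE vessel-wall kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcerepro)
```

## What the package models

Dynamic contrast-enhanced (DCE) MRI of the carotid vessel wall quantifies
plaque microvasculature through two Patlak-model parameters: the transfer
constant $K^{trans}$ (min$^{-1}$), a surrogate of neovessel permeability and
inflammation, and the fractional plasma volume $v_p$ (unitless), a surrogate
of neovessel density. Before such parameters can serve as trial endpoints,
their scan-rescan measurement error must be known: a subject scanned twice
without biological change should yield the same numbers, and the degree to
which they differ determines how many subjects a longitudinal study needs.

`dcerepro` implements that whole chain as testable code:

1. a **forward simulator** of the bright-blood spoiled gradient echo (SPGR)
   acquisition over a vessel-wall phantom;
2. the **kinetic analysis** of a dynamic series (registration, temporal
   smoothing, signal-to-concentration inversion, arterial input function
   extraction, pixel-wise Patlak estimation, wall masking, plaque-mean
   measurement);
3. the **reproducibility statistics** on paired scan-rescan cohorts
   (variance components, between-scan CV and ICC with bootstrap confidence
   intervals, vendor comparisons, Bland–Altman agreement);
4. **sample-size planning** driven by the measured CV.

Because the original multi-center imaging data are not public, a synthetic
cohort generator stands in for them. Its defaults *are* the study
conditions the statistics are exercised under; they are stated below and
deliberately not treated as tunable knobs.

## The kinetic forward model and its inversion

Tissue concentration follows the two-parameter Patlak model

$$C_t(t) = K^{trans}\int_0^{t} C_p(\tau)\,d\tau + v_p\,C_p(t),$$

valid when back-flux from the interstitium is negligible over the ~5-minute
acquisition. $C_p(t)$ is the plasma concentration in the feeding artery
(the arterial input function, AIF). The integral is discretized by the
trapezoidal rule on the frame times; the same discretization is used by the
simulator and the estimator, so the noise-free pipeline is exactly
self-consistent (the end-to-end recovery test demands relative error below
$10^{-6}$ and in practice sees $10^{-14}$).

Concentration maps to signal through the SPGR steady-state equation

$$S = M_0 \sin\alpha\,\frac{1-E}{1-E\cos\alpha},\qquad
  E = e^{-TR/T_1},\qquad \frac{1}{T_1(t)} = \frac{1}{T_{10}} + r_1 C(t),$$

with flip angle $\alpha = 50^\circ$ and TR 117 ms (GE) / 126 ms (Philips).
At these settings $S$ is strictly increasing in $C$, so the inversion is
closed-form: $M_0$ is estimated per pixel from the two pre-injection
baseline frames, $E$ recovered algebraically, and $C(t)$ obtained from the
relaxivity relation. Signals outside the invertible range (e.g. corrupted
pixels) are flagged invalid rather than extrapolated.

The protocol constants mirror a standard multi-center carotid DCE setup: 18
frames every 18 s, contrast injected coincident with frame 3 (0.05 mmol/kg
at 0.7 ml/s), 160 mm field of view on a 256 matrix (0.625 mm pixels).

### Relaxation and AIF parameters the protocol does not fix

The acquisition protocol says nothing about tissue relaxation times, the
contrast agent's relaxivity, or the shape of the bolus; these are
simulation inputs with literature-typical 3T defaults, all configurable:

| parameter | default | units | role |
|---|---|---|---|
| `t10_wall` | 1000 | ms | baseline T1 of vessel wall |
| `t10_blood` | 1650 | ms | baseline T1 of blood |
| `r1` | 4.5 | L mmol$^{-1}$ s$^{-1}$ | gadolinium relaxivity |
| AIF `peak` | 2 | mmol/L | peak plasma concentration at 0.05 mmol/kg |
| AIF `washout_rate` | 0.2 | 1/min | mono-exponential clearance after first pass |

The simulated AIF is a gamma-variate first pass (peaking one frame after
injection) with exponential washout, rescaled so the sampled maximum equals
`peak` exactly. The phantom's lumen is assigned $v_p = 1$, $K^{trans} = 0$,
so it carries plasma concentration directly; closed-loop AIF extraction on
simulated data therefore uses hematocrit 0. When the lumen signal
represents whole blood (real data), `extract_aif()` applies the plasma
conversion $C_p = C_{blood}/(1-Hct)$ with a configurable hematocrit
defaulting to 0.42.

## The image-analysis chain

**Registration.** Frames are aligned by translation only, maximizing
normalized cross-correlation against a running reference that is updated
with a constant Kalman-style gain (0.25) as frames are registered outward
from the anchor frame. Two details matter. First, NCC is computed on
gradient-magnitude images: contrast arrival changes tissue intensities
drastically (the dark lumen becomes the brightest structure), which can
anti-correlate raw intensities at the true alignment, while boundary edges
stay put. Second, integer search is refined on successively finer grids of
actually-resampled candidates (0.25 then 0.125 px) rather than by parabolic
interpolation, which we found biased by up to 0.15 px near asymmetric
correlation peaks. Estimated shifts below 0.1 px — the method's resolution —
are treated as zero and the frame is not resampled, so a motion-free series
passes through bit-identical.

**Temporal smoothing.** Pixel time curves are smoothed by a fixed-interval
(Rauch–Tung–Striebel) Kalman smoother under a random-walk state model with
shared scalar variances, so the gain sequence is common to all pixels and
the smoother vectorizes. The observation variance can be supplied (in
simulation it is the known noise variance; a noise-free run uses 0, whose
perfect-observation limit is the identity) or estimated from second
temporal differences: for white noise on a slowly-varying curve,
$\Delta^2 y \sim N(0, 6\sigma^2)$, and the median of $(\Delta^2 y)^2$ over
pixels divided by $6\,q_{0.5}(\chi^2_1)$ is robust to the minority of
strongly-enhancing pixels.

**Wall masking.** Plaque means average all valid pixels whose centers lie
inside the outer-wall contour, outside the lumen contour, and more than
1 mm (configurable) from the lumen polygon — the standard guard against
bright-lumen contamination in bright-blood imaging. Point-in-polygon uses
the even-odd rule on pixel centers (centers at $(i-0.5)\times$ pixel size
from the image origin); the exclusion distance is measured to the polygon
segments, not to a rasterized mask. Raw least-squares estimates, including
negative ones, enter the plaque mean; clamping to display ranges happens
only when rendering the parametric image ($K^{trans}$ green over 0–0.2
min$^{-1}$, $v_p$ red over 0–1). Lesions qualify for analysis only with
maximum wall thickness strictly greater than 1 mm.

## The reproducibility model

For a parameter measured twice in each of $n$ subjects,

$$y_{ij} = \mu + b_i + e_{ij},\qquad b_i \sim N(0,\sigma_b^2),\quad
  e_{ij} \sim N(0,\sigma_w^2),$$

with $\sigma_w$ the **between-scan SD**, CV $= \sigma_w/\mu$ (raw scale,
not log) and ICC $= \sigma_b^2/(\sigma_b^2+\sigma_w^2)$. In this balanced
two-scan design the REML solution coincides with the one-way ANOVA moment
estimator, which is what `fit_variance_components()` computes exactly:
$\hat\sigma_w^2 = \mathrm{MSW}$ (the mean of $d_i^2/2$),
$\hat\sigma_b^2 = \max(0, (\mathrm{MSB}-\mathrm{MSW})/2)$. Truncation at
zero is recorded; all-constant data yield ICC 0 by convention, flagged
degenerate. The equivalence with a brute-force two-parameter REML
optimization is asserted to $10^{-6}$ relative in the test suite.

**Bootstrap intervals.** Confidence intervals resample *subjects* with
replacement, keeping scan pairs intact — the only resampling scheme that
respects the model's dependence structure. The default interval for the SD
and CV is the studentized (bootstrap-t) interval with delta-method standard
errors rather than the simpler percentile interval: the $d_i^2/2$ behind
$\hat\sigma_w$ are scaled $\chi^2_1$ draws, skewed enough that percentile
intervals measurably undercover at $n$ in the tens, while the studentized
interval restores near-nominal coverage (the calibration test in the suite
checks 95% intervals over outer replicates of the generator). The ICC, a
bounded ratio with no convenient SE, uses the percentile interval. B = 2000
replicates by default; intervals with more than 10% undefined replicates
are flagged unstable.

**Vendor comparisons.** The mean difference between scanner platforms is
tested by the balanced fast path of the mixed model with a vendor fixed
effect — a two-sample t-test on subject means. The difference in
between-scan SDs is tested by permuting vendor labels across subjects with
statistic $|\hat\sigma_w^{GE}-\hat\sigma_w^{Philips}|$ and the add-one
estimate $p = (1+\#\{perm \ge obs\})/(n_{perm}+1)$, 10 000 permutations by
default.

**Agreement and size effects.** Bland–Altman limits use mean difference
$\pm 2\,SD$ of the differences (the factor 2, not 1.96, matching the
field's reporting convention). Per-subject variability is the two-point
sample SD $|y_{i1}-y_{i2}|/\sqrt2$, related to subject means and plaque
area by the Spearman rank correlation (average ranks for ties, two-sided p
from the t approximation). The large-plaque subgroup keeps subjects whose
*smaller* of the two scans' analyzed areas is at least 25 mm².

## Sample-size planning

A follow-up-minus-baseline change carries two independent measurement
errors, so its CV is the single-measurement CV times $\sqrt2$; with
measurement error dominating within-arm variability, that is the per-arm SD
(as a fraction of the baseline mean) for a two-arm comparison of % change.
`sample_size_per_arm()` solves the two-sided unpaired t-test design at 80%
power and $\alpha = 0.05$ using the exact noncentral-t power function
(noncentrality $\delta/(\sigma\sqrt{2/n})$, $2n-2$ df) — the normal
approximation is off by one to two subjects exactly in the range of
practical interest.

One deliberate choice: the continuous solution of the power equation is
converted to an integer by *rounding to nearest* (the convention of
standard sample-size software, and the one that reproduces the published
values for this design), not by ceiling. The two can differ by one subject
when the continuous solution sits just above an integer; `rounding =
"ceiling"` is available for strict guaranteed-power planning, and the test
suite verifies for every emitted value that power at $n-1$ falls below
target. Dropout is deliberately not modelled.

## What the synthetic cohort emulates — and what it does not

`generate_roster()` reproduces the *exclusion anatomy* of a multi-center
trial: 51 subjects across 15 sites (GE sites totalling 29 subjects,
Philips 22), of whom exactly 10 carry a significant protocol violation in
at least one scan (3 wrong frame interval, 2 too few frames, 2 failed
contrast injection, 3 misaligned slab — disjoint categories spread over 9
sites, one two-subject site fully lost) and, among the compliant, exactly 6
carry uninterpretable image quality (score 1) in at least one scan, spread
over 6 sites. The cascade is protocol first, then quality, leaving 35
analyzed subjects (20 GE / 15 Philips); the counts are conserved by
construction and checked by test. The seed randomizes which subject within
a site carries each flag and the nuisance values, never the counts.

`generate_measurement_cohort()` draws measurement tables from the
random-intercept model itself. The study-condition defaults are, per
parameter: $K^{trans}$ mean 0.062 min$^{-1}$, between-scan CV 25%, ICC
0.65; $v_p$ mean 0.067, CV 62%, ICC 0.28. Plaque areas are lognormal with
log-mean $\log 27$ and log-SD 0.7 mm² (chosen so that roughly half of a
35-subject cohort clears the 25 mm² subgroup threshold, matching the
subgroup-to-cohort ratio such studies report) with a 0.1 log-SD between-scan
jitter.

What passing tests on these cohorts shows: the estimators recover the
generating variance structure without bias at the study's size, the
bootstrap and permutation procedures are calibrated under the model, and
the pipeline's arithmetic is correct. What it cannot show: anything about
model misspecification in real data — real between-scan variation includes
repositioning, coil placement and physiological effects that are only
partially mimicked (the image-level scan-rescan generator perturbs series
by sub-pixel repositioning, fresh noise, and multiplicative kinetic jitter),
and real plaque kinetics are spatially heterogeneous where the phantom wall
is uniform. The published real-data values (ICC 0.65 / CV 25% for
$K^{trans}$; 0.28 / 62% for $v_p$) are generator inputs here, not
reproduced findings.

## Numerical choices and degenerate inputs

* Baseline frames are frames 1–2 (injection coincident with frame 3); they
  have $C_p = 0$ and stay in the Patlak fit, stabilizing the
  intercept-free regression. A frame-interval deviation beyond 1 s
  (configurable) flags protocol non-compliance.
* The Patlak design matrix is shared across pixels, so all pixel fits are
  one QR solve; a singular design (zero AIF) flags every pixel invalid
  rather than returning numbers.
* Registration on an all-zero frame is skipped and flagged; an empty lumen
  ROI is an error ("unusable AIF"), an empty wall mask yields a
  measurement marked *missing*, never zero.
* Bootstrap of an all-constant table returns the degenerate interval
  [0, 0]; permutation p-values are bounded in $[1/(n_{perm}+1), 1]$.
* All generators take an explicit integer seed and restore the caller's
  RNG state, so every simulated object is a pure function of its
  arguments.

## Problem sizes used by the test suite

The heavy checks run at sizes chosen to balance Monte-Carlo resolution
against runtime on a single core: 500 replicate phantoms (48×48 px, 18
frames) at wall SNR 20 for the plaque-mean bias check; 1000 cohort
replicates for CV/ICC recovery; 1000 simulations × 199 permutations for
the type-I calibration of the vendor SD test; 200 outer replicates × 2000
bootstrap replicates for CI coverage. The full suite completes in about
two minutes.

## Known limitations

* Registration is translation-only per slice; through-plane and rotational
  motion are out of scope, consistent with thick-slice 2D acquisitions.
* The Kalman registration-and-smoothing stage is a documented surrogate
  with the same role as the proprietary algorithm used by the clinical
  analysis software; its exact state model and gains are not public.
* Additive Gaussian noise approximates Rician magnitude noise; at the
  SNRs the pipeline targets (wall SNR ≳ 20) the distinction is negligible,
  and the inversion stays simple.
* No multi-site random effect is modelled (site enters only the roster);
  no reader variability is simulated — boundaries are inputs, as in the
  consensus-review workflow the analysis mirrors.
* $v_p$ at CV 62% is a poor trial endpoint; the package reproduces that
  arithmetic (sample sizes in the hundreds per arm) rather than fixing it.
  The subgroup analysis quantifies how much large lesions help.
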