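---
title: "Measuring movement synchrony in dyads: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring movement synchrony in dyads: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The measurement model

`dyadsync` quantifies how much two interacting people move *together*. The
chain has four stages, each with a small number of consequential parameters.

### Motion energy

Body movement is operationalized as frame-differenced motion energy: for a
fixed rectangular region of interest (ROI) around one person, the value at
frame transition $t \to t+1$ is

$$E_t \;=\; \#\{\,p \in \mathrm{ROI} : |I_{t+1}(p) - I_t(p)| > \theta\,\},$$

the number of pixels whose grayscale intensity changes by **strictly more**
than the threshold $\theta$. The strictness matters at the boundary: with
$\theta = 3$, a change of exactly 3 is still treated as camera noise.
$\theta$ is calibrated from a background region where nothing moves, as the
empirical 99% quantile of pooled absolute frame-to-frame changes, rounded
*up* to the next integer — rounding up plus the strict comparison guarantees
that at least 99% of pure noise is excluded. Typical consumer cameras yield
$\theta = 3$, which is the package default. Calibration pools pixels and
transitions across all supplied background material; a per-video-averaged
variant would also be defensible, and pooling was chosen because it weights
every background sample equally and is a single well-defined quantile.

Color input is converted with ITU-R BT.601 luminance
($0.299R + 0.587G + 0.114B$), the standard weighting for video material,
so conversion is deterministic and documented. A centered moving median of
0.5 s (13 frames at 25 fps) is available to damp spike artifacts
(compression glitches, brief occlusions); the pipeline applies it at the
MEA stage and it can be switched off. The kernel width is a conventional
spike-filter scale, not a fitted quantity: it must be long enough to kill
1–2 frame spikes and short enough not to blur genuine bout onsets
(which last several hundred milliseconds).

*Gross body movement* is the fraction of transitions with $E_t > 0$: how
much of the interaction a person spent moving at all. It is the main
movement-level confound of synchrony measures and is therefore carried
through to the statistics layer as a control variable.

### Windowed cross-lagged correlation

Synchrony is localized in time and lag by correlating a sliding window of
one series with lag-shifted windows of the other. Defaults: window 5 s,
step 1 s, maximum lag 5 s — movements further apart than 5 s are not
considered synchronous. The window and step are not dictated by the
measurement model itself; a window equal to the maximum-lag scale is the
convention of this method family (long enough for a stable Pearson r over
~125 frames, short enough to resolve individual movement bouts), and a 1 s
step keeps the surface at desk scale. Both are configurable.

**Lag convention.** At lag $\ell$ the *leader's* window is anchored at grid
position $t$ and the follower's window starts $|\ell|$ frames later:
positive $\ell$ means the clinician's window is the later one, i.e. the
patient leads. For $\ell \ge 0$ this equals the plain convention
$r(t,\ell) = \mathrm{cor}(x_{t:t+W},\, y_{t+\ell:t+\ell+W})$; anchoring the
earlier window at $t$ for both signs was chosen because it makes the
surface *exactly* mirror-symmetric under exchanging the two people —
swapping the series maps $r(t, \ell) \mapsto r(t, -\ell)$ cell for cell, so
patient-led and clinician-led results exchange exactly rather than
approximately. The alternative (always anchoring the first series) breaks
this exchange symmetry off the window grid. The price is that time-reversal
symmetry holds only approximately (reversed peaks land between grid
positions); the package treats exchange symmetry as the more important
invariant because leader attribution is the scientific output.

Cells whose shifted window would leave the series, and cells in which
either window has zero variance (nobody moved), are undefined. Zero
variance is detected on the rolling second-moment identity
$W\sum x^2 - (\sum x)^2 \le \varepsilon$ with a relative guard
$\varepsilon = 10^{-9} W \sum x^2$ against cumulative-sum round-off; for
integer-valued motion-energy series the moments are exact and the test is
exact. The implementation uses cumulative sums per lag (exact for integer
series of realistic magnitude) and matches a naive two-pass per-window
Pearson oracle to better than $10^{-10}$, which the test suite asserts on
random series.

### Peak-picking and synchrony intervals

Per window start, candidate peaks are lags that are strict local maxima of
$R^2$ along the lag axis, reach the cutoff $R^2 \ge 0.25$, and have
positive $r$. The choices here:

* **Positive r only (default).** "Moving together" denotes in-phase
  movement; anti-phase coupling ($r < 0$) is a different phenomenon. An
  `"absolute"` mode is provided for sensitivity analyses.
* **Cutoff .25.** The value that empirically minimizes false-positive
  interval detection in this method family; it is the package default and a
  single tunable.
* **Plateaus** of equal $R^2$ count once, at the plateau center — a
  deterministic tie-break. Ties between distinct candidate lags go to the
  smaller $|\ell|$, then to the positive sign; with continuous data such
  ties have probability zero, but determinism is guaranteed either way.

The per-window peak is the candidate with maximal $R^2$. Maximal runs of
consecutive window starts whose peaks share a lag *sign* become one
synchrony interval; a sign flip or a window without a valid peak breaks the
run. The interval spans the union of its windows (the alternative —
peak-center spans — is narrower; window union is the simplest faithful
reading and is the implemented rule), its lag is the $R^2$-weighted mean of
the absolute peak lags (weighting by evidence strength; an unweighted
median would be similar and is not offered), and its leader follows the
sign: positive → patient, negative → clinician, all-zero → tie. Minimum
interval length is one window and runs are never merged across gaps.

### From intervals to per-dyad measures

Frames covered by at least one interval are attributed to exactly one side;
overlaps between opposite-leader intervals go to the higher peak $R^2$
(ties: earlier start, then patient — again a deterministic, practically
irrelevant rule). Tie-leader (zero-lag) frames count half to each side.
This makes attribution a partition, so

$$\mathrm{MS}_{\mathrm{total}} = \mathrm{MS}_{\mathrm{patient\mbox{-}led}} +
  \mathrm{MS}_{\mathrm{clinician\mbox{-}led}}$$

holds *exactly*, and the leading variable is defined as their difference.
(One numerical caveat: the total is computed as the sum of two separately
rounded quotients, so comparisons across runs should allow one ulp.)
Mean time-lags are unweighted means over intervals — each interval is one
observation, regardless of length — overall and per leader class, of the
absolute lag magnitudes; they are missing, not zero, when a dyad has no
interval of the class, so cohort-level correlations use pairwise deletion.

## The statistics layer

Cohort analysis mirrors the standard plan for such studies: two-sided
Pearson correlations between each clinical scale and each synchrony
measure with pairwise deletion (sample sizes therefore vary per cell);
the same grid as partial correlations — residualize both variables on the
controls (age, gender, medication, patient gross body movement) with an
intercept, correlate the residuals, and test with $n - 2 - k$ degrees of
freedom; extreme-value screening of the time-lag columns at $|z| > 3.29$
(two-sided, single pass); and block-wise OLS regression on z-scored
variables (controls, then severity, then dependency) on the
listwise-complete cases, with
$$F_{\mathrm{change}} = \frac{(R^2_k - R^2_{k-1})/\Delta p}
  {(1 - R^2_k)/(n - p_k - 1)}.$$
Binary covariates are coded 0/1 (gender: 1 = female; medication:
1 = medicated) and the coding is stated in the output metadata because the
reference category is otherwise ambiguous. No multiple-testing correction
is applied — matching the analysis plan this layer reproduces — and the
report carries a note saying so.

## What the simulator emulates — and what it does not

The generator produces the *structure the measurement chain assumes*:

* **Bout structure.** Movement comes in epochs: onsets follow the previous
  epoch's end after an exponential gap (~6 nominal epochs/minute),
  lengths are lognormal (median 3 s, truncated to 1–10 s), and the energy
  trace is smoothed positive noise under half-cosine on/off ramps —
  nonnegative and bursty like real motion-energy traces, not Gaussian.
* **Coupling.** With probability `coupling`, an epoch is echoed by the
  other person after a uniform lag (default 0.5–2.5 s, always within the
  5 s detection bound); the echo is a scaled (×0.7–1.0), noise-perturbed
  copy of the leader's trace. The follower-noise level (15% of the
  amplitude) is set so that in-window $R^2$ of a genuine echo lies well
  above the .25 cutoff — coupling strength is a design constant, not a
  fitted quantity.
* **Cohorts.** Latent severity $d_i \sim N(0,1)$ drives the patient-led
  coupled-epoch probability through a logistic link with slope
  `effect_size`, while the clinician-led epoch probability stays constant —
  so a negative effect is planted on patient-led synchrony and *nothing* is
  planted on clinician-led synchrony, which is the pattern the analysis
  layer must be able to tell apart. HAMD and BDI-II are noisy linear
  readouts of $d_i$ rescaled to instrument ranges (loadings .85/.80);
  interpersonal scales load more weakly (.55–.65); medication probability
  rises with severity; age and gender come from demographic marginals.
  All randomness flows from one cohort seed via per-dyad derived seeds, so
  cohorts are reproducible dyad by dyad.
* **Videos.** `render_video()` maps series values to counts of ROI pixels
  that jump by 16 intensity units per transition over a static background
  with ±1 sub-threshold jitter, making the MEA stage testable end to end.

It does **not** emulate: camera motion or lighting drift, occlusion between
the two people, within-bout acceleration profiles of human limbs, postural
(sub-threshold) movement, or any appearance realism. Passing tests
therefore demonstrate that the chain recovers the coupling structure it is
designed to measure, under clean recording conditions — not that a given
real camera setup is noise-free. The threshold calibration and smoothing
exist precisely for the artifacts the simulator leaves out.

A pseudosynchrony control is included: circularly shifting one series by a
random offset of at least twice the maximum lag preserves each person's
marginal movement but destroys the coupling, so genuine dyads should beat
their surrogates — and do, overwhelmingly, in the validation suite.

## Validation scale and degenerate inputs

The shipped validation uses problem sizes chosen to characterize the
estimator at desk scale: 50 ten-minute dyads (25 fps, 15 000 transitions)
for leader/lag recovery and the surrogate control; 20 replicate cohorts of
114 dyads with 120 s segments for sign recovery of the planted severity
effect (120 s ≈ 12 epochs per dyad is the shortest segment for which the
per-dyad MS estimates are stable enough to be interesting, and a cohort
remains a few minutes of compute); 300-frame pairs for the brute-force
WCLC oracle; 5 000 draws for null calibration of the correlation tests.

Degenerate inputs are handled explicitly rather than incidentally: a
perfectly static background calibrates to threshold 0; all-zero series
yield zero gross movement and fully invalid WCLC cells (no synchrony, not
an error); an interval-free dyad has MS 0 and *missing* lag means;
zero-variance variables make correlations an error (undefined), while a
zero-variance screening column simply excludes nothing; rank-deficient
covariate sets raise a collinearity error instead of silently dropping
terms.

## Known limitations

* Rectangular ROIs measure *amount* of pixel change only — no direction,
  speed, or body-part information; two people must not enter each other's
  ROI.
* Interval boundaries are quantized to the window grid (1 s), so MS values
  change in steps of roughly `step / duration`.
* Mean time-lags are magnitudes; a dyad alternating short and long delays
  is summarized by their mean, and lag means over few intervals are noisy —
  hence the extreme-value screen at the cohort level.
* The statistics layer implements the uncorrected, cross-sectional analysis
  plan it mirrors; it is not a general-purpose regression framework.
* Video decoding is delegated: containers must be pre-extracted to image
  frames; the package reads PNG/TIFF directories and delimited series.
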