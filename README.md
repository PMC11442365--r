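# dyadsync

Movement synchrony in dyadic interactions, measured from video and analyzed
against clinical covariates.

When two people interact, their body movements couple: one person starts
moving and the other joins in, simultaneously or with a short delay. In
clinical settings this nonverbal synchrony carries information — depressed
patients, for example, tend to elicit less movement synchrony from their
interviewers. `dyadsync` implements the full measurement chain used to
quantify this phenomenon:

1. **Motion energy analysis (MEA).** Each person in the camera view gets a
   rectangular region of interest (ROI). Movement at frame transition
   *t → t+1* is the count of ROI pixels whose grayscale intensity changes by
   strictly more than a noise threshold (default 3; calibrated as the ceiled
   99% quantile of frame-to-frame change in a static background region).
2. **Windowed cross-lagged correlation (WCLC).** A 5 s window slides over
   the two movement series in 1 s steps; at each position the Pearson
   correlation is computed for every lag up to ±5 s, the latency up to which
   movements count as synchronous. Positive lags mean the patient leads.
3. **Peak-picking.** Per window, the best local maximum of *R²* along the
   lag axis that exceeds the cutoff (*R²* ≥ .25) becomes the window's peak;
   runs of consecutive windows with a constant peak-lag sign merge into
   **synchrony intervals** with a leader, a lag, and a peak strength.
4. **Synchrony measures.** Per dyad: total movement synchrony (MS, the
   proportion of the interaction spent in synchrony), its patient-led and
   clinician-led components (which sum to the total exactly), the *leading
   variable* (patient-led − clinician-led MS), and mean time-lags.
5. **Statistics.** Two-sided Pearson and partial correlations (controls:
   age, gender, medication, gross body movement) between the MS measures
   and clinical scales, extreme-value screening (|z| > 3.29), and
   block-wise hierarchical regression with F-change tests.

Because real interview videos of this kind cannot be shared, the package
ships a first-class simulator: coupled-dyad movement series with known
ground truth (bout structure, leader, lag), synthetic two-ROI videos for
end-to-end MEA validation, and whole cohorts with a planted
severity → patient-led-synchrony effect. Every stage is validated against
that ground truth.

## Worked example

Simulate a 10-minute dyad in which the patient always leads the coupled
movement bouts (coupling probability .8, follower delay uniform on
0.8–1.6 s), then measure it:

```r
library(dyadsync)

sim <- simulate_dyad(sim_config(duration_s = 600, coupling = 0.8,
                                leader_share = 1,
                                lag_range_s = c(0.8, 1.6), seed = 20001))
fit <- dyad_synchrony(sim$patient, sim$clinician)
fit
#> Dyadic movement synchrony fit
#>   15000 frame transitions at 25 fps (600.0 s), 33 synchrony intervals
#> Movement synchrony profile
#>   total MS        : 0.638
#>   patient-led MS  : 0.630
#>   clinician-led MS: 0.008
#>   leading         : +0.622
#>   mean time-lag   : 1.61 s (pat 1.25 / clin 4.22)
#>   intervals       : 33
```

The dyad spent 64% of the interaction in synchrony, almost all of it
patient-led (leading +0.62), and the recovered patient-led mean time-lag
(1.25 s) matches the planted lag distribution (mean 1.2 s). `plot(fit)`
shows the *R²* surface with the detected intervals; `coef(fit)` returns the
profile as a named vector; `summary(fit)` lists the intervals.

From video instead of series: `read_frames()` loads a directory of PNG/TIFF
frames, `calibrate_threshold()` derives the noise cutoff from a static
background ROI, and `motion_energy()` produces the per-person series.
`run_pipeline(pipeline_config(...))` drives the whole chain (including the
cohort statistics via `analysis_report()`) and writes CSV/JSON artifacts;
`inst/scripts/dyadsync.R` wraps it for the shell.

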