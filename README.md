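# vtcycle

Cycle-length variability analysis of ventricular tachycardia (VT) episodes
recorded by implantable cardioverter defibrillators (ICDs).

ICD shocks are painful and associated with harm, yet many detected VT
episodes would have terminated on their own. An ICD stores each episode as a
beat-to-beat cycle-length (CL) series in milliseconds, beginning with CL1,
the interval from the initiating premature ventricular contraction to the
first VT beat. `vtcycle` asks whether the **first 10 CLs** (~3.4 s of
rhythm) predict spontaneous termination, for electrophysiologists and device
researchers studying therapy-deferral algorithms.

From each eligible episode (≥ 11 CLs) the package computes:

- time-domain variability over the first-10 window: mean, sample SD, RMSSD,
  NN50/pNN50, and TINN (least-squares triangular interpolation of the CL
  histogram, 7.8125 ms bins by default);
- Poincaré dispersion SD1/SD2 in rotated coordinates,
  `SD1 = sd((x[t+1] − x[t])/√2)`, `SD2 = sd((x[t+1] + x[t])/√2)`;
- a first-order autoregressive stability fit by least squares of `x[t]` on
  `x[t−1]`: coefficient φ, constant c, residual SD — in the model
  `x[t] = c + φ·x[t−1] + ε[t]`, φ captures beat-to-beat persistence of the
  tachycardia cycle;
- whole-episode descriptors: full-series SD, duration, beat count, and
  initiation-to-shortest-CL dynamics.

Groups (spontaneously terminating vs sustained) are compared feature-wise
with Student's t or Mann–Whitney U tests gated by Shapiro–Wilk normality,
and a feature-selected random forest (importance greater than the mean, 500
trees) is evaluated by stratified 10-fold cross-validation with pooled
out-of-fold predictions.

Because no public VT cycle-length dataset exists, the package includes a
**calibrated synthetic generator**: a deceleration trend plus stationary
AR(1) noise whose defaults reproduce the published cohort composition (36
terminating / 33 sustained episodes from 27 patients) and group statistics.
`calibrate_innovation_scale()` matches the mean first-10 window SD and mean
*fitted* AR coefficient, correcting for small-sample fitting bias
(Kendall's −(1+3φ)/n) and the variance-shrinking effect of autocorrelation
on sample SDs. See the methods vignette
(`vignettes/cycle-length-variability.Rmd`) for the model and its limits.

## Worked example

```r
library(vtcycle)

# one device-recorded episode: CL1 follows the initiating PVC
e <- episode("F1", "P01", "terminating",
             c(373, 375, 360, 373, 371, 352, 345, 341,
               349, 353, 348, 350, 346, 344, 350, 347))
extract_features(e)
#>  mean_cl10  sd_cl10  rmssd10  tinn10  ar_phi  ar_const  ar_resid_sd ...
#>    359.200   12.900   10.044  46.875   0.645   125.473        9.859
```

The window mean (359.2 ms ≈ 167 bpm), SD (12.9 ms) and RMSSD (10.0 ms)
describe the level and beat-to-beat variability of the tachycardia; φ = 0.65
says consecutive CLs are strongly serially dependent — the decelerating,
wobbling pattern typical of episodes about to self-terminate.

A full synthetic analysis:

```r
ch <- generate_cohort(cohort_spec(seed = 42))   # 36 terminating + 33 sustained
ft <- cohort_features(ch)
compare_groups(ft[c("label", "mean_cl10", "sd_cl10", "ar_phi", "episode_sd")])
#>      feature summary_terminating   summary_sustained    test_used  p_value
#> 1  mean_cl10      345.77 ± 34.12      316.30 ± 26.84       t_test 1.61e-04
#> 2    sd_cl10 17.06 (11.71-21.97)   8.64 (6.65-15.85) mann_whitney 3.88e-05
#> 3     ar_phi         0.33 ± 0.33         0.15 ± 0.31       t_test 2.54e-02
#> 4 episode_sd 17.31 (13.64-23.46)   8.70 (6.02-13.05) mann_whitney 2.96e-08

cross_validate(ft, cfg = classifier_config(seed = 42))
#> <vt_eval> accuracy 0.725 (95% CI 0.619-0.830), sens 0.778, spec 0.667,
#>           PPV 0.718, NPV 0.733, AUROC 0.855
#> selected features: ar_resid_sd, mean_cl10, rmssd10, sd_cl10
```

Terminating episodes show roughly twice the CL variability of sustained ones
and a higher AR coefficient; the cross-validated forest separates the groups
with accuracy ≈ 0.73 on this seed (positive class = terminating, threshold
0.5 on pooled out-of-fold probabilities).

A command-line interface wraps the same functions:

```sh
vtcycle simulate --seed 7 -o cohort.csv
vtcycle run cohort.csv --seed 7 -o out/      # features.csv, compare.md, metrics.json, figures
```

(after installation the script lives at `exec/vtcycle` inside the installed
package; from the source tree, `exec/vtcycle`).

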