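# imcpattern

Pattern analysis of knee isokinetic moment curves, for clinicians and
biomechanics researchers who use isokinetic dynamometry to assess structural
knee injury.

A concentric knee-extension effort at constant angular velocity (here
60°/s, 90°–10° of flexion) traces a torque–angle curve that is smooth and
parabolic in a healthy knee. Injuries leave characteristic *breakpoints* in
that curve: a slight recovering notch before or near the peak ("Valley"), a
sharp non-recovering fall right after the peak ("Drop"), or irregular
mid-curve flutter spanning the peak ("Shaking"). `imcpattern` implements the
full analysis chain around this taxonomy:

* a **synthetic trial generator** reproducing the test conditions (five
  repetitions, trapezoidal velocity profile with sub-50°/s ramps, injectable
  artifacts, seeded noise) and cohort sampling that reproduces a packaged
  reference pattern-by-injury contingency table (114 legs: ACL n = 10, MS
  n = 17, PFJ n = 24, ACL+MS n = 23, 40 healthy control legs);
* **preprocessing**: 1°-grid linear resampling, interpolation averaging of
  sub-threshold/missing samples, per-repetition peak normalization, and
  selection of repetitions 2–4;
* a **rule-based classifier** with a breakpoint detector (local-quadratic
  smoothing and baseline, residual excursions with depth/sharpness/recovery/
  position) and the three-repetition consistency rule;
* **Cohen's kappa** for rater agreement, with the conventional bands from
  "no agreement" to "almost perfect";
* the **association model** — a saturated multinomial logit of injury class
  (reference Healthy) on pattern (reference Normal), fitted by Newton on the
  grouped-count likelihood, with Wald inference:
  OR = exp(β), CI = exp(β ± 1.96·SE), and the closed-form identities
  OR = (n₍p,k₎·n₍N,H₎)/(n₍N,k₎·n₍p,H₎),
  SE(log OR) = √(1/n₍p,k₎ + 1/n₍N,H₎ + 1/n₍N,k₎ + 1/n₍p,H₎)
  as an independent oracle;
* **predictor evaluation**: modal-class prediction per pattern, in-sample
  5 × 5 confusion matrix, per-class recall/precision/F1, macro-averaged F1
  and accuracy.

## Worked example

```r
library(imcpattern)

## simulate one trial with a Valley notch and 2% noise, and classify it
trial <- generate_trial(curve_spec("Valley", noise_sd = 0.02, seed = 42))
classify_trial(preprocess_trial(trial))
#> [1] "Valley"

## association model on the packaged reference cohort (ACL equation shown)
fit <- fit_multinomial(reference_pattern_counts())
subset(as.data.frame(fit), outcome_class == "ACL")
#>   outcome_class      term estimate    se odds_ratio ci_lower ci_upper wald_z   p_value
#> 1           ACL Intercept   -2.862 0.727    0.05714  0.01374   0.2376 -3.937 8.256e-05
#> 2           ACL    Valley    2.862 1.236   17.50000  1.55114 197.4352  2.315 2.061e-02
#> 3           ACL      Drop    3.961 1.365   52.50000  3.61977 761.4435  2.903 3.699e-03
#> 4           ACL   Shaking    3.268 1.167   26.25000  2.66546 258.5159  2.800 5.110e-03

## in-sample evaluation of the modal-class predictor
evaluate_predictions(counts_to_labels())
#> Pattern-to-injury predictor, in-sample over 114 observations
#>          predicted
#> actual    ACL MS PFJ ACL+MS Healthy
#>   ACL       0  3   2      3       2
#>   MS        0 11   1      1       4
#>   PFJ       0  9  10      1       4
#>   ACL+MS    0  6   6      8       3
#>   Healthy   0  2   2      1      35
#>    class recall precision    f1
#>      ACL  0.000     0.000 0.000
#>       MS  0.647     0.355 0.458
#>      PFJ  0.417     0.476 0.444
#>   ACL+MS  0.348     0.571 0.432
#>  Healthy  0.875     0.729 0.795
#> Macro-averaged F1: 0.426   Accuracy: 56.1%
```

Reading: a Valley-patterned curve multiplies the odds of an ACL rupture
(versus a healthy knee, relative to a Normal curve) by 17.5; the modal
predictor never predicts ACL (its row of zeros), and overall assigns the
correct structure to 56.1% of legs with a macro-averaged F1 of 0.426 —
significant associations, modest predictive power.

A YAML-configurable end-to-end pipeline (`run_pipeline()`) and a thin
command-line wrapper (`inst/scripts/imc-pipeline.R`, subcommands
`simulate-cohort`, `classify`, `agreement`, `fit-model`, `evaluate`,
`reproduce-tables`, `run`) tie the stages together with one root seed and
byte-reproducible reports.

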