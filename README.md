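# screenval

Diagnostic accuracy of brief multi-informant screening items under
skip-rule verification, and projection of population prevalence onto a
screen-only survey wave.

## The problem

National mental-health surveys of children and young people screen for
eating disorders with five brief gating items answered by a parent and by
the young person themselves; only those scoring at or above threshold
(two endorsed items for parents, one for young people) continue into the
full diagnostic module that a clinical rater uses to assign DSM-5 / ICD-10
diagnoses. That skip rule keeps respondent burden low but has two
analytic consequences:

1. **Verification (work-up) bias.** Screen-negatives are never assessed,
   so the survey observes zero false negatives by construction. Test
   accuracy must therefore be reported twice: as observed, and under an
   externally estimated false-negative rate among screen-negatives (2.4%,
   from a clinical validation sample that completed the module with skip
   rules disabled).
2. **Screen-only follow-up waves.** A later wave that administers only
   the screening items yields no diagnoses; its expected prevalence is
   projected as the screen-positive proportion times the positive
   predictive value (PPV) established in the fully verified wave, with a
   range from the PPV's 95% CI.

`screenval` implements the whole pipeline for epidemiologists and
psychometricians working with such designs: record I/O and validation,
threshold scoring and informant combination, confusion tables and the
five accuracy measures with 95% CIs, the false-negative reanalysis, the
PPV-based prevalence projection, an integer back-solver that recovers
2x2 cells from published rounded percentages when the microdata are
restricted, and a synthetic survey generator for testing everything
without restricted data.

## The statistics

For a 2x2 table (TP, FP, TN, FN):
sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
NPV = TN/(TN+FN), accuracy = (TP+TN)/n. Intervals are Wald,
p ± z_{0.975} √(p(1−p)/n), with an exact Clopper–Pearson fallback at
k ∈ {0, n} (lower bound (α/2)^{1/n} when k = n). The false-negative
scenario at rate r moves m = round(r·(TN+FN)) subjects from TN to FN,
leaving TP and FP — hence the PPV — untouched. The projection for a
stratum with screen-positive proportion s is simply s·PPV/100, bounded
by s·PPV_lower/100 and s·PPV_upper/100.

## Worked example

```r
library(screenval)

# a synthetic survey at the 2017 operating point (~4055 subjects, two
# age bands, prevalence 0.6-0.8%)
rec <- generate_survey(synthetic_config(seed = 8467))
tab <- build_confusion(rec[rec$age_band == "11-16", ], informant = "parent")
format_accuracy(accuracy_report(tab))
#> # A tibble: 5 x 2
#>   metric display
#>   <chr>  <chr>
#> 1 se     68.4 (47.5-89.3)
#> 2 sp     93.6 (92.7-94.5)
#> 3 ppv    6.2 (2.9-9.4)
#> 4 npv    99.8 (99.6-100.0)
#> 5 acc    93.4 (92.6-94.3)
```

Parent report is highly specific and has near-perfect NPV, while PPV is
small — at ~0.6% prevalence most screen-positives are false alarms; the
screen is built for ruling out, not ruling in.

Recover the published parent stratum from its printed percentages and
rerun it under the 2.4% false-negative scenario:

```r
cells <- backsolve_cells(3112, ppv = 4.9, npv = 99.8, sensitivity = 66.7,
                         specificity = 93.7, accuracy = 93.6,
                         ci = list(sensitivity = c(42.8, 90.5),
                                   ppv = c(1.9, 7.9)),
                         n_tolerance = 0)
cells
#> # A tibble: 1 x 4
#>      tp    fp    tn    fn
#> 1    10   194  2903     5
adj <- apply_fn_rate(confusion_table(10, 194, 2903, 5), fn_scenario(0.024))
round_half_up(100 * adj$tp / (adj$tp + adj$fn))  # sensitivity falls to 11.8
#> [1] 11.8
```

Project prevalence onto the screen-only follow-up wave from the built-in
published inputs:

```r
run_study2()[, c("age_band", "sex", "screen_positive", "estimate", "lower", "upper")]
#> # A tibble: 6 x 6
#>   age_band sex   screen_positive estimate lower upper
#> 1 11-16    all              13        0.6   0.2   1
#> 2 11-16    girls            17.8      0.9   0.3   1.4
#> 3 11-16    boys              8.4      0.4   0.2   0.7
#> 4 17-19    all              58.2      1     0.5   1.7
#> 5 17-19    girls            76.4      1.3   0.7   2.3
#> 6 17-19    boys             41        0.7   0.4   1.2
```

Despite the screen-positive proportion roughly doubling between waves,
the projected prevalence is close to the earlier wave's (0.6% in the
younger band, 1.0% in 17–19-year-olds), because the PPV of the screen is
so low; the widest relative movement is among boys and young men.

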