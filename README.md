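# fidnavQC

Head motion is the dominant cause of non-diagnostic structural MRI in
unsedated children: motion-corrupted scans are typically discovered only
after reconstruction and must be repeated, wasting scanner time and money.
Free induction decay navigators (FIDnavs) — ultra-short, gradient-free
readouts inserted after each RF excitation — offer a way to monitor motion
*during* the scan: each receive coil in a multi-channel array has a
localized spatial sensitivity, so the per-coil complex FID amplitude shifts
whenever the head moves within the array.

`fidnavQC` is an R package for radiology QC researchers and MR physicists
that implements the full analysis chain from raw navigator samples to a
scan-abort cost model:

1. **Preprocessing** — average the central ADC samples of each readout,
   collapse each echo train to one complex navigator value per channel per
   TR, discard pre-steady-state TRs.
2. **Per-TR motion metrics** — four coil-combination algorithms. With
   `s_j(i)` the complex navigator signal of coil `j` at TR `i` and `N_c`
   coils:
   - reference change:
     `Δref(i) = (1/N_c) Σ_j |s_j(i) − s_j(ref)| / |s_j(ref)|`
   - previous-TR change:
     `Δ(i) = (1/N_c) Σ_j |s_j(i) − s_j(i−1)| / |s_j(i−1)|`
   - top-3 magnitude change `Δmax(i)`: the mean of the three largest
     per-coil relative magnitude changes at each TR
   - cross-correlation: `CCC(i) = 1 − cor(|s(i)|, |s(i−1)|)` across
     coils — sensitive to redistribution of coil loading.
3. **Integration** — per-scan motion scores
   `FIDnav = (1/(n·TR)) Σ_i FIDnav_i` (units 1/s), optionally weighted by
   the k-space energy of each phase-encoding partition,
   `wFIDnav = (1/(n·TR)) Σ_i w_i·FIDnav_i`.
4. **Detection statistics** — empirical ROC against radiologist grades
   (1 = severe artifact … 5 = none), Youden-optimal thresholds
   (`J = SE + SP − 1`), the 0.632 bootstrap
   (`Acc = mean(0.368·Acc_resub + 0.632·Acc_oob)`) for out-of-sample
   sensitivity/specificity, Spearman score–grade correlation, and weighted
   Cohen's kappa for inter-rater agreement.
5. **Scan-abort savings** — running (cumulative) motion scores, the first
   threshold crossing (fraction acquired FA, fraction remaining FR), the
   aggregate time savings
   `T(%) = 100·(Σ_TP FR − Σ_FP FA) / (2(nTP+nFN) + nTN + nFP)`, and a
   dollar cost model of repeat scans.
6. **Synthetic cohort simulator** — a digital ellipsoid-head phantom, a
   32-channel ring coil array, rigid 6-DOF pediatric motion archetypes
   (still / drift / abrupt / continuous restlessness), drift + complex
   Gaussian noise, and ground-truth grading from the k-space-weighted mean
   displacement — so the entire pipeline is testable without patient data.

## Worked example

```r
library(fidnavQC)

# simulate a 40-subject cohort with known ground truth
coh <- generateCohort(n_subjects = 40, n_tr = 160, n_channels = 32,
                      seed = 7)
table(coh$manifest$grade)
#>  1  2  3  4  5
#>  1  4  5 11 19

# integrated motion scores for every subject (eight variants)
scores <- scoreCohort(coh$series, coh$manifest$grade,
                      weighting = coh$weighting)
head(scores[, c("subject_id", "grade", "delta", "ccc")], 3)
#>      subject_id grade       delta          ccc
#> S001       S001     5 0.001244381 2.086800e-05
#> S002       S002     5 0.001266594 2.106640e-05
#> S003       S003     5 0.001165218 1.656825e-05

# detect non-diagnostic scans (grades 1-2) with the integrated
# cross-correlation score
positive <- dichotomizeGrades(scores$grade, "12v345")
rocCurve(scores$ccc, positive)
#> RocResult: AUC = 1.000, J = 1.000 at threshold 0.003589 (41 thresholds)
bootstrap632(scores$ccc, positive, b = 1000, seed = 7)
#> BootstrapResult (b = 1000):
#>   AUC 1.000 +/- 0.000, J 1.000 +/- 0.000
#>   0.632 estimator: SE 0.842, SP 1.000 at threshold 0.003589

# abort policy: stop a scan once its running score crosses the threshold
ab <- abortAnalysis(coh$series, coh$manifest$grade, metric = "ccc",
                    threshold = "youden")
ab$report
#> SavingsReport: time savings 1.86%
#>   TP 5  FP 0  TN 35  FN 0
#>   saved 3.5 min, wasted 0.0 min, net 221 at 62.84/min
```

The simulated grade-5 subjects sit at the noise floor of the
cross-correlation score (~2×10⁻⁵ 1/s) while restless subjects score two
orders of magnitude higher, so the detector separates the classes cleanly;
the savings report then quantifies what aborting the five flagged scans at
their threshold crossings would have saved at $2828 per 45-minute slot.

A command-line front end over the same functions is installed at
`system.file("scripts/fidnav.R", package = "fidnavQC")` with subcommands
`simulate`, `metrics`, `integrate`, `roc`, `bootstrap`, `savings` and
`report`.

## Vignette

`vignettes/fidnav-motion-monitoring.Rmd` describes the signal model, the
four metrics and their assumptions, the simulator's design and
calibration, and known limitations.
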