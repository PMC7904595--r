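---
title: "FID-navigator motion monitoring: models, metrics and design notes"
author: "fidnavQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FID-navigator motion monitoring: models, metrics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidnavQC)
```

## The measurement and its physics

A free induction decay navigator (FIDnav) is a short, gradient-free ADC
readout played immediately after each RF excitation of a structural
sequence. It costs essentially nothing — here 0.2 ms of otherwise dead
time per excitation — and returns, for every element of the receive
array, a single complex number: the coil-sensitivity-weighted volume
integral of the excited magnetization,

$$ s_j(i) \;=\; \int \rho(\mathbf x)\, c_j(\mathbf x)\, d\mathbf x, $$

evaluated at TR $i$ for coil $j$ with sensitivity field $c_j$. Because
$c_j$ is spatially localized, rigid head motion changes the overlap
between the head and each coil's sensitive region, and the vector
$\mathbf s(i) = (s_1(i),\dots,s_{N_c}(i))$ shifts in a
position-dependent way. That is the entire mechanism this package
models; no image is ever reconstructed.

### Preprocessing

Raw readouts carry 64 complex samples per coil in 0.2 ms. The leading
and trailing samples are corrupted by ADC electronic adjustments, so the
middle half (samples 17–48 of 64; `averageAdcSamples()`) is averaged.
All readouts of one echo train are then averaged to one complex value
per coil per TR (`collapseEchoTrain()`), and the first three TRs are
discarded while the magnetization approaches steady state
(`trimPresteady()`, `n_discard = 3`). Averaging is complex throughout:
phase information is only dropped where a metric explicitly takes
magnitudes.

The fixed reference for the reference-change metric is the mean of the
first three *retained* TRs (`referenceSignal()`, `n_ref = 3`). Both
counts are parameters; the alternative reading — taking the reference
from the discarded transient — would contaminate the reference with
non-steady-state signal, so it is not the default.

## The four motion metrics

All four compress the multi-coil change between TR $i$ and either a
fixed reference or TR $i-1$ into one non-negative number, defined for
$i \ge 2$ (so an $n$-TR scan yields $n-1$ values):

| metric | definition | character |
|---|---|---|
| `delta_ref` | mean over coils of $\lvert s_j(i)-s_j(\text{ref})\rvert / \lvert s_j(\text{ref})\rvert$ | cumulative departure from the initial position; drifts with scanner drift |
| `delta` | same, relative to $s_j(i-1)$ | event detector; subjects rarely return to their initial position, so differencing consecutive TRs isolates events |
| `delta_max` | mean of the 3 largest per-coil relative magnitude changes | suppresses random fluctuations while keeping fast-motion sensitivity |
| `ccc` | $1-\mathrm{cor}\big(\lvert\mathbf s(i)\rvert, \lvert\mathbf s(i-1)\rvert\big)$ across coils | detects redistribution of coil loading; invariant to global gain and scaling |

Two readings of the top-3 metric are possible because "change in
absolute signal" is typographically ambiguous; this package uses the
magnitude-domain change
$\lvert\,\lvert s_j(i)\rvert-\lvert s_j(i-1)\rvert\,\rvert / \lvert s_j(i-1)\rvert$,
distinct from the complex-difference magnitude used by `delta`, and
ranks channels by the same quantity. The correlation metric uses the
sample ($N_c-1$) variance normalization and lies in $[0,2]$. When one
magnitude vector is constant across coils the correlation is undefined;
the package returns 0 with a warning — no detectable redistribution.

Degenerate denominators (a reference or previous-TR magnitude below
$10^{-12}\times\max_j \lvert s_j\rvert$) raise an error naming the
channel rather than silently producing huge values.

## Integrated scores and k-space weighting

The per-scan score is the numerical time-integral

$$ \mathrm{FIDnav} = \frac{1}{n\,\mathrm{TR}}\sum_i \mathrm{FIDnav}_i
\qquad [\mathrm s^{-1}], $$

with $n$ the number of outer phase-encoding steps — one per TR for this
3D sequence, so the $i\ge 2$ trace contributes $n-1$ terms. The
cross-correlation score is reported $\times 100$ for legibility
(`displayValue()`); computations always use the raw scale.

Motion is not equally harmful at every moment: artifact severity scales
with the k-space energy of the partitions acquired while the head was
moving. `weightedIntegrate()` therefore weights each step by the norm of
the corresponding k-space plane. Weights come from reference
acquisitions (`kspaceWeightsFromReference()`) or from a packaged smooth
centre-peaked synthetic default (`defaultKspaceWeights()`; a
Lorentzian-plus-floor profile in acquisition order, centre reached
halfway through the scan). Weights are normalized to unit mean — a
choice the estimator itself does not dictate, made so that weighted and
unweighted scores share a scale and a constant trace yields identical
values under both. Trimmed series stay aligned to the weights through
the `firstStep` slot.

## Detection statistics

Scans are graded 1 (severe artifact, non-diagnostic) to 5 (no
appreciable artifact). Two dichotomizations are first-class: grades 1–2
vs 3–5 (non-diagnostic) and 1–3 vs 4–5 (impaired). A scan is called
positive when its score is $\ge$ the threshold; the non-strict
comparison keeps the maximum observed score detectable. Candidate ROC
thresholds are the observed scores plus a $+\infty$ sentinel; the AUC is
the trapezoidal area, which equals the tie-corrected Mann–Whitney
statistic (a property-tested identity). Youden's $J = SE + SP - 1$ is
maximized with ties broken toward the smaller threshold (higher
sensitivity). The reported single optimal threshold is computed on the
full sample — the only reproducible choice when no held-out set exists.

`bootstrap632()` draws cohorts with replacement; each replicate's
Youden threshold is evaluated on the replicate itself (resubstitution)
and on the out-of-bag subjects, blended as
$0.368\,Acc_r + 0.632\,Acc_h$ with the constants as conventionally
printed (not $1/e$). Replicates with a single-class bootstrap sample or
out-of-bag set are redrawn and counted. Replicate RNG streams are
derived from the seed by counter-based splitting, so results do not
depend on execution order. One subtlety: with thresholds restricted to
observed scores and ties broken low, a replicate's threshold sits at its
smallest in-bag positive score, so an out-of-bag positive below it is
missed; even perfectly separated classes therefore show a 0.632
sensitivity slightly below 1 (specificity is unaffected).

Spearman correlation uses average ranks with the two-sided
$t$-approximation p-value. Inter-rater agreement uses weighted Cohen's
kappa, implemented from the contingency table with linear (default) or
quadratic disagreement weights — linear is the default because the
choice is not dictated by the analysis and linear penalizes adjacent
disagreements least aggressively — with a seeded 2000-replicate
subject-level bootstrap CI.

## Scan-abort model

The running score is the cumulative metric sum scaled by
$1/(n\,\mathrm{TR})$; it is non-decreasing (all metrics are
non-negative), so the first threshold crossing is unique. If a scan
crosses at step $i^\*$ of $n$, the fraction acquired is
$FA = i^\*/n$ and the fraction remaining — the time an abort would save
— is $FR = 1 - FA$. Aggregated over a cohort in which every
non-diagnostic scan is assumed to be repeated (cost $2\,TA$ without
monitoring) and every diagnostic scan costs $TA$:

$$ T_{\text{savings}}(\%) = 100\cdot
\frac{\sum_{TP} FR - \sum_{FP} FA}
     {2(n_{TP}+n_{FN}) + n_{TN} + n_{FP}}. $$

The denominator groups all non-diagnostic scans (detected or not) at
$2\,TA$; the literal reading $2n_{TP}+n_{FN}+n_{TN}+n_{FP}$, which
doubles only detected ones, is available via
`timeSavings(grouping = "printed")`. The cost layer converts minutes to
currency at `slot_cost / slot_minutes` (defaults \$2828 per 45-minute
slot, 4.2-minute scans); currency is rounded to whole dollars only at
the report layer.

`optimizeThresholdForSavings()` grid-searches the union of all final
integrated scores plus midpoints between consecutive candidates, with
ties broken toward the larger threshold (fewer false aborts). Because an
abort's timing — not just its occurrence — enters $FR$, the savings
function is not flat between candidates; the operation is defined as the
optimum over this grid, and the matching oracle test evaluates the same
grid exhaustively.

## The synthetic cohort

No public FIDnav pediatric dataset exists, so the package ships a
forward simulator that reproduces exactly the mechanism the metrics
exploit and nothing more:

$$ s_j(i) = \sum_{\mathbf x} \rho(T_i^{-1}\mathbf x)\,
   c_j(\mathbf x)\, e^{\mathrm i \varphi_j}
   + \text{drift}_j(i) + \text{fluct}_j(i) + \varepsilon_j(i), $$

with an ellipsoidal head phantom $\rho$ (semi-axes 75/90/80 mm on a
24³ grid at 9 mm; trilinear resampling under the rigid pose $T_i$),
Gaussian coil profiles ($\sigma$ = 60 mm) on a 120 mm ring cylinder with
seeded per-coil gain and phase, per-channel linear drift
($10^{-4}$/TR), a quasi-respiratory sinusoid (0.05 %, 4 s period) and
complex Gaussian noise (0.1 % of the per-channel baseline — FIDs are
unencoded whole-volume signals, so their SNR is very high). Spin
history, $B_0$ and flip-angle effects are deliberately omitted: the
simulator validates the *analysis*, not MR physics.

Acquisition defaults mirror the target protocol: TR 1.54 s, 160 TRs
(~4.1 min), 32 channels.

### Motion archetypes and ground-truth grades

Four trajectory archetypes cover the clinically observed patterns:
`still`, `drift` (linear ramp), `abrupt` (step repositioning at event
times), and `continuous` restlessness. The continuous profile is a
mean-reverting walk (OU, $\rho = 0.9$): foam padding keeps a squirming
head wandering within a bounded range, which both matches the phenomenon
and makes the per-TR step size a stable function of the overall
displacement — a pure random walk reaches the same displacement with
wildly varying step sizes (few effective degrees of freedom in the
path), producing unrealistically heterogeneous scores within a grade.

Ground truth is assigned from the k-space-weighted mean displacement of
six reference points on a 60 mm shell (so rotations about every axis
contribute), binned at 0.3/0.8/2/5 mm into grades 5…1. Per-grade target
displacements are 0.12, 0.5, 1.3 and 4.0 mm (mid-bin, grades 5 to 2)
and 6.0 mm for grade 1's open-ended bin. Grades 1–2 use the
continuous profile (motion-prone subjects move throughout the scan),
grade 3–4 mix abrupt and drift, grade 5 is still or barely-moving.
Each trajectory is scaled (two fixed-point iterations; rotations are
mildly nonlinear) so its weighted displacement lands on target, and the
recorded grade is always re-derived from the final trajectory. The
default grade mix is 3/9/12/29/49 per 102 subjects.

These calibration constants were fixed once, by checking that the
default cohort's mean cross-correlation scores are ordered
grade 1 > 2 > 3 > 4 ≥ 5 — the ordering observed in real cohorts — and
were not revisited afterwards.

### What the simulator does *not* emulate

Real navigator data contain swallowing and breathing episodes that mimic
motion, coil-load changes from hands touching the coil, low-SNR
channels far from the head (which inflate ratio metrics and are a large
part of why the reference-change metric performs poorly clinically),
scanner drift structure beyond a linear term, and the full
translation/rotation statistics of real children. Passing tests
therefore demonstrate that the pipeline recovers planted effects under
this mechanism — not that clinical sensitivity/specificity would match;
the published clinical values depend on an unavailable patient cohort
and are treated as cohort-dependent throughout.

## Numerical choices

* Denominator floor $10^{-12}\times\max\lvert s\rvert$ guards synthetic
  divide-by-zero edge cases.
* The correlation metric clamps float round-off into $[0,2]$.
* ROC ties: thresholds at observed values; tie-break low for Youden,
  high for savings optimization (documented asymmetry: the former
  favours sensitivity, the latter avoids false aborts).
* Largest-remainder apportionment converts the grade mix into integer
  counts, reproducing 3/9/12/29/49 at $n = 102$ exactly.
* Every stochastic routine takes an explicit seed; per-replicate and
  per-subject streams are split by a counter scheme below $2^{31}$.
* Problem sizes in the packaged analyses: the acceptance run simulates
  the full 102-subject cohort at 160 TRs × 32 channels and uses
  $b = 1000$ bootstrap replicates; unit tests use 8–16³ grids, 8
  channels and 10–40 TRs, which exercise identical code paths at a
  fraction of the cost.

## Known limitations

* The 2D slice-wise navigator variant, prospective correction, and
  image-artifact rendering are out of scope.
* The cost model excludes technologist latency, recall visits and
  anesthesia economics.
* The simulator's grade thresholds are plausible but uncalibrated
  against real radiologist behaviour; only the *ordering* of grades is
  anchored.
* Weighted-kappa weighting (linear vs quadratic) is a convention choice;
  both are implemented.
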