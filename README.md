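# recurfs

Identify breast cancer recurrence — and *when* it happened — from routinely
collected administrative health events, and build recurrence-free survival
(RFS) data fit for Kaplan–Meier and Cox analyses without chart review.

Registries track diagnosis and death but not recurrence, and chart review
is slow and costly. A recurrence, however, leaves an administrative
footprint: a second cluster of oncology visits, renewed imaging and
biopsy, re-operation, a new chemotherapy or radiation episode. `recurfs`
is for epidemiologists and health-services researchers who have
longitudinal claims/EMR extracts (events + patient baselines) and,
optionally, a chart-reviewed subset to validate against.

## Method

1. **Indicators.** Each patient's event stream is reduced to binary
   indicators restricted to events on/after a *landmark* (definitive
   surgery + 6 calendar months by default; 12/18 supported): second
   surgery, second radiation, a new chemotherapy episode (≥ 3
   administrations), re-imaging, re-biopsy, a visit cluster (≥ 3 oncology
   visits within 90 days, carrying a time window), plus vital status,
   breast-cancer death and stage III.
2. **Classification.** A CART decision tree over the indicators, induced
   by minimizing Gini impurity `1 − Σ p_k²`. Three operating points come
   from one knob — a weight `w` on recurrent-class observations in both
   impurity and leaf votes: `w = 4` (high sensitivity), `w = 1` (high
   accuracy), `w = 0.5` (high PPV).
3. **Dating.** A flagged patient's recurrence date is the evidence date of
   the indicator they met; window indicators contribute
   `start + floor((end − start)/2)`. Undated triggers fall back to the
   earliest dated evidence, then the death date, then the midpoint of the
   remaining follow-up.
4. **RFS.** Days from surgery (diagnosis if no surgery) to the estimated
   recurrence date; non-flagged patients censored at last contact (death
   without recurrence is censoring).
5. **Validation.** Confusion metrics, month-binned timing agreement
   (30.4375-day months), rank-sum comparison of RFS lengths, K–M curves
   with log-rank, per-covariate Cox hazard-ratio direction/significance
   concordance, and Table-1-style characteristic comparisons.

A bundled simulator (`simulate_cohort()`) generates cohorts with this
exact generative structure and known ground truth — 598 patients, 20.2%
recurrence, median 4-year follow-up by default — so the whole pipeline is
testable without data access.

## Worked example

```r
library(recurfs)

co <- simulate_cohort(default_sim_params(), seed = 1)
im <- build_indicator_matrix(co, indicator_config())
labs <- co$labels$recurred[match(rownames(im$matrix), co$labels$patient_id)]
trees <- fit_operating_points(im$matrix, labs)
print(trees$high_ppv)
#> second_chemo?
#>   yes:
#>     [recurrent]
#>   no:
#>     died_of_breast_cancer?
#>       yes:
#>         [recurrent]
#>       ...
```

The induced high-PPV tree reads exactly like the field's rule lists: *a
new chemotherapy episode after the landmark ⇒ recurrent; else breast
cancer death ⇒ recurrent; else …*. Validate all three operating points
against the gold labels:

```r
rep <- validation_report(co, trees)
rep$high_accuracy$confusion
#> tp=123 fp=9 tn=453 fn=13 | sens 90.4% spec 98.1% PPV 93.2% NPV 97.2% acc 96.3%
rep$high_accuracy$agreement
#>      bin  n  pct cum_n cum_pct
#> 1    <=1 22 16.2    22    16.2
#> 2 >1,<=2 40 29.4    62    45.6
#> 3 >2,<=3 44 32.4   106    77.9
#> 4 >3,<=6 10  7.4   116    85.3
#> 5     >6 20 14.7   136   100.0
```

So on this simulated cohort the high-accuracy tree finds 123 of the 136
true recurrences with 9 false flags, and 77.9% of estimated recurrence
dates land within 3 months of the truth (every gold recurrence is
counted; missed ones sit in the `>6` bin). The same report carries the
RFS rank-sum p (0.927), the algorithm-vs-gold log-rank p (0.749) and Cox
concordance (direction match 0.93) — i.e. survival analyses run on the
algorithm's RFS data reproduce the gold-standard conclusions.

Real data enter through three CSV files (`events.csv`, `patients.csv`,
optional `labels.csv`; see `?read_cohort`), and a thin CLI wraps the same
functions: `Rscript inst/cli/recurfs.R simulate|extract|fit|call|validate …`.

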