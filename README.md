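# troponinCEA

Decision-analytic cost-effectiveness model for assessing low-risk
chest-pain patients with the ESC 0/1-h high-sensitivity cardiac troponin T
(hs-cTnT) algorithm in **emergency primary care** instead of admitting them
to hospital, from the Norwegian health-system perspective (2020 EUR).

Hospital admission of patients at low risk of non-ST-elevation acute
coronary syndrome is a major source of avoidable cost and emergency-
department crowding: most such admissions end with a non-specific
discharge diagnosis. This package is aimed at health economists and
emergency-care researchers who want to reproduce, stress, or extend that
comparison.

## The model

Two strategies are compared for the same low-risk patient:

* **Primary-care algorithm** — serial hs-cTnT at the out-of-hours clinic:
  shared EMS transport and consultation, plus the algorithm add-on
  (diagnostics EUR 41, personnel EUR 99 by wages or EUR 137 by tariffs,
  outpatient referrals EUR 52).
* **Hospital standard** — the same shared components, plus an ambulance
  transfer (EUR 559 at probability 0.90 or 0.75) and the mean DRG cost of
  a low-risk admission (EUR 840,664 / 567 = EUR 1483).

Effects are quality-adjusted life years (QALYs). Health loss has two
components, evaluated per scenario:

* waiting: `-(LOS / 8766 h) * d`, with waiting-utility decrement
  `d = 0.232` per year, and
* excess 30-day events: `-r * ΔQ`, where `r` is the arm's 30-day AMI/death
  rate (5/1485 primary care, 2/862 hospital; zero in the base case) and
  `ΔQ ≈ 2.22` is the discounted lifetime QALY difference between an
  average 56-year-old with and without an index AMI (13.3 vs 11.1 QALYs),
  produced by a three-state (non-CVD / CVD / dead) Markov cohort model
  with one-year cycles, half-cycle correction, a CVD mortality hazard
  ratio of 1.6, and 4% annual discounting.

Incremental results are classified on the cost-effectiveness plane
(dominant / dominated / trade-off quadrants), with ICER, net monetary
benefit `λ·ΔQALY − ΔCost`, and verdicts against the Norwegian
willingness-to-pay band (EUR 25,600–76,900 per QALY; in the SW quadrant a
strategy is acceptable when savings per QALY lost exceed the threshold).
A probabilistic sensitivity analysis (beta / gamma / truncated-normal
distributions moment-matched to each parameter) propagates uncertainty
and summarizes it as a cost-effectiveness acceptability curve, and a
budget-impact module scales per-patient savings to national level via
laboratory-catchment coverage. A seeded synthetic-cohort generator stands
in for the patient-level study data.

## Worked example

```r
library(troponinCEA)
b <- run_pipeline(psa_draws = 0, budget = TRUE)
print(b)
```

```
<cea_bundle> scenarios: base_case, conservative
  base_case     delta cost EUR  -1794; delta QALY +0.00050; dominant
  conservative  delta cost EUR  -1672; delta QALY -0.00184; sw_trade
  budget impact at 20 km: discharged 4936 / year
```

In the base case, primary-care assessment saves EUR 1794 per low-risk
patient and gains 0.0005 QALYs (less waiting), so it is **dominant** —
cheaper and better, cost-effective at any threshold. In the conservative
scenario it still saves EUR 1672 but loses about 0.0018 QALYs to the
assumed excess events, a south-west trade-off whose savings per QALY lost
(~EUR 0.9 million; EUR 880,000 when computed from the whole-EUR /
4-decimal rendered pair −1672 / −0.0019) are far above the
willingness-to-accept band, so the verdict stays cost-effective. At
national scale, 4936 avoided admissions per year translate into savings
of EUR 8.3–8.9 million.

```r
tab <- render_report(b)
tab[tab$row %in% c("TOTAL", "LOS_h", "QALY"),
    c("row", "primary_base", "hospital_base", "difference_base")]
```

```
    row primary_base hospital_base difference_base
6 TOTAL      5.2e+02    2314.00000      -1794.0000
7 LOS_h      3.4e+00      22.30000        -18.9000
8  QALY     -9.0e-05      -0.00059          0.0005
```

The diagnostic worked example — the rule-in arm of the algorithm applied
to 1000 patients at 3.6% AMI prevalence (sensitivity 73.8%, specificity
98.7%):

```r
expected_confusion(1000)
```

```
<confusion_counts> n = 1000 (prevalence 0.036)
  TP 27  FP 13  TN 951  FN 9   (diseased 36)
  PPV 0.679  NPV 0.990 (on unrounded expectations)
```

36 patients have an AMI and 13 of the 964 without one are expected to
test false-positive.

## Configuration

All parameters live in one validated configuration
(`inst/extdata/default_config.yaml` documents every field). Overrides can
be passed as a YAML file or a nested list; unknown keys are rejected and
each field carries a provenance label:

```r
p <- load_parameters(list(economics = list(discount_rate = 0)))
```

See the methods vignette (`vignettes/cost-effectiveness-methods.Rmd`) for
the model assumptions, calibration, and limitations.
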