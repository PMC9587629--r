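---
title: "Methods: cost-effectiveness of primary-care troponin triage for low-risk chest pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-effectiveness of primary-care troponin triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troponinCEA)
```

# The decision problem

Patients with chest pain judged at low risk of non-ST-elevation acute
coronary syndrome are routinely admitted to hospital for serial troponin
measurement, although the large majority are discharged with a
non-specific diagnosis. When an out-of-hours (OOH) primary-care clinic can
send samples to a high-sensitivity cardiac troponin T (hs-cTnT)
laboratory, the ESC 0/1-h algorithm allows the same rule-out to happen
without admission. `troponinCEA` models the economic consequences of that
substitution for one average low-risk patient, and scales them to the
national level. All costs are 2020 EUR (NOK converted at 10.73).

Two strategies are compared under two scenarios. The *base case* uses the
most-likely value of every input. The *conservative* scenario replaces
four inputs with their worst case for the primary-care strategy:
personnel time priced by tariffs (EUR 137) instead of wages (EUR 99),
inclusion of excess 30-day events, a lower ambulance probability for
hospital transfer (0.75 instead of 0.90, which shrinks the hospital arm's
cost and so works against primary care), and the upper range of the
primary-care length of stay (4.0 h instead of 3.4 h).

# Cost model

Each arm is an expected-cost decision tree. Both arms share the initial
EMS transport to primary care (EUR 559 at probability 0.29) and the
general consultation (EUR 166); these are assumed identical in the two
settings and cancel exactly in the incremental comparison — the package
builds them from the same component definitions so the cancellation is
structural, and a test perturbs the consultation cost to confirm the
increment is invariant.

Micro-costing conversions follow the national guidelines for economic
evaluation: wages are multiplied by 1.3 for payroll taxes and social
charges (`gross_up(x, "payroll")`), and HELFO reimbursements by 2.0 to
cover other financing sources (`gross_up(x, "helfo")`). The hospital
arm's stay is valued by the cohort DRG mean, EUR 840,664 / 567 = EUR 1483.

**Rounding convention.** Components are rounded to whole EUR *before*
summation, because the published totals (520, 2314, 558, 2230) are sums
of the published rounded components; internally all values are carried at
full precision and rounding happens only at the reporting boundary.
The PSA (below) deliberately skips the whole-EUR rounding: it is a
presentation convention, not part of the model.

# QALY model

Health effects are QALY losses per patient with two additive components.

*Waiting.* A patient waiting `h` hours loses `(h / 8766) * d` QALYs,
where `d = 0.232` is the utility decrement while waiting for rule-out and
8766 = 365.25 × 24. We use 8766 hours per year; 8760 reproduces the same
values at the printed 5-decimal rounding. The decrement 0.232 is the
value jointly implied by the published pairs (22.3 h → 0.00059 QALYs) and
(3.4 h → 0.00009 QALYs); the underlying quality-of-life weight is
published only in supplementary material, so the decrement is exposed in
the configuration.

*Excess events.* Each 30-day AMI/death among non-admitted patients costs
`ΔQ` discounted lifetime QALYs, the difference between remaining QALYs of
an average 56-year-old without (13.3) and with (11.1) an index AMI. The
default `ΔQ = 2.222` is calibrated from the published per-arm cells
(0.00749 = (5/1485)·ΔQ and 0.00515 = (2/862)·ΔQ). These two cells are not
*jointly* consistent with a single ΔQ — they imply 2.2245 and 2.2197
respectively, because each was rounded independently — so 2.222 matches
both within 1e-5 and no single value can match both exactly. AMI and
death events carry the same decrement, matching the published arithmetic
of 5 combined events / 1485; the source does not separate them. In the
base case both arms' event losses are set to zero, since both observed
rates lie below the accepted 1% miss rate.

# Markov model

The lifetime QALY inputs come from a three-state cohort model — non-CVD,
CVD, dead (absorbing) — with one-year cycles from age 56. Background
mortality is Gompertz, `q(a) = 1 − exp(−b·e^{θa})` with defaults
`b = 2e-5`, `θ = 0.095` (adult mortality of plausible Norwegian scale);
annual CVD incidence from the non-CVD state defaults to 0.01. Living with
CVD multiplies the mortality *hazard* by 1.6:
`q_cvd(a) = 1 − (1 − q(a))^{1.6}`, capped at 1 — exponentiating the
survival probability rather than multiplying the probability keeps the
transition well-defined as `q → 1`, and a test covers that region.

A half-cycle correction credits each cycle with the mean of its start-
and end-of-cycle occupancy. Discounting is 4% per year; the first cycle
is discounted by one full year (`discount_from_cycle = 1`), a convention
the source does not state, so it is configurable and tested in both
positions. The lifetime horizon ends when the alive fraction drops below
1e-6 or at age 110, whichever comes first.

**Calibration.** The exact life table and utility weights behind the
published 13.3 / 11.1 remaining-QALY pair are supplementary-only, so the
model is calibrated to them: a mortality scale multiplying the Gompertz
level and a global utility scale multiplying the state utilities
(defaults 0.87 non-CVD, 0.80 CVD). Because discounted QALYs are linear in
the utility scale, the scale is solved in closed form for the first
target at any mortality scale, leaving one-dimensional root finding
(`stats::uniroot`) on the mortality scale for the second:

```{r calibration}
cal <- calibrate_schedules(targets = c(13.3, 11.1))
round(c(mortality_scale = cal$mortality_scale,
        utility_scale = cal$utility_scale,
        achieved_no_event = cal$achieved[1],
        achieved_post_ami = cal$achieved[2]), 4)
```

The achieved values are *calibration targets, not independent
predictions*: hitting 13.3/11.1 shows the calibration machinery works,
not that the mortality schedule is correct. The engine itself is checked
against an independent brute-force per-year scalar loop on randomized
instances, against hand-computed traces, and against closed-form
discounting sums.

# Incremental analysis

Increments are primary care minus hospital; positive ΔQALY favours
primary care. The base case gives ΔCost = −1794 EUR and
ΔQALY = +0.0005 — dominant. The conservative scenario gives
ΔCost = −1672 and ΔQALY ≈ −0.00184: a south-west trade-off, judged by the
willingness-to-accept rule (cost-effective when savings per QALY lost are
*at or above* the threshold; boundary equality counts as cost-effective).
The published ratio of EUR 880,000 per QALY follows from the incremental
pair at its printed precision, −1672 / −0.0019; our unrounded increment
gives ≈ EUR 0.91 million per QALY because the two independently rounded
event cells perturb the fourth decimal of ΔQALY (−0.00184 vs the
published −0.00186 → −0.0019). Either way the ratio sits an order of
magnitude above the Norwegian band (25,600–76,900), so the verdict —
cost-effective in both scenarios — is insensitive to the rounding chain.

```{r incremental}
b <- run_pipeline(psa_draws = 0, budget = FALSE)
b$scenarios$conservative$icer$quadrant
icer(-1672, -0.0019)$icer   # ratio at the printed precision
```

# Probabilistic sensitivity analysis

The PSA samples the base-case parameters: probabilities from beta,
unit costs from gamma, LOS means from normal truncated at zero, each
moment-matched to (mean, SE) with SE defaulting to 20% of the mean where
no standard error is published (the source defers distribution choices to
supplementary figures, so family and SE are package conventions, all
overridable). Out-of-range draws are rejected and resampled — not
truncated — so the matched moments stay interpretable, and the rejection
count is logged in the result. Each draw re-evaluates the unrounded
incremental pipeline; fixing every distribution collapses the PSA to the
deterministic result exactly, which is tested. The acceptability curve
reports, per threshold λ, the fraction of draws with positive net
monetary benefit; the default grid runs 0–150,000 EUR/QALY in 1,000-EUR
steps, covering the Norwegian band.

# Budget impact

Of 7613 annual non-specific chest-pain admissions referred after an OOH
assessment, the fraction within reach of an hs-cTn laboratory is a step
function of distance: the shipped table carries the two published anchor
tiers (on hospital grounds: 31.4% of the 5,367,580 population; within
20 km: 74.7%), and further tiers load from CSV. At 20 km,
`round(7613 × 0.747) = 5687` are assessed; the assessed count is rounded
*first* and the discharged count taken as assessed − hospitalised
(5687 − 751 = 4936), so the split always conserves the total. Savings are
the direct product: 4936 × 1672 = EUR 8.3 million per year. The published
upper bound of 8.6 million does not equal the direct product
4936 × 1794 ≈ 8.9 million; the intermediate rounding behind 8.6 is
unstated, so the package reports the direct product and documents the
discrepancy rather than guessing the path to 8.6.

# Synthetic cohorts

The generator emulates the marginal structure the analysis assumes, not
any real patient-level data. Primary-care cohorts draw triage classes
multinomially with the exact count-based fractions 1311/334/66 of 1711
(rule-out / observation / rule-in — note these are 76.6/19.5/3.9%; the
fractions must sum to 1), admission Bernoulli(0.132), and 30-day events
Bernoulli(5/1485); hospital cohorts are all-admitted with gamma-
distributed per-patient costs (mean EUR 1483, coefficient of variation
0.5 — only the mean is anchored, so the CV is a package default, exposed
in the spec). Length of stay is lognormal, moment-matched to (mean, SD):
the hospital SD (22.0 h) nearly equals its mean, indicating strong right
skew, which the lognormal family captures while guaranteeing positive
values. Events are assigned independently of LOS — no joint structure is
published. Everything is deterministic given the seed.

Passing the 3-Monte-Carlo-SE marginal checks therefore shows that the
generator and the estimators agree with the *assumed* marginals; it says
nothing about covariate structure, LOS–event dependence, or any feature
of real cohorts beyond those marginals.

# Problem sizes and numerical choices

The test suite exercises the cohort checks at n = 1e5 (primary care) and
5e4 (hospital) and the PSA at 1e4 draws — sizes at which 3-SE bands are a
few tenths of a percent and the full suite runs in a few seconds.
Degenerate inputs are handled explicitly: empty cohorts summarize to an
empty sentinel rather than erroring, SD = 0 collapses the LOS
distribution to a point mass, `q = 1` mortality forces the half-cycle
alive credit to exactly 0.5, and a zero QALY difference with non-zero
cost difference is classified as a cost-only comparison instead of being
divided.

# Limitations

* The comparison is theoretical: it combines an observational
  primary-care cohort with administrative hospital data, not a
  randomized implementation study.
* The Markov schedule is calibrated, not sourced from the actual life
  table; only its two QALY outputs are anchored.
* The budget projection assumes admissions distribute uniformly over
  clinics and ignores geography beyond the coverage step function.
* Utilities are for a single average 56-year-old; no age or sex
  stratification.
* The induced-testing fraction (10–15% overuse when troponin becomes
  available in primary care) is stored for sensitivity analyses but
  excluded from base outputs, since those patients are already inside
  the cohort the cost estimates are built on.
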