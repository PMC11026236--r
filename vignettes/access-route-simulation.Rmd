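---
title: "Simulating TAVI access-route feasibility in hemodialysis patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating TAVI access-route feasibility in hemodialysis patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tavisim)
```

## The problem

Patients with end-stage renal disease on hemodialysis (HD) develop medial
arterial calcification that is most severe in the abdominal aorta and the
common iliac arteries — exactly the vessels a transfemoral (TF)
transcatheter aortic valve implantation (TAVI) sheath must traverse. Before
TAVI, the heart team measures each candidate access vessel on CT and decides
which of the access routes — transfemoral, transcervical (TC, carotid),
trans-subclavian (TS), direct aorta (DA), or as a last resort transapical
(TA) — the delivery sheath can use. `tavisim` encodes that decision rule as
a reproducible, testable pipeline: ordinal calcification grading, a
per-vessel diameter criterion, route-level classification, sheath-to-artery
risk ratios, and cohort-level reporting, together with a seeded generator of
synthetic HD cohorts so that every downstream stage can be exercised without
patient data.

## Calcification grading

Two six-level ordinal scales score each vessel at its site of minimal
diameter: the *degree* scale D0–D5 (fraction of the circumference calcified)
and the *range* scale R0–R5 (fraction of the vessel length involved). The
bins are half-open at the lower end — D0 exactly 0%, D1 (0, 25], D2
(25, 50], D3 (50, 75], and D5 exactly 100% — so every percentage maps to
exactly one grade. The published scale leaves the open interval (99, 100)
unassigned between D4 (75, 99] and D5 (100); `grade_from_percent()` assigns
it to grade 4, keeping grade 5 strictly for complete circumferential (or
full-length) calcification. This is the only place the implementation
departs from the printed bin edges, and it only affects percentages above
99%.

The *range* grade is deliberately **not** used by the feasibility rules:
how far a calcified segment extends was not part of the sheath-passage
criterion, and the package carries R grades for description and reporting
only. Vessel tortuosity and all cardiac-structure eligibility factors
(annulus size, coronary height, valve anatomy) are likewise out of scope:
the simulation assumes TAVI is anatomically indicated and asks only which
access route admits the sheath.

## The decision rule

The reference device is the expandable 14-F introducer sheath
(`sheath_14f()`): 6.0 mm nominal outer diameter, transiently expanding to
7.6 mm as the valve passes. Its instructions for use (IFU) require an
access-route diameter above 5.5 mm. The rule implemented by
`required_diameter()` is:

* **IFU mode** — mild calcification (degree ≤ D2): the vessel must exceed
  **5.5 mm**; moderate/severe calcification (≥ D3): the vessel is assumed
  unable to stretch, so it must exceed the full expanded diameter,
  **7.6 mm**.
* **Fully-expanded mode** — every vessel must exceed **7.6 mm** regardless
  of grade; this asks whether the route is safe even at maximal transient
  expansion.

Both thresholds are *strict* inequalities (a 7.6 mm vessel does not pass a
7.6 mm requirement), and because the expanded requirement (7.6 mm) is never
below the IFU one, the set of feasible routes under the expanded criterion
is a subset of the IFU set for every patient — a nesting property the test
suite asserts on randomized profiles.

Routes are chains of vessels, all of which must pass:

| route | chain (distal → proximal) |
|-------|---------------------------|
| TF_R / TF_L | CFA, EIA, CIA (+ abdominal aorta by default) |
| TC_R / TC_L | common carotid artery |
| TS | left subclavian artery |
| DA | ascending aorta (calcification rule, below) |

Whether the TF chain includes the abdominal aorta is configurable
(`include_abdao`): the sheath physically traverses it and it was measured,
but published accounts of the rule do not state the chain explicitly, so
the package makes the inclusive reading the default and exposes the switch.
The transcervical route lies outside the device's IFU; its verdicts carry
`off_ifu = TRUE` so reports can flag it.

Three further rules complete the flow (`assess_patient()` /
`assess_cohort()`):

* **Puncture method** (percutaneous TF): requires a feasible TF side with
  no calcification on either the anterior or the lateral aspect of the
  femoral puncture site.
* **Direct aorta**: requires an insertion zone (outer curvature 5.5–6 cm
  above the annulus) free of calcification *and* atheroma. The package
  requires strictly grade D0 at the insertion site; atheroma is a separate
  boolean because non-contrast CT cannot grade it. A D1 ascending aorta
  therefore fails DA — "absence of calcification" is read literally.
* **Transapical fallback** (`ta_only`): no feasible route remains except,
  at most, the off-IFU transcervical one (TF, TS and DA all infeasible).

One reported row — "preferable to avoid TS" — has no published criterion.
The package's interpretation (`avoid_ts_rule = "left_access"`): the TS
route is feasible but the dialysis access is on the left arm, whose inflow
a left-subclavian sheath would compromise. The rule is configurable
(`"off"` disables it) and its output is labelled interpretive.

## Risk ratios

`sfar()` and `sifar()` compute the sheath outer-to-femoral and
sheath-outer-to-iliofemoral artery ratios with their published major
vascular-complication cut-offs, 1.05 and 0.95. Which sheath diameter enters
the numerator is the caller's choice; the default is the *nominal* 6.0 mm,
because the cut-offs were derived with non-expandable sheaths and their
transfer to expandable devices is not straightforward. Cohort-level
exceedance (`cohort_sifar_exceedance()`) takes each patient's better
(smaller-ratio) side — the side an operator would puncture — since
laterality handling is otherwise unspecified.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts whose *marginal* structure matches the
vascular phenotype of elderly HD patients with aortic stenosis:

* heavily calcified common iliacs (P(D ≥ 3) = 0.5, P(R ≥ 4) = 0.6; mean
  minimal diameters 7.3 / 7.0 mm right / left) and abdominal aorta
  (P(D ∈ {4,5}) = 0.5, P(R ≥ 4) = 0.6);
* nearly clean carotids (P(D0) = 0.95) and ascending aorta
  (P(D ≤ 1) = 0.88);
* an adequate subclavian (mean 8.6 mm) with P(D ≥ 3) = 0.2, reflecting
  ostial calcification;
* mildly calcified femorals (P(D ≤ 1) = 0.7) whose calcification is
  nonetheless extensive in length (P(R ≥ 3) = 0.5);
* external iliacs strictly stochastically less calcified than the common
  iliacs;
* LEAD prevalence 0.181, age ~ Normal(72.2, 7.3²) truncated to [40, 95],
  59.7% male, HD duration log-normal fitted (least squares on log
  quantiles) to median 9 with quartiles [4, 16] years; access
  predominantly left-sided (90%).

Grades are drawn from explicit categorical distributions rather than by
thresholding a latent calcification fraction, because the source data are
reported only at grade level. Within each vessel, diameter and
calcification are coupled through a shared Gaussian latent with correlation
−0.4 (configurable in [−1, 0]): grades are read off their categorical
inverse CDF at the latent quantile, so the categorical marginals are
preserved *exactly* while narrower vessels tend to be more calcified, and
the degree and range grades of a vessel co-vary. LEAD patients receive a
+1 degree-grade shift (capped at 5) on the six iliofemoral vessels,
injecting the expected excess TF-unsuitability; puncture-site
calcification is then drawn conditionally on the resulting femoral degree
grade (probabilities 0.02 → 0.90 across D0 → D5 per aspect).

Values the source describes only qualitatively ("approximately", "almost
half") are fixed here as stated design choices and are not revisited; where
nothing is stated (diameter SDs, the carotid residual categories, the
puncture-probability curve, body surface area SD 0.2 m² — a printed SD of
0.5 m² being physiologically implausible), the defaults are what a
clinician would call realistic for this population. Two deliberate
non-goals: joint outcome rates (such as the fraction TF-suitable) are *not*
calibration targets — tuning the generator to the quantities the engine is
meant to compute would be circular — and no attempt is made to model
intima-versus-media calcification biology or longitudinal progression.
Consequently, passing tests demonstrate that the *rules* and the
*marginals* behave as specified; they do not certify that joint outcome
rates reproduce any particular clinical cohort, whose diameter–grade joint
distribution is unknown.

## Reporting conventions

`format_count_pct()` prints "n (p)" with the percentage rounded to one
decimal **half away from zero** — the convention clinical tables actually
use (5/16 = 31.25% prints as 31.3, 1/16 = 6.25% as 6.3), which banker's
rounding would violate. Denominators follow the table conventions:
whole-cohort for route availability, the TF-suitable subgroup for the
bilateral and puncture rows (printed "n/d (p)"), and the
alternative-approach subgroup for the avoid-TS and TA-only rows. Because
the puncture row is ambiguous in published presentations, the summary
carries the puncture percentage both of the TF-suitable subgroup and of the
whole cohort. The LEAD risk-factor analysis is the unadjusted 2×2 odds
ratio with the Haldane–Anscombe 0.5 correction on zero cells; covariate
adjustment is deliberately out of scope (it is a routine logistic
regression, not part of the decision rule).

## Numerical and testing choices

* Diameters are millimetres throughout; grades percentages in [0, 100].
  Generated diameters are truncated below at 0.5 mm and rounded to 0.1 mm
  (CT reporting resolution); ties at a threshold fail (strict inequality).
* All randomness flows from a single integer seed; classification and
  reporting are pure functions, so a fixed seed and configuration give
  byte-identical CSV/JSON outputs end to end.
* The test suite checks the engine against an independently written
  brute-force rule evaluator on an exhaustive grid (diameters
  {5.0, 5.5, 5.6, 7.5, 7.6, 7.7, 9.0} × grades 0–5 per chain vessel —
  spanning both thresholds from both sides), monotonicity and mode-nesting
  on 10,000 randomized profiles, generator calibration at n = 2000 (every
  configured marginal within 3 binomial standard errors; iliofemoral degree
  marginals are checked on the non-LEAD subgroup, since the LEAD shift
  intentionally distorts them cohort-wide), and risk-factor direction
  (odds ratio > 1) at n = 2000 across 20 seeds. These problem sizes keep
  every property statistically sharp while the whole suite runs in
  seconds.

## Worked example

```{r example}
cfg <- cohort_config(n_patients = 72, seed = 1)
cohort <- simulate_cohort(cfg)
summary(assess_cohort(cohort, mode = "ifu"))
summary(assess_cohort(cohort, mode = "expanded"))
cohort_sifar_exceedance(cohort)
lead_tf_odds(assess_cohort(simulate_cohort(
  cohort_config(n_patients = 2000, seed = 2))))$odds_ratio
```

## Known limitations

* Verdicts are per-vessel threshold checks; real heart-team decisions also
  weigh tortuosity, atheroma burden, annular anatomy and frailty.
* The generator reproduces marginal distributions and one injected
  association (LEAD → iliofemoral calcification); real joint structure
  (e.g. aorto-iliac calcification correlating across vessels) is richer.
* The avoid-TS rule is an interpretation and is flagged as such.
* The 16-F sheath pathway (29-mm valve) is stored as constants only; no
  route logic uses it.
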