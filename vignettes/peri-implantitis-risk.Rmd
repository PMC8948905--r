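---
title: "Scoring peri-implantitis risk: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring peri-implantitis risk: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periRisk)
```

## The scores

Both scores are deterministic rule tables over routinely collected
maintenance-visit data. Every parameter maps to one of three ordered
categories, `low < moderate < high`, and the per-parameter categories are
aggregated into an overall patient risk.

**PRA** uses six periodontal parameters. The numeric cut-offs (closed
upper bounds of the low and moderate ranges) are:

| parameter | low | moderate | high |
|---|---|---|---|
| BOP% | 0–9 | >9–25 | >25 |
| sites with PPD ≥ 5 mm | 0–4 | >4–8 | >8 |
| BL/age (worst site) | 0–0.5 | >0.5–1 | >1 |
| tooth loss (periodontal) | 0–4 | >4–8 | >8 |

plus systemic/genetic status (present → high) and smoking (non/former →
low, <20 cigarettes/day → moderate, heavy smoker → high; former means
quit more than five years before score calculation).

**IRA** keeps BOP% and BL/age, tightens the deep-site cut-offs
(low 0–2, moderate >2–6, high >6), and adds five parameters. Three of
them are deliberately restricted in range:

* *history of stage II–IV periodontitis*: yes → moderate; the high
  category is never assigned;
* *compliance*: two levels only — compliant → low, no maintenance visit
  over a continuous two-year period → high;
* *RM-bone*: tissue-level implant → low; bone-level implant, or a
  measured restoration-margin-to-bone distance < 1.5 mm → high.

*Periodontitis susceptibility* comes from current staging/grading
(stage I → low; stage II/III grade A/B → moderate; grade C at stage ≥ II
or any stage IV → high) and the *prosthesis/plaque score* is low with
fewer than 4 implant sites of Plaque Index > 1, adequate fit and no
cement excess, moderate with supramucosal poor fit, and high with
submucosal poor fit, cement excess, or more than 3 plaque sites. With
multiple implants the implant-level parameters come from the implant
with the highest (RM-bone, then prosthesis) category; remaining ties
break on the smallest implant id so scoring is deterministic.

**Aggregation.** Overall risk is high with at least two high-risk
parameters; low with none high and at most one moderate; moderate in
every other case. Two aggregation corners are not pinned down by the
published prose and were decided here once: (i) exactly one high-risk
parameter with at most one moderate is classed moderate for *both*
scores — the rule is explicit for IRA and we apply the same reading to
PRA, the minimal symmetric assumption; (ii) stage/grade combinations
missing from the published susceptibility row (stage I grade B/C, stage
II grade C) follow the pattern that stage I is low and grade C escalates
to high from stage II upward. Both choices are isolated in
`aggregate_risk()` / `categorize_susceptibility()` and covered by
exhaustive enumeration tests against an independently coded restatement
of the prose rules (all 3^6 and 3^8 category combinations), including a
monotonicity check: raising any single parameter's category never lowers
the overall risk.

**Boundary convention.** Printed ranges such as "0 to 9%", "5 to 8" or
"0 to 0.5" are closed on the right, so a BOP of exactly 25% is moderate
and a BL/age of exactly 0.5 is low. Values falling strictly between two
printed integer bounds (a BOP of 9.5%) take the next category up — ranges
are treated as `(previous bound, bound]` — the only reading under which
the three ranges partition the whole admissible domain.

## Case definition and follow-up

An implant is a peri-implantitis case when probing depth ≥ 6 mm with
bleeding on probing or suppuration coincides with a radiographic bone
level ≥ 3 mm; a patient is a case when any implant is. Bone levels are
consumed as pre-measured millimetres; radiographic image analysis is out
of scope. Event time is measured in years from score calculation to the
first occurrence of peri-implantitis; implants lost for peri-implantitis
count as events, carried by the cohort's explicit event flag rather than
recomputed. Missing mandatory fields are validation errors, never
imputed — the cohort schema assumes complete records, with one
exception: an unmeasured RM-bone distance on a tissue-level implant is
legitimate (implant type alone then decides the category).

## The synthetic cohort generator

Patient-level data of the motivating study are not public, so every
downstream stage is exercised on synthetic cohorts whose *marginals*
emulate the study population at score-calculation time:

* categorical fields use the published counts over n = 73 — compliant
  61/73, history 65/73, tissue-level-only 70/73, smoking 36/20/16/1
  (non / former / current / heavy), susceptibility 13/50/6/4
  (II A/B, III A/B, III C, IV), prosthesis/plaque 48/22/3
  (clean / supramucosal poor fit / high plaque), diabetes 3/73;
* continuous fields are truncated normals matched to published mean/SD —
  age 60.08 (7.96), BOP% 24.29 (21.25) on [0, 100], BL/age 0.59 (0.23)
  on [0, ∞);
* counts are negative binomials matched to mean/SD — tooth loss
  8.44 (4.24), deep sites 7.85 (11.41) — because both are over-dispersed
  and only mean/SD are published; shapes are a modelling choice.

Implants per patient are `1 + Poisson(2.18)` (the study averaged 232/73 ≈
3.2 implants per patient); a bone-level patient receives exactly one
bone-level implant; RM-bone distances are left unmeasured so the category
is driven by implant type, as in the study's reporting; cement excess is
not generated (it does not appear in the published marginals).

Events follow a constant-hazard (exponential) time-to-event process with
one annual rate per overall risk category — defaults 0.005 / 0.010 /
0.043 for low / moderate / high, chosen once to give roughly 18%
cumulative incidence over the censoring window and a high-vs-low/moderate
hazard ratio near the study's ≈ 4.8. A Weibull shape parameter is
available for sensitivity checks. Administrative censoring is uniform on
3–14 years (scores are calculated at least three years before the final
examination). The implants' follow-up clinical fields are then filled so
the case definition, OR-ed over a patient's implants, reproduces the
sampled event flag exactly.

Parameters are sampled **independently** by default. Real risk factors
co-occur (smokers are less compliant, deep sites track bone loss), so a
Gaussian-copula hook (`latent_correlation`) can correlate the latent
uniforms; it defaults to independence because independent marginals make
the generator's behaviour analytically checkable. Consequences to keep in
mind: the generator reproduces published *marginal* composition, not the
real joint distribution, so the simulated overall-risk distribution need
not match the published one (under independence more patients reach two
high-risk parameters than in the real cohort), and passing tests
demonstrate correctness of the scoring and statistics machinery — not
clinical performance of the scores on real patients.

All sampling is inverse-CDF from per-parameter uniforms under a single
seed (`withr::with_seed`), so a config is a complete, reproducible
description of a cohort and the caller's RNG state is untouched.
`sample_event_times()` used standalone draws from the caller's RNG.

## Validation statistics

The patient is the statistical unit throughout. Kaplan–Meier,
the log-rank test and the Cox model are delegated to the `survival`
package; the package's own closed forms (ordinal AUC, kappa, 2×2
reconstruction) are checked in the test suite against independent
routes — brute-force all-pairs Mann–Whitney, `pROC`, `e1071`, a
hand-coded Efron partial likelihood maximised by grid, and a textbook
observed-minus-expected log-rank table.

Numerical choices: Cox ties use Efron's correction (a small cohort
produces few ties and Efron degrades gracefully); confidence intervals
are Wald on the log scale, `exp(β ± 1.96·se)`, consistent with the
asymmetric intervals published for these scores; degenerate fits
(monotone likelihood / complete separation) raise errors instead of
returning extreme hazard ratios; p-values are two-sided with 0.05 as the
significance label. The ordinal ROC uses the score's at-most-two interior
thresholds; its trapezoidal area equals the tie-corrected Mann–Whitney
AUC by construction. In `reconstruct_confusion()` the true-positive count
is rounded half away from zero; with 13 events every printed sensitivity
yields unambiguous integer cells. Metrics with zero denominators return
`NA` with a warning naming the metric rather than propagating `NaN`.

**A kappa discrepancy worth documenting.** The published high-risk
agreement between the two scores (16 both-high, 11 PRA-only, 4 IRA-only,
42 neither, n = 73) gives an unweighted Cohen's kappa of 0.534, not the
printed 0.559. The printed value equals the *chance-agreement* term
p_e = 0.5588 of that same table to three decimals, suggesting a reporting
slip or a different weighting; this package exposes the standard
unweighted formula and asserts the discrepancy in its tests rather than
reverse-engineering the printed number.

Published quantities that require patient-level data (the survival curves,
log-rank p-values, HRs 4.78/3.65, AUCs 0.696/0.754) cannot be recomputed
from summaries; the acceptance suite substitutes parameter-recovery
properties: mean recovered HR within 10% of a true 4.8 with 95%-CI
coverage in [0.92, 0.97] over 500 cohorts of n = 2,000, and log-rank
type-I error within three binomial standard errors of 0.05 over 500
equal-hazard replicates of n = 200. Marginal fidelity of the default
generator is checked at n = 10,000 within ±2 percentage points. These
problem sizes keep each simulation block within seconds while leaving
Monte-Carlo error well inside the asserted bands.

## Limitations

* The generator models the score-time cross-section plus a single
  time-to-first-event process; it does not model score drift during
  maintenance, implant-level clustering of events, or competing risks
  (death, implant loss for other reasons).
* The original unmodified IDRA is not implemented, only the adaptation
  described above; nor is any treatment-decision (CIST) logic.
* BL/age and implant bone level are inputs in millimetres; no image
  measurement or examiner-calibration machinery is included.
* Reports round percentages to two decimals; published tables mix
  rounding and truncation in the second decimal, which is why the count
  checks compare at printed precision (±0.01 points).
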