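---
title: "Models and methods behind copdwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind copdwatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdwatch)
```

`copdwatch` is a rule-based clinical-decision-support engine for the remote
monitoring of COPD patients. This vignette documents the models it
implements, the interpretation choices made where the underlying clinical
tables are ambiguous, the design of the synthetic-data generator, and the
numerical conventions used throughout. Nothing here states an empirical
result beyond what the package's own tests and acceptance script compute.

## 1. The monitoring model

The engine evaluates a set of declarative rules against a per-minute stream
of joined observations (activity, location, indoor and outdoor environment,
vitals). A rule is a safe band or a one-sided limit on a registered
parameter, plus:

* a **context predicate** — activity category, location (with `indoor`
  matching `bedroom` and `living_room`), season, daypart, and optional
  numeric side conditions on other observed fields (e.g. the outdoor
  humidity rule applies only while the outdoor temperature is below 30 °C);
* an optional **exposure window** *W* in minutes;
* a **severity applicability** set over the four protection levels;
* an optional **dynamic schedule** of (exposure, limit) steps.

**Exposure semantics.** A printed constraint such as "exposure limit: 1 h"
is interpreted as: the alarm fires once the violation has persisted *longer
than* the limit, i.e. on the (W+1)-th consecutive violating minute (the
61st minute for a 1-h limit). Rules without a window are the W = 0 case and
fire immediately. The accumulator resets on any compliant or
context-non-matching minute. A missing sensor value freezes the rule: the
accumulator neither grows nor resets, and no alarm can fire on that minute.
The 24-h particulate rules use the same continuous accumulator: a rolling
count of violating minutes within a trailing 24-h window reaches 1440
exactly when all 1440 minutes violate, so the two formulations coincide
when the required exposure equals the window length.

**De-duplication.** A stable violation should not page the patient every
minute. After firing, a rule is disarmed and re-arms only after five
consecutive compliant minutes (`refractory`, configurable). Violation
episodes separated by shorter recoveries are treated as one episode.

**Dynamic thresholds.** A rule may carry a schedule of exposure steps; the
engine tracks the rule's cumulative context exposure (minutes matching the
rule's context within the trailing 24 h) and applies the limit of the
largest step not exceeding it. The shipped example is indoor PM10 for the
low-severity group: 0.150 mg/m³ from zero exposure, tightening to
0.020 mg/m³ once the patient has spent more than 8 h (480 min) in the
room. For an upper limit the schedule is validated non-increasing, so
protection only ever tightens with exposure.

**Reading the printed constraint tables.** The rule tables use the notation
"a < X > b", which is unsatisfiable read literally; it is encoded as
*alarm when X is outside [a, b]*, which is consistent with the bands
bracketing the reference profile's normal ranges. Blood-pressure rows
joined by "AND" are encoded as separate SBP and DBP rules (alarm if either
component leaves its band — the safety-first reading of an ambiguous
conjunction). The living-room temperature row conflicts with the cited
indoor-climate evidence that respiratory recordings are best at and above
21 °C; the shipped rule alarms when the room is *colder* than 21 °C. The
indoor-pressure band of 1013–1018 is treated as hPa, since values of that
magnitude in kPa are physically impossible. The nutrient table is encoded
as printed (including a sodium limit far below dietary norms, noted in the
pack comments); band-type nutrient rules (fiber 15–30 g, vitamin D
800–2000 IU) alarm outside the band, which makes minimum-type rules (e.g.
calcium below 1200 mg) fire at zero intake. Where travel thresholds are
printed inconsistently (SpO₂ 92%/84%-with-6MWT and PaO₂ 50 mmHg in the
activity table versus a 50 mmHg / 85% prose variant), the table values take
precedence.

## 2. Profiles, severity, and band synthesis

A profile carries demographics, GOLD stage, mMRC grade, comorbidities,
medications, baselines for the 11 monitored vitals plus FEV1 (fixed units:
°C, mmHg, bpm, %, mL/kg/min, breaths/min, pH, mmol/L, L — validated on
load, never inferred), and per-activity safe bands.

The four-level **severity grouping** is not printed in the source tables;
the package's mapping is: `low` = GOLD I–II, no comorbidities, under 65;
`moderate` = GOLD I–II with a comorbidity or age ≥ 65; `high` = GOLD III;
`very_high` = GOLD IV or GOLD III with a comorbidity. It is monotone in
stage, and adding a comorbidity never lowers the level — the property the
four "levels of protection" require; the exact cut points are a package
design choice and are configurable at the rulepack level through severity
applicability sets.

Records rarely print bands for every vital × activity combination.
Missing bands are **synthesized from the baselines** using fixed additive
offsets anchored on the one reference record that does print bands (heart
rate baseline 60 bpm with light 60–97, moderate 98–120, vigorous 121–130;
SpO₂ baseline 96.01% with vigorous 91.30–92.6; and so on). Sedentary bands
always bracket the baseline by construction. This keeps every profile
runnable; explicitly supplied bands always win.

## 3. Ambient physiology

* **Hypsometric formula.** The printed scale constant (4430.76923 m) gives
  ≈183 mmHg at 1050 m, which is physically impossible; the standard
  constant 44330.76923 m reproduces textbook values (≈670 mmHg at 1050 m)
  and is the default, with the constant exposed as an argument. Both give
  exactly 760 mmHg at sea level. Domain: 0–11,000 m.
* **Partial pressures** are linear in total pressure with fractions 0.21 /
  0.78 / 0.00038. The computed sea-level CO₂ partial pressure is 0.289 mmHg
  (0.038% × 760); a printed value of 0.02 mmHg is inconsistent with its own
  fraction and is not used.
* **Temperature deltas.** HR responds around a 22 °C threshold and blood
  pressure around 27 °C, on both the cold and hot sides (cold: +0.063 /
  +0.129 / +0.065 per °C for HR/SBP/DBP; hot: +0.133 / +0.605 / +0.128).
  Each delta is continuous and piecewise linear with a single knot; the
  deltas are non-negative because both cold and heat stress raise these
  vitals.
* **Cold-season FEV1 decline** returns the slope product (2.20 mL·°C⁻¹;
  3.64 for FVC). For the warm/cold pair 21.1 °C / 0.78 °C this is
  44.70 mL; the observational median of 44.9 mL reported alongside the
  slope is a different quantity and is not asserted.
* **Resting heart rate** comes from a stage × age-decade reference grid
  (male; stage I at 40–50 years is 72.6 ± 12 bpm rising to 84.9 ± 14 in
  stage IV), shipped as a versioned CSV (`inst/extdata/hr_reference.csv`).
  Modifiers are additive marginal mean changes (smoker +6.6, obese BMI ≥ 30
  +9, inhaler +7, CHF +9.6, anemia +7, PH +10, asthma +8); interactions are
  ignored because only marginal changes are reported. The female offset is
  a constant +3 bpm — the underlying gender curve is published only as a
  figure, so a digitized constant is used and is configurable in the
  reference table. Exercise categories replace the resting value with the
  category reference means (76.3 / 85.5 / 125.6 / 145.3 bpm) scaled by the
  profile's stage-to-stage-I ratio within its age decade. Ages outside
  40–90 clamp to the grid edge with a warning.

## 4. Indoor air quality

Neither source index publishes its sub-index formula. Both are implemented
as EPA-AQI-style piecewise-linear interpolations anchored on the shipped
per-pollutant alarm limits: the comfort scale maps clean air to 100, the
limit to 50 (the printed unhealthy boundary), twice the limit to 25 and
three times the limit to 0; the AQI-style scale maps the limit to 100
points. Category boundaries follow the printed closed ranges
(good 100–76, normal 75–51, unhealthy 50–26, hazardous 25–0), with a
boundary value belonging to the better category. The two scales run in
opposite directions and the sources do not define "most stringent" across
them, so the combination rule is: comfort index = minimum sub-index,
AQI-style index = maximum sub-index, and the alarm is the OR of (comfort
category worse than normal) and (AQI-style index above the 150-point
respiratory-protection threshold).

## 5. The synthetic-data generator

The generator exists to exercise the engine end to end under controlled,
reproducible conditions; its defaults are fixed once and are not tuned to
any test outcome.

**Activities.** Eighteen activity labels (the source enumeration lists 17;
`resting` completes the set) in four intensity categories. A day is tiled
by events drawn from six per-daypart row-stochastic transition matrices
(4-h blocks starting 06:00; the published matrix is figure-only, so the
defaults are hand-authored to respect the documented examples — commuting
high in the morning block, lunch high in the early-afternoon block, sleep
dominating the night blocks). Durations are per-activity truncated
Gaussians; per-day frequency bounds [f_min, f_max] are enforced during
sampling, with satisfiability (Σ f_min × mean duration ≤ 1440) validated at
model construction. Functional capacity maps GOLD I–II to all categories,
GOLD III to at most moderate, and GOLD IV or mMRC ≥ 3 to at most light;
excluded activities get zero probability everywhere. The underlying
principle (capacity restricts participation) is stated by the ICF
framework; the specific mapping is a package choice.

**Environment.** Every outdoor field (temperature, humidity, wind
speed/direction, precipitation, pressure, AQHI, CO, H₂S, NO, NO₂, NOx, O₃,
PM10, PM2.5, SO₂, TRS) and indoor field (temperature, humidity, pressure,
CO₂, VOC, PM2.5, PM10) is generated per minute. Continuous fields follow a
mean-reverting AR(1) process around a seasonal mean (annual sinusoid
peaking mid-July plus a diurnal component), with defaults consistent with
the printed sample rows of the source environmental tables (e.g. indoor
temperature ≈ 21 °C, CO₂ ≈ 680 ppm, VOC ≈ 0.062 ppm, indoor PM10 ≈
9 µg/m³). The real monitoring-station archives behind those tables are not
redistributable; the stochastic process replaces them and reproduces their
structure (seasonality, persistence, plausible levels), not their exact
trajectories. Precipitation is an episodic wet/dry Markov process (snow
below freezing), and outdoor pollutants are scaled up during episodic
pollution events — these episodic fields are therefore *not*
mean-targeted, while the purely mean-reverting fields recover their
configured means to within 2% over a 365-day run (a law-of-large-numbers
check in the test suite).

**Vitals.** Each vital is drawn from a Gaussian centred on the midpoint of
the profile's band for the current activity category, truncated at ±4
standard deviations (SD = band width / 4), so that with a zero anomaly
rate every sample lies within 4 SD of its centre. Heart rate instead
centres on the reference-grid expectation with the grid's spreads (e.g.
SD 14 bpm for stage IV at 40–50 years) — which means heart-rate samples
regularly leave the personal safe bands, and vital-sign alarms dominate
simulated logs; this is a direct consequence of pairing the published
population spreads with personal bands, and alarm counts are deliberately
not asserted anywhere. Ambient conditions shift the centres through the
closed forms of section 3 (temperature deltas applied to minutes spent
outdoors; altitude lowers SpO₂ and raises HR in proportion to the
fractional barometric-pressure drop, gains −20%/+30 bpm per unit drop —
a package choice calibrated to give a few percent SpO₂ depression at
1000–2500 m). Anomaly injection replaces a random vital with a value well
outside its band at a configurable per-minute rate (default 5 × 10⁻⁴) and
records the ground-truth flag, which the evaluation layer uses as the
reference outcome.

**What passing tests do and do not show.** The simulator demonstrates that
the engine's temporal logic, personalization and aggregation behave as
specified on realistic *structure*; it does not validate clinical alarm
quality on real patients, because the environmental trajectories, the
activity model and the anomaly oracle are all synthetic.

## 6. Numerical choices and degenerate inputs

* Band edges are inclusive; an alarm requires strict exit from the band.
* Index boundary values (76, 51, 26) belong to the better category.
* Confusion metrics with a zero denominator return `NA` ("undefined"), not
  an error; the total count must be positive. The published evaluation's
  sensitivity figure (91.14%) is internally inconsistent with its own
  counts — TP/(TP+FN) = 512/568 = 90.14%, corroborated by the published
  false-negative fraction of 9.85% — so the formula value is returned and
  asserted; the published F1 (88.13%) is consistent only with the 91.14
  figure and is likewise not asserted.
* The engine requires strictly increasing timestamps and raises a
  sequencing error otherwise; streams may use POSIXct timestamps or plain
  minute indices (season-dependent contexts need real dates).
* Rule limits may be declared in a non-canonical unit (the dynamic PM10
  rule is stored in mg/m³ exactly as printed); the engine converts to the
  sensor's canonical unit at evaluation, and `dynamic_threshold()` reports
  in the rule's declared unit.
* Seeds: every generator takes an explicit seed; sub-streams of the cohort
  generator derive per-patient seeds by fixed offsets, so patients are
  reproducible individually and jointly.
* Test problem sizes: the randomized engine-equivalence checks use 24-h
  single-parameter streams; the law-of-large-numbers checks use one
  365-day environmental run and 10⁵-sample vital draws; the capacity
  exclusion property scans 10⁴ simulated days. These sizes make the
  stochastic tolerances (3σ bounds) tight while keeping the suite quick.

## 7. Known limitations

* The severity mapping, band-synthesis offsets, female heart-rate offset
  and altitude gains are package choices where the sources give only the
  qualitative principle; all are documented above and encoded in one place
  each.
* The risk-score operation implements only the published danger band
  (total 3–9, with higher totals mapping to the highest band); the
  individual item definitions are not published in the source material.
* No ontology/semantic-web layer is reproduced: the rule semantics are
  implemented natively, not as OWL/SWRL artifacts.
* The engine is single-patient sequential; cohort monitoring iterates
  patients independently (which also guarantees no cross-talk).
* Real sensor acquisition, EHR integration and caregiver interfaces are
  out of scope.
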