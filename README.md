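# copdwatch

Rule-based telemonitoring for patients with chronic obstructive pulmonary
disease (COPD).

Patients with COPD are highly sensitive to context: the "normal" range of a
vital sign depends on the individual medical profile (age, GOLD stage, BMI,
smoking, medication, comorbidities) and on what the patient is doing, while
indoor air quality, weather and altitude act as exacerbation triggers.
`copdwatch` implements a clinical-decision-support engine for remote
monitoring built on that principle: **personalized, activity- and
exposure-dependent safe bands**, evaluated continuously over per-minute
observation streams, with a synthetic-cohort simulator to exercise the whole
pipeline end to end. It is aimed at digital-health researchers who need a
native, testable implementation of dynamic-threshold alarm logic.

## What is inside

* **Patient profiles** — typed medical records carrying baselines for the 11
  monitored vitals plus FEV1 (body temperature, DBP, SBP, heart rate, PaO₂,
  SpO₂, PaCO₂, VO₂, respiration rate, pH, HCO₃, FEV1) and per-activity safe
  bands; a monotone four-level severity grouping scopes rule applicability.
* **Ambient physiology** — the closed forms linking environment to vitals:
  the hypsometric formula `P = 760·(1 − h/44330.76923)^5.255876` (mmHg, m);
  gas partial pressures (21% O₂, 78% N₂, 0.038% CO₂); the altitude
  arterial-oxygen regression `PaO₂_alt = 0.5196·PaO₂_sea + 11.856·FEV1 −
  1.76`; piecewise-linear ambient-temperature effects on HR/SBP/DBP (+0.063
  / +0.129 / +0.065 per °C of cold below 22 °C resp. 27 °C, +0.133 / +0.605
  / +0.128 per °C of heat); cold-season FEV1 decline at 2.20 mL·°C⁻¹; and a
  stage × age resting-heart-rate reference grid with additive profile
  modifiers.
* **Indoor air quality** — per-pollutant piecewise-linear sub-indices on two
  opposite-direction scales (a 0–100 comfort index categorised
  good/normal/unhealthy/hazardous, and an EPA-AQI-style index with a
  150-point health-protection threshold), combined by a most-stringent rule.
* **Declarative rulepacks** — YAML rule files (shipped packs: `vitals`,
  `pollution`, `weather`, `activity`) with safe bands or relational limits,
  context predicates (activity, location, season, side conditions), temporal
  exposure windows, severity applicability, and dynamic schedules that
  tighten a limit as cumulative exposure grows (e.g. indoor PM10:
  0.150 mg/m³, dropping to 0.020 mg/m³ once a low-severity patient has been
  exposed for more than 8 h).
* **Streaming engine** — stateful per-minute evaluation with
  continuous-violation exposure accumulators, alarm de-duplication, frozen
  accumulators on missing sensor values, altitude-travel advisories, 24-h
  nutrient checks and a symptom-score risk band.
* **Simulator** — Markov-chain activities of daily living (18 labels, six
  4-hour dayparts, frequency bounds, functional-capacity exclusions),
  mean-reverting environmental series over the full outdoor/indoor schema,
  and profile-conditioned vitals with anomaly injection.
* **Pipeline & evaluation** — simulate → monitor → aggregate orchestration,
  seasonal alarm tables, and confusion-matrix metrics (accuracy,
  sensitivity, specificity, FNF, FPF, PPV, NPV, F1).

## Worked example

```r
library(copdwatch)

p <- patient_profile(
  id = "demo", age = 51, gender = "male", height = 172, weight = 68,
  smoker = FALSE, gold_stage = "I", mmrc = 2, comorbidities = "GERD",
  medications = c("SABA", "LABA"),
  baselines = c(temperature = 36.95, dbp = 75, sbp = 115, heart_rate = 72,
                pao2 = 78, spo2 = 96, paco2 = 39, vo2 = 2.53,
                respiration_rate = 15, ph = 7.3, hco3 = 25, fev1 = 1.73))
p
#> <copd_profile demo> male, 51 y, GOLD I, mMRC 2, BMI 23.0
#>   comorbidities: GERD
#>   severity group: moderate

activity_band(p, "heart_rate", "light")
#> [72, 109]
```

The profile's own light-exercise heart-rate band (synthesized from the
72 bpm baseline) replaces the pack default when rules are expanded for this
patient. A week of simulated monitoring:

```r
cohort <- generate_cohort(1, 7, seed = 42)   # 1 patient, 7 days, 10,080 records
logs <- run_monitoring(cohort)
aggregate_alarms(logs, by = "category")
#>     vital pollution   weather  activity
#>       866         5        94         0

altitude_travel_check(p, 1200)
#> <travel advisory> altitude 1200 m: ALARM
#>  - Altitude 1200 m exceeds the 1050 m safe limit.

iaqi(c(pm10 = 80, co = 1.5))
#> indoor air quality: 41.7 (unhealthy); AQI-style 133.3; alarm: TRUE
#>   limiting pollutant: pm10 at 80
```

Vital-sign alarms dominate because generated vitals carry the full
reference-grid spreads while safe bands are personal and narrow; the alarm
log records, for every alarm, the violated band, the observed value, the
rule id and a suggestion text. Evaluation against reference outcomes uses
the standard confusion metrics:

```r
confusion_metrics(512, 88, 544, 56)
#> confusion counts: TP 512  FP 88  TN 544  FN 56
#>   accuracy     88%
#>   sensitivity  90.14%
#>   ...
#>   ppv          85.33%
#>   npv          90.67%
```

## Vignette

`vignettes/copdwatch-methods.Rmd` describes the models and their
assumptions, the encoded rule tables and the interpretation choices behind
them, the simulator's design and its limitations, and all numerical
choices (tolerances, tie-breaks, degenerate inputs).
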