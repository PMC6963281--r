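# Biomarker alarms and constraints: default safe bands per activity category
# for the 12 monitored parameters. Bands are the pack-level defaults for a
# reference profile; expand_rulepack() replaces them with the patient's own
# per-activity ranges. "Moderate/vigorous: N min" constraints are encoded as
# exposure windows (continuous violation must exceed N minutes).
name: vitals
version: "1.0"
rules:
- id: sbp_light
  category: vital
  parameter: sbp
  context: {activity: light}
  band: [110.0, 130.0]
  suggestion: "Systolic pressure outside the light-activity band: stop activity and rest."
- id: sbp_moderate
  category: vital
  parameter: sbp
  context: {activity: moderate}
  band: [110.0, 146.0]
  exposure_window: 20.0
  suggestion: "Systolic pressure outside the moderate-activity band for over 20 min: rest and re-measure."
- id: sbp_vigorous
  category: vital
  parameter: sbp
  context: {activity: vigorous}
  band: [110.0, 168.0]
  exposure_window: 15.0
  suggestion: "Systolic pressure outside the vigorous-activity band for over 15 min: stop exercise."
- id: dbp_light
  category: vital
  parameter: dbp
  context: {activity: light}
  band: [70.0, 78.0]
  suggestion: "Diastolic pressure outside the light-activity band: stop activity and rest."
- id: dbp_moderate
  category: vital
  parameter: dbp
  context: {activity: moderate}
  band: [70.0, 78.0]
  exposure_window: 20.0
  suggestion: "Diastolic pressure outside the band for over 20 min: rest and re-measure."
- id: dbp_vigorous
  category: vital
  parameter: dbp
  context: {activity: vigorous}
  band: [70.0, 78.0]
  exposure_window: 15.0
  suggestion: "Diastolic pressure outside the band for over 15 min: stop exercise."
- id: hr_light
  category: vital
  parameter: heart_rate
  context: {activity: light}
  band: [77.0, 113.0]
  suggestion: "Heart rate outside the light-activity band: sit down and breathe slowly."
- id: hr_moderate
  category: vital
  parameter: heart_rate
  context: {activity: moderate}
  band: [80.0, 144.0]
  exposure_window: 60.0
  suggestion: "Heart rate outside the moderate-activity band for over 1 h: stop and rest."
- id: hr_vigorous
  category: vital
  parameter: heart_rate
  context: {activity: vigorous}
  band: [85.0, 160.0]
  exposure_window: 15.0
  suggestion: "Heart rate outside the vigorous-activity band for over 15 min: stop exercise."
- id: spo2_light
  category: vital
  parameter: spo2
  context: {activity: light}
  band: [95.0, 97.0]
  suggestion: "Oxygen saturation outside the light-activity band: rest; use oxygen if prescribed."
- id: spo2_moderate
  category: vital
  parameter: spo2
  context: {activity: moderate}
  band: [94.0, 96.0]
  exposure_window: 30.0
  suggestion: "Oxygen saturation outside the band for over 30 min: rest; contact caregiver if persistent."
- id: spo2_vigorous
  category: vital
  parameter: spo2
  context: {activity: vigorous}
  band: [91.0, 96.0]
  exposure_window: 15.0
  suggestion: "Oxygen saturation outside the band for over 15 min: stop exercise immediately."
- id: temp_light
  category: vital
  parameter: temperature
  context: {activity: light}
  band: [37.0, 38.1]
  suggestion: "Body temperature outside the light-activity band."
- id: temp_moderate
  category: vital
  parameter: temperature
  context: {activity: moderate}
  band: [37.8, 38.4]
  suggestion: "Body temperature outside the moderate-activity band."
- id: temp_vigorous
  category: vital
  parameter: temperature
  context: {activity: vigorous}
  band: [38.0, 38.8]
  exposure_window: 20.0
  suggestion: "Body temperature outside the band for over 20 min: stop and cool down."
- id: pao2_light
  category: vital
  parameter: pao2
  context: {activity: light}
  band: [75.0, 80.0]
  suggestion: "Arterial oxygen outside the light-activity band."
- id: pao2_moderate
  category: vital
  parameter: pao2
  context: {activity: moderate}
  band: [78.0, 85.0]
  exposure_window: 60.0
  suggestion: "Arterial oxygen outside the band for over 1 h."
- id: pao2_vigorous
  category: vital
  parameter: pao2
  context: {activity: vigorous}
  band: [80.0, 98.0]
  exposure_window: 15.0
  suggestion: "Arterial oxygen outside the band for over 15 min: stop exercise."
- id: paco2_light
  category: vital
  parameter: paco2
  context: {activity: light}
  band: [36.0, 42.0]
  suggestion: "Arterial CO2 outside the light-activity band."
- id: paco2_moderate
  category: vital
  parameter: paco2
  context: {activity: moderate}
  band: [35.0, 40.0]
  exposure_window: 60.0
  suggestion: "Arterial CO2 outside the band for over 1 h."
- id: paco2_vigorous
  category: vital
  parameter: paco2
  context: {activity: vigorous}
  band: [30.0, 36.0]
  exposure_window: 15.0
  suggestion: "Arterial CO2 outside the band for over 15 min: stop exercise."
- id: rr_light
  category: vital
  parameter: respiration_rate
  context: {activity: light}
  band: [14.0, 20.0]
  suggestion: "Respiration rate outside the light-activity band: practice pursed-lip breathing."
- id: rr_moderate
  category: vital
  parameter: respiration_rate
  context: {activity: moderate}
  band: [15.0, 35.0]
  exposure_window: 60.0
  suggestion: "Respiration rate outside the band for over 1 h."
- id: rr_vigorous
  category: vital
  parameter: respiration_rate
  context: {activity: vigorous}
  band: [20.0, 50.0]
  exposure_window: 15.0
  suggestion: "Respiration rate outside the band for over 15 min: stop exercise."
- id: fev1_light
  category: vital
  parameter: fev1
  context: {activity: light}
  band: [2.5, 2.7]
  suggestion: "FEV1 outside the light-activity band."
- id: fev1_moderate
  category: vital
  parameter: fev1
  context: {activity: moderate}
  band: [2.4, 2.7]
  exposure_window: 30.0
  suggestion: "FEV1 outside the band for over 30 min."
- id: fev1_vigorous
  category: vital
  parameter: fev1
  context: {activity: vigorous}
  band: [2.2, 2.7]
  exposure_window: 10.0
  suggestion: "FEV1 outside the band for over 10 min: stop exercise."
- id: vo2_light
  category: vital
  parameter: vo2
  context: {activity: light}
  band: [2.5, 6.5]
  suggestion: "Oxygen consumption outside the light-activity band."
- id: vo2_moderate
  category: vital
  parameter: vo2
  context: {activity: moderate}
  band: [3.09, 9.7]
  exposure_window: 20.0
  suggestion: "Oxygen consumption outside the band for over 20 min."
- id: vo2_vigorous
  category: vital
  parameter: vo2
  context: {activity: vigorous}
  band: [4.3, 11.8]
  exposure_window: 10.0
  suggestion: "Oxygen consumption outside the band for over 10 min: stop exercise."
- id: ph_light
  category: vital
  parameter: ph
  context: {activity: light}
  band: [7.18, 7.34]
  suggestion: "Blood pH outside the light-activity band."
- id: ph_moderate
  category: vital
  parameter: ph
  context: {activity: moderate}
  band: [7.05, 7.24]
  exposure_window: 60.0
  suggestion: "Blood pH outside the band for over 1 h."
- id: ph_vigorous
  category: vital
  parameter: ph
  context: {activity: vigorous}
  band: [6.93, 7.12]
  exposure_window: 60.0
  suggestion: "Blood pH outside the band for over 1 h: seek assessment."
- id: hco3_light
  category: vital
  parameter: hco3
  context: {activity: light}
  band: [20.0, 30.0]
  suggestion: "Bicarbonate outside the light-activity band."
- id: hco3_moderate
  category: vital
  parameter: hco3
  context: {activity: moderate}
  band: [16.0, 26.0]
  exposure_window: 60.0
  suggestion: "Bicarbonate outside the band for over 1 h."
- id: hco3_vigorous
  category: vital
  parameter: hco3
  context: {activity: vigorous}
  band: [15.0, 24.0]
  exposure_window: 60.0
  suggestion: "Bicarbonate outside the band for over 1 h: seek assessment."
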