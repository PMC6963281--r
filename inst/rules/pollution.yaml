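# Indoor pollutant alarms: upper limits with exposure windows ("Exposure
# Limit: N h" = alarm after more than N hours of continuous excess).
# pm10_dynamic is the exposure-dependent rule: the safe-zone limit for a
# low-severity patient tightens from 0.150 mg/m3 to 0.020 mg/m3 once indoor
# exposure exceeds 8 h; its limits are expressed in mg/m3 (the engine
# converts to the ug/m3 sensor unit at evaluation).
name: pollution
version: "1.0"
rules:
- id: co_1h
  category: pollution
  parameter: co
  context: {location: indoor}
  limit: {direction: above, value: 2.0}
  exposure_window: 60.0
  suggestion: "Carbon monoxide above 2 ppm for over 1 h: ventilate and leave the room."
- id: hcho_1h
  category: pollution
  parameter: hcho
  context: {location: indoor}
  limit: {direction: above, value: 0.04}
  exposure_window: 60.0
  suggestion: "Formaldehyde above 0.04 ppm for over 1 h: ventilate."
- id: tvoc_1h
  category: pollution
  parameter: tvoc
  context: {location: indoor}
  limit: {direction: above, value: 0.9}
  exposure_window: 60.0
  suggestion: "Volatile organic compounds above 0.9 ppm for over 1 h: ventilate."
- id: co2_8h
  category: pollution
  parameter: co2
  context: {location: indoor}
  limit: {direction: above, value: 600.0}
  exposure_window: 480.0
  suggestion: "CO2 above 600 ppm for over 8 h: air the room."
- id: pm10_24h
  category: pollution
  parameter: indoor_pm10
  context: {location: indoor}
  limit: {direction: above, value: 60.0}
  exposure_window: 1440.0
  suggestion: "PM10 above 60 ug/m3 for over 24 h: use air filtration."
- id: pm25_24h
  category: pollution
  parameter: indoor_pm25
  context: {location: indoor}
  limit: {direction: above, value: 45.0}
  exposure_window: 1440.0
  suggestion: "PM2.5 above 45 ug/m3 for over 24 h: use air filtration."
- id: o3_8h
  category: pollution
  parameter: o3_indoor
  context: {location: indoor}
  limit: {direction: above, value: 0.03}
  exposure_window: 480.0
  suggestion: "Ozone above 0.03 ppm for over 8 h: ventilate."
- id: bacteria_now
  category: pollution
  parameter: bacteria
  context: {location: indoor}
  limit: {direction: above, value: 600.0}
  suggestion: "Airborne bacteria above 600 CFU/m3: no tolerance, leave and sanitise the room."
- id: no2_8h
  category: pollution
  parameter: no2_indoor
  context: {location: indoor}
  limit: {direction: above, value: 5.0}
  exposure_window: 480.0
  suggestion: "Nitrogen dioxide above 5 ppm for over 8 h: ventilate."
- id: so2_8h
  category: pollution
  parameter: so2_indoor
  context: {location: indoor}
  limit: {direction: above, value: 0.06}
  exposure_window: 480.0
  suggestion: "Sulfur dioxide above 0.06 ppm for over 8 h: ventilate."
- id: h2s_8h
  category: pollution
  parameter: h2s_indoor
  context: {location: indoor}
  limit: {direction: above, value: 1.0}
  exposure_window: 480.0
  suggestion: "Hydrogen sulfide above 1 ppm for over 8 h: ventilate."
- id: no_8h
  category: pollution
  parameter: no_indoor
  context: {location: indoor}
  limit: {direction: above, value: 25.0}
  exposure_window: 480.0
  suggestion: "Nitric oxide above 25 ppm for over 8 h: ventilate."
- id: nox_8h
  category: pollution
  parameter: nox_indoor
  context: {location: indoor}
  limit: {direction: above, value: 10.0}
  exposure_window: 480.0
  suggestion: "Nitrogen oxides above 10 ppm for over 8 h: ventilate."
- id: trs_4h
  category: pollution
  parameter: trs_indoor
  context: {location: indoor}
  limit: {direction: above, value: 10.0}
  exposure_window: 240.0
  suggestion: "Total reduced sulfur above 10 ppm for over 4 h: ventilate."
- id: pm10_dynamic
  category: pollution
  parameter: indoor_pm10
  unit: "mg/m3"
  context: {location: indoor}
  limit: {direction: above, value: 0.150}
  severity: [low]
  dynamic:
  - {exposure: 0.0, limit: 0.150}
  - {exposure: 480.0, limit: 0.020}
  suggestion: "PM10 above the exposure-adjusted safe limit: ventilate or change rooms."
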