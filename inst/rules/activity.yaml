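# Activity and daily-living alarms: aerobic-training endurance, travel /
# altitude checks, and 24 h nutrient intake limits. Nutrient rules are
# evaluated on daily totals by nutrition_check(), not on the per-minute
# stream. The sodium limit (180 mg / 24 h) is encoded as printed in the
# source table although it is far below dietary norms; likewise the glucose
# limit's unit (mg).
name: activity
version: "1.0"
rules:
- id: aerobic_training
  category: activity
  parameter: activity_duration
  context: {activity: vigorous}
  limit: {direction: above, value: 30.0}
  suggestion: "Aerobic training beyond 30 min endurance time: stop and rest."
- id: travel_spo2
  category: activity
  parameter: spo2
  context:
    when:
    - {parameter: altitude, min: 800.0}
  limit: {direction: below, value: 92.0}
  suggestion: "SpO2 below 92% at altitude: supplemental oxygen required for travel."
- id: travel_spo2_6mwt
  category: activity
  parameter: spo2
  context:
    when:
    - {parameter: altitude, min: 800.0}
    - {parameter: activity_duration, min: 6.0}
  limit: {direction: below, value: 84.0}
  suggestion: "SpO2 below 84% on walking test at altitude: do not travel without oxygen."
- id: travel_pao2
  category: activity
  parameter: pao2
  context:
    when:
    - {parameter: altitude, min: 800.0}
  limit: {direction: below, value: 50.0}
  suggestion: "PaO2 below 50 mmHg: cannot travel without supplemental oxygen."
- id: mountain_altitude
  category: activity
  parameter: altitude
  context: {location: outdoor}
  limit: {direction: above, value: 1050.0}
  suggestion: "Altitude above 1050 m: descend or use supplemental oxygen."
- id: sodium_24h
  category: activity
  parameter: sodium
  limit: {direction: above, value: 180.0}
  suggestion: "Daily sodium intake above limit."
- id: fructose_24h
  category: activity
  parameter: fructose
  limit: {direction: above, value: 25.0}
  suggestion: "Daily fructose intake above 25 g."
- id: glucose_24h
  category: activity
  parameter: glucose
  limit: {direction: above, value: 20.0}
  suggestion: "Daily glucose intake above limit."
- id: calcium_24h
  category: activity
  parameter: calcium
  limit: {direction: below, value: 1200.0}
  suggestion: "Daily calcium intake below 1200 mg."
- id: vitamin_d_24h
  category: activity
  parameter: vitamin_d
  band: [800.0, 2000.0]
  suggestion: "Daily vitamin D outside 800-2000 IU."
- id: vitamin_c_24h
  category: activity
  parameter: vitamin_c
  limit: {direction: above, value: 1000.0}
  suggestion: "Daily vitamin C above 1000 mg."
- id: vitamin_a_24h
  category: activity
  parameter: vitamin_a
  limit: {direction: above, value: 850.0}
  suggestion: "Daily vitamin A above 850 mcg."
- id: vitamin_e_24h
  category: activity
  parameter: vitamin_e
  limit: {direction: above, value: 900.0}
  suggestion: "Daily vitamin E above 900 IU."
- id: vitamin_b12_24h
  category: activity
  parameter: vitamin_b12
  limit: {direction: above, value: 2.2}
  suggestion: "Daily vitamin B12 above 2.2 mcg."
- id: iron_24h
  category: activity
  parameter: iron
  limit: {direction: above, value: 35.0}
  suggestion: "Daily iron above 35 mg."
- id: zinc_24h
  category: activity
  parameter: zinc
  limit: {direction: above, value: 40.0}
  suggestion: "Daily zinc above 40 mg."
- id: magnesium_24h
  category: activity
  parameter: magnesium
  limit: {direction: above, value: 435.0}
  suggestion: "Daily magnesium above 435 mg."
- id: carbohydrate_24h
  category: activity
  parameter: carbohydrate
  limit: {direction: above, value: 380.0}
  suggestion: "Daily carbohydrate above 380 g."
- id: protein_24h
  category: activity
  parameter: protein
  limit: {direction: above, value: 80.0}
  suggestion: "Daily protein above 80 g."
- id: fat_24h
  category: activity
  parameter: fat
  limit: {direction: above, value: 75.0}
  suggestion: "Daily fat above 75 g."
- id: fiber_24h
  category: activity
  parameter: fiber
  band: [15.0, 30.0]
  suggestion: "Daily fiber outside 15-30 g."
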