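# Weather / climate alarms, indoor and outdoor. Notes on the encoded
# interpretations:
#   - living_room_temperature alarms when the room is COLDER than 21 C
#     (optimal respiratory recordings are obtained at and above 21 C).
#   - indoor_pressure band is 1013-1018 hPa (values of that magnitude in kPa
#     are physically impossible).
#   - rainfall/snowfall limits are stored in mm (0.2 cm = 2 mm, 5 cm = 50 mm).
name: weather
version: "1.0"
rules:
- id: bedroom_temperature
  category: weather
  parameter: indoor_temperature
  context: {location: bedroom}
  band: [18.0, 18.5]
  exposure_window: 540.0
  suggestion: "Bedroom temperature outside 18-18.5 C for over 9 h overnight: adjust heating."
- id: living_room_temperature
  category: weather
  parameter: indoor_temperature
  context: {location: living_room}
  limit: {direction: below, value: 21.0}
  suggestion: "Living room below 21 C: raise the thermostat."
- id: indoor_humidity
  category: weather
  parameter: indoor_humidity
  context: {location: indoor}
  band: [30.0, 50.0]
  suggestion: "Indoor humidity outside 30-50%: humidify or dehumidify."
- id: indoor_pressure
  category: weather
  parameter: indoor_pressure
  context: {location: indoor}
  band: [1013.0, 1018.0]
  suggestion: "Indoor pressure outside 1013-1018 hPa: check ventilation pressurisation."
- id: outdoor_humidity
  category: weather
  parameter: outdoor_humidity
  context:
    location: outdoor
    when:
    - {parameter: outdoor_temperature, max: 30.0}
  limit: {direction: above, value: 75.0}
  suggestion: "Outdoor humidity above 75%: limit time outside."
- id: outdoor_heat
  category: weather
  parameter: outdoor_temperature
  context: {location: outdoor}
  limit: {direction: above, value: 27.0}
  exposure_window: 30.0
  suggestion: "Hot weather above 27 C for over 30 min: move to shade and hydrate."
- id: outdoor_cold
  category: weather
  parameter: outdoor_temperature
  context: {location: outdoor}
  limit: {direction: below, value: 14.0}
  exposure_window: 30.0
  suggestion: "Cold weather below 14 C for over 30 min: go indoors and cover airways."
- id: outdoor_very_cold
  category: weather
  parameter: outdoor_temperature
  context: {location: outdoor}
  limit: {direction: below, value: 5.0}
  exposure_window: 15.0
  suggestion: "Very cold weather below 5 C for over 15 min: go indoors immediately."
- id: outdoor_pressure
  category: weather
  parameter: outdoor_pressure
  context:
    location: outdoor
    when:
    - {parameter: outdoor_temperature, min: 15.0, max: 25.0}
  limit: {direction: below, value: 89.325}
  suggestion: "Low atmospheric pressure (below 89.325 kPa): avoid exertion outdoors."
- id: wind_gust
  category: weather
  parameter: wind_speed
  context: {location: outdoor}
  limit: {direction: above, value: 12.0}
  exposure_window: 15.0
  suggestion: "Wind above 12 mph for over 15 min: shelter from the wind."
- id: wind_sustained
  category: weather
  parameter: wind_speed
  context: {location: outdoor}
  limit: {direction: above, value: 7.0}
  exposure_window: 60.0
  suggestion: "Wind above 7 mph for over 1 h: limit time outside."
- id: rainfall
  category: weather
  parameter: precipitation
  context: {location: outdoor}
  limit: {direction: above, value: 2.0}
  suggestion: "Rainfall above 2 mm: stay indoors."
- id: snowfall
  category: weather
  parameter: snowfall
  context: {location: outdoor}
  limit: {direction: above, value: 50.0}
  suggestion: "Snowfall above 5 cm: stay indoors."
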