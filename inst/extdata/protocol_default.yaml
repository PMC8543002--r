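# Default 7 x 3 min lap protocol: four segments per lap with fixed inclines and
# intensity-dependent treadmill speeds. Segment 4 is a simulated downhill skied
# at a safe treadmill speed (20 km/h); whole-session distance and mean speed are
# reported with the display speeds below substituted for segment 4.
laps: 7
lap_duration_s: 180
downhill_display_speed_li_kmh: 30
downhill_display_speed_hi_kmh: 35
segments:
  - {incline_pct: 5,  speed_li_kmh: 12.6, speed_hi_kmh: 16.9, duration_s: 60}
  - {incline_pct: 2,  speed_li_kmh: 19.0, speed_hi_kmh: 25.0, duration_s: 50}
  - {incline_pct: 12, speed_li_kmh: 10.0, speed_hi_kmh: 13.0, duration_s: 40}
  - {incline_pct: -5, speed_li_kmh: 20.0, speed_hi_kmh: 20.0, duration_s: 30}
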