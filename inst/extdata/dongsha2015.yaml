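# Synthetic reef-flat scenario: steady trades collapsing for a week in
# mid-June over a neap tide, with a 2 degC offshore SST anomaly.
latitude: 20.7
start: "2015-06-01 00:00:00"
end: "2015-06-20 00:00:00"
timestep_min: 1
wind_baseline: 8
wind_event:
  start: "2015-06-08 00:00:00"
  end: "2015-06-16 00:00:00"
  mean: 2
  airtemp_delta: 2
  rh_mean: 88
cloud_base: 0.3
airtemp_mean: 29
airtemp_amplitude: 1.5
rh_mean: 80
pressure_hpa: 1010
offshore_base: 29.6
offshore_anomaly: 2
anomaly_ramp_days: 10
exchange_coefficient: 0.3
flushing_length: 2000
current_tidal_coef: 0.05
current_wind_coef: 0.024
depth: 2
seed: 1
constituents:
  - {name: M2, amplitude_m: 0.50, phase_rad: 0.0, period_hr: 12.4206012}
  - {name: S2, amplitude_m: 0.20, phase_rad: 0.0, period_hr: 12.0}
  - {name: K1, amplitude_m: 0.30, phase_rad: 0.0, period_hr: 23.9344697}
  - {name: O1, amplitude_m: 0.25, phase_rad: 0.0, period_hr: 25.8193417}
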