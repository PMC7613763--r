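# Example cardiopore pipeline configuration.
# Missing keys fall back to the package defaults, which reproduce the
# optimized reference protocol (1 Vpp, 200 us phase, 1 ms IPI, 25,000
# pulses, 200 electrodes of 4 um diameter, random selection).
culture:
  amplitude_mv: 100
  t_dep_ms: 10
  apd90_ms: 300
  rep_width_ms: 20
  rate_bpm: 30
  cv: 0.05
protocol:
  vpp_v: 1
  phase_us: 200
  ipi_ms: 1
  n_pulses: 25000
  n_electrodes: 200
  selection_strategy: random
  electrode_area_um2: 12.6
classifier:
  min_peak_uv: 500
  min_width_ms: 25
  yield_min_amp_mv: 1
  settle_delay_s: 9
simulate:
  fs_hz: 2000
  duration_s: 30
  poration_at_s: 10
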