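lung:
  R_cmH2O_s_L: 3.0
  C_mL_cmH2O: 30.0
  peep_cmH2O: 8.0
  label: healthy
diverter:
  flow_L_min: 30.0
  eta_insp: 0.6945
  R_EC_open: 77.86
  R_EC_span: 57.57
  delta_EC: 0.75
  R_SC_open: 25.0
  R_SC_span: 25.0
  P_high_base: 20.0
  k_SC: 8.0
  k_FC: 8.0
  P_low_base: 8.0
  m_SC: 4.0
  m_FC: 4.0
screws:
  EC: 0.5
  FC: 0.5
  SC: 0.5
trigger:
  enabled: no
  interval_s: 4.0
  amplitude_cmH2O: 3.0
sim:
  dt_s: 0.001
  duration_s: 60.0
  transient_discard: 2
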