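# Demo run configuration: small seeded cohorts of every experiment type.
seed: 101
noise:
  sigma: 10
  dt: 0.2
cohorts:
  - type: binding
    mode: [3p5p]
    test_force: [56]
    filament_nt: [700]
    n_traces: 4
  - type: control
    test_force: [56]
    n_traces: 3
  - type: exchange
    rate: 0.21
    pulled_strand: outgoing
    n_traces: 6
  - type: exchange
    rate: 0.12
    pulled_strand: complementary
    n_traces: 6
calibration:
  bead_scale: 1.05
  sigma: 0
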