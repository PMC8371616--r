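# Example scenario configuration (flat key/value, control-panel names).
# ARDS2 lung under volume-controlled assist control.
label: ards2_vcac_example
lung_model: ARDS2
run_enable: yes
control_mode: volume
respiration_rate: 20
inspiratory_time: 1.0
maximum_volume: 300
maximum_pressure: 40
trigger_threshold: -2   # relative to PEEP -> 8 cmH2O absolute
peep: 10
peep_minimum: 2
pip: 35
duration: 78
seed: 1
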