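# Outcome binding, no eye-movement control: AS vs SO, sound-time report.
experiment_id: exp1
conditions: [AS, SO]
n_timing: 50
n_catch: 50
n_probe_per_location: 30
probe_locations_deg: [-50, -30, -10, 10, 30, 50]
event_delay_ms: 250
report_task: sound-time
revolution_ms: 1800
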