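# Action binding: AS vs AO, keypress-time report, 11 probe locations from the
# keypress (-50 deg = 0 ms) to 500 ms after it.
experiment_id: exp4
conditions: [AS, AO]
n_timing: 50
n_catch: 100
n_probe_per_location: 30
probe_locations_deg: [-50, -40, -30, -20, -10, 0, 10, 20, 30, 40, 50]
event_delay_ms: 250
report_task: keypress-time
revolution_ms: 1800
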