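# Attention-matched control: AS vs VS (vibration replaces keypress), reduced
# trial counts (170 per condition).
experiment_id: exp3
conditions: [AS, VS]
n_timing: 30
n_catch: 20
n_probe_per_location: 20
probe_locations_deg: [-50, -30, -10, 10, 30, 50]
event_delay_ms: 250
report_task: sound-time
revolution_ms: 1800
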