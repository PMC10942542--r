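# Small shared fixtures, built in code at test time.

tiny_design <- function(n_timing = 6, n_catch = 4, n_probe = 5) {
  experiment_design(
    experiment_id = "tiny",
    conditions = c("AS", "SO"),
    n_timing = n_timing, n_catch = n_catch,
    n_probe_per_location = n_probe,
    probe_locations_deg = c(-50, -30, -10, 10, 30, 50),
    report_task = "sound-time"
  )
}

tiny_trials <- function(n_participants = 4, seed = 42, noise = 30, ...) {
  simulate_experiment(tiny_design(), default_fields("outcome")[c("AS", "SO")],
                      observer_params(report_noise_sd = noise),
                      n_participants = n_participants, seed = seed, ...)
}

# hand-rolled trial rows for exact-count tests
manual_trials <- function(rows) {
  defaults <- tibble::tibble(
    participant_id = "P1", experiment_id = "man", condition = "AS",
    trial_type = "probe", probe_location_deg = NA_real_,
    detected = NA_integer_, actual_event_angle_deg = 0,
    reported_angle_deg = NA_real_, keypress_to_sound_ms = NA_real_
  )
  dplyr::bind_rows(lapply(rows, function(r) {
    out <- defaults
    for (nm in names(r)) out[[nm]] <- r[[nm]]
    out
  }))
}
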