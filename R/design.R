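#' Experiment design
#'
#' Trial counts, probe grid, clock speed and event timing that drive both
#' the simulator and the preprocessing contracts. Outcome-binding designs
#' probe six locations around the sound (`-50, -30, -10, 10, 30, 50`
#' degrees, i.e. -250 ... 250 ms with the sound at 0); the action-binding
#' design probes eleven locations from the keypress (`-50` deg = 0 ms) to
#' 500 ms after it in 50 ms steps.
#'
#' @param experiment_id Identifier, e.g. `"exp1"`.
#' @param conditions Character vector, subset of `c("AS","SO","VS","AO")`.
#' @param n_timing Timing-report trials per condition.
#' @param n_catch Catch trials (no probe) per condition.
#' @param n_probe_per_location Probe trials per probe location per condition.
#' @param probe_locations_deg Probe locations, degrees relative to the
#'   judged event.
#' @param event_delay_ms Keypress-to-sound delay, milliseconds.
#' @param report_task `"sound-time"` or `"keypress-time"`: which event's
#'   clock position is reported. Determines the report-time grid `T_k`
#'   associated with the probe locations.
#' @param clock A [clock_config()].
#' @return An object of class `experiment_design`.
#' @seealso [design_preset()] for the four shipped presets.
#' @export
experiment_design <- function(experiment_id,
                              conditions,
                              n_timing,
                              n_catch,
                              n_probe_per_location,
                              probe_locations_deg,
                              event_delay_ms = 250,
                              report_task = c("sound-time", "keypress-time"),
                              clock = clock_config()) {
  report_task <- match.arg(report_task)
  check_clock_config(clock)
  stopifnot(
    is.character(experiment_id), length(experiment_id) == 1,
    all(conditions %in% c("AS", "SO", "VS", "AO")), length(conditions) >= 1,
    n_timing >= 1, n_catch >= 1, n_probe_per_location >= 1,
    length(probe_locations_deg) >= 2,
    !is.unsorted(probe_locations_deg, strictly = TRUE),
    event_delay_ms >= 0
  )
  structure(
    list(
      experiment_id = experiment_id,
      conditions = conditions,
      n_timing = as.integer(n_timing),
      n_catch = as.integer(n_catch),
      n_probe_per_location = as.integer(n_probe_per_location),
      probe_locations_deg = as.numeric(probe_locations_deg),
      event_delay_ms = event_delay_ms,
      report_task = report_task,
      clock = clock
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", x$experiment_id, ": ",
      paste(x$conditions, collapse = "/"),
      ", ", trials_per_condition(x), " trials/condition (",
      x$n_timing, " timing + ", x$n_catch, " catch + ",
      x$n_probe_per_location, " x ", length(x$probe_locations_deg),
      " probe), ", x$report_task, " report\n", sep = "")
  invisible(x)
}

#' Total designed trials per condition
#'
#' @param design An [experiment_design()].
#' @return Integer: `n_timing + n_catch + n_probe_per_location * n_locations`.
#' @export
trials_per_condition <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  design$n_timing + design$n_catch +
    design$n_probe_per_location * length(design$probe_locations_deg)
}

#' Report-time grid associated with the probe locations
#'
#' Each probe location maps to the report time a clock-hand position at that
#' location would correspond to. For the sound-time task the sound is at 0
#' degrees = 0 ms, so `T_k = angle * ms_per_deg`. For the keypress-time task
#' the keypress (at -50 degrees, one event delay before the sound) defines
#' 0 ms, so the grid is shifted by the event delay: `T_k = angle *
#' ms_per_deg + event_delay_ms`.
#'
#' @param design An [experiment_design()].
#' @return Numeric vector of report times (ms), one per probe location.
#' @export
design_report_times <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  offset <- if (design$report_task == "keypress-time") design$event_delay_ms else 0
  angle_to_time(design$probe_locations_deg, design$clock) + offset
}

#' Shipped experiment-design presets
#'
#' Four presets mirroring the study's designs:
#' \describe{
#'   \item{exp1}{AS vs SO, sound-time report; 50 timing + 50 catch + 30 x 6
#'     probe = 280 trials per condition.}
#'   \item{exp2}{Same design as exp1 (the empirical study added eye-movement
#'     control, which does not change the trial structure).}
#'   \item{exp3}{AS vs VS, sound-time report; 30 timing + 20 catch + 20 x 6
#'     probe = 170 trials per condition.}
#'   \item{exp4}{AS vs AO, keypress-time report; 50 timing + 100 catch +
#'     30 x 11 probe = 480 trials per condition.}
#' }
#' Presets are stored as YAML under `inst/extdata/` and parsed at call time.
#'
#' @param preset One of `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`.
#' @return An [experiment_design()].
#' @examples
#' trials_per_condition(design_preset("exp3")) # 170
#' @export
design_preset <- function(preset = c("exp1", "exp2", "exp3", "exp4")) {
  preset <- match.arg(preset)
  path <- system.file("extdata", paste0(preset, ".yaml"),
                      package = "clockbind", mustWork = TRUE)
  read_design_yaml(path)
}

#' Read an experiment design from a YAML file
#'
#' @param path Path to a YAML file with the fields of [experiment_design()]
#'   (`revolution_ms` may be given instead of a clock object).
#' @return An [experiment_design()].
#' @export
read_design_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  experiment_design(
    experiment_id = y$experiment_id,
    conditions = unlist(y$conditions),
    n_timing = y$n_timing,
    n_catch = y$n_catch,
    n_probe_per_location = y$n_probe_per_location,
    probe_locations_deg = unlist(y$probe_locations_deg),
    event_delay_ms = y$event_delay_ms %||% 250,
    report_task = y$report_task %||% "sound-time",
    clock = clock_config(y$revolution_ms %||% 1800)
  )
}
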