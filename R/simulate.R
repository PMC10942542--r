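#' Simulate a full probe-detection / timing-report experiment
#'
#' Generates trial-level data with the statistical structure the analysis
#' assumes. Per participant and condition the designed numbers of timing,
#' catch and probe trials are emitted in random order:
#' \itemize{
#'   \item probe trials: `detected ~ Bernoulli(fa + (1 - fa - lapse) * A(x))`
#'     at each design location `x`, where `A` is the condition's attention
#'     field;
#'   \item catch trials: `detected ~ Bernoulli(fa)`;
#'   \item timing trials: the reported clock angle is the actual event angle
#'     (uniform on `[0, 360)`) plus the attention-weighted model prediction
#'     plus Gaussian report noise, converted back to degrees.
#' }
#' The default report generator is model-consistent: each participant's
#' timing reports are driven by the attention-weighted model applied to
#' their own realized detection profile (the Bernoulli probe outcomes drawn
#' for that participant and condition), so that participants vary and
#' recovering a planted binding through the full pipeline is a meaningful
#' test. `report_basis = "field"` uses the noiseless field values on the
#' design grid instead, and an alternative `"shift"` generator produces
#' true-time-plus-constant reports for robustness checks.
#'
#' @param design An [experiment_design()].
#' @param fields Named list of [attention_field()]s, one per design
#'   condition.
#' @param obs An [observer_params()].
#' @param n_participants Number of simulated participants.
#' @param seed Master integer seed. Participant `i` uses the derived seed
#'   `seed + i`, so any participant subset is reproducible.
#' @param report_generator `"attention"` (default, model-consistent) or
#'   `"shift"` (reported time = `shift_ms[condition]` + noise).
#' @param report_basis For the attention generator: `"realized"` (default)
#'   bases each participant's reports on their own drawn detection profile;
#'   `"field"` uses the true field sampled at the design locations.
#' @param shift_ms Named numeric vector of per-condition report shifts (ms),
#'   used only by the `"shift"` generator.
#' @param deterministic_probes If `TRUE`, probe and catch detections are
#'   emitted as the rounded expected counts per location instead of
#'   Bernoulli draws, and report noise is suppressed; used to exercise the
#'   pipeline with sampling noise switched off.
#' @return A tibble of trial records: `participant_id`, `experiment_id`,
#'   `condition`, `trial_type` (`"timing"`, `"probe"`, `"catch"`),
#'   `probe_location_deg` (NA off probe trials), `detected` (NA on timing
#'   trials), `actual_event_angle_deg`, `reported_angle_deg` (NA off timing
#'   trials), `keypress_to_sound_ms` (NA in conditions without a sound
#'   following a keypress or cue).
#' @examples
#' trials <- simulate_experiment(design_preset("exp3"),
#'                               default_fields("outcome")[c("AS", "VS")],
#'                               observer_params(), n_participants = 2,
#'                               seed = 1)
#' dplyr::count(trials, condition)
#' @export
simulate_experiment <- function(design, fields, obs = observer_params(),
                                n_participants = 20, seed = 1,
                                report_generator = c("attention", "shift"),
                                report_basis = c("realized", "field"),
                                shift_ms = NULL,
                                deterministic_probes = FALSE) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(obs, "observer_params"),
            n_participants >= 1)
  report_generator <- match.arg(report_generator)
  report_basis <- match.arg(report_basis)
  missing_fields <- setdiff(design$conditions, names(fields))
  if (length(missing_fields) > 0) {
    stop("No attention field supplied for condition(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  if (report_generator == "shift" &&
      (is.null(shift_ms) || !all(design$conditions %in% names(shift_ms)))) {
    stop("`shift_ms` must name every design condition for the shift generator.",
         call. = FALSE)
  }

  purrr::map_dfr(seq_len(n_participants), function(i) {
    withr_seed <- seed + i
    set.seed(withr_seed)
    purrr::map_dfr(design$conditions, function(cond) {
      simulate_condition(design, fields[[cond]], obs, cond,
                         participant_id = sprintf("P%03d", i),
                         report_generator = report_generator,
                         report_basis = report_basis,
                         shift_ms = shift_ms,
                         deterministic_probes = deterministic_probes)
    })
  })
}

simulate_condition <- function(design, field, obs, cond, participant_id,
                               report_generator, report_basis, shift_ms,
                               deterministic_probes) {
  locs <- design$probe_locations_deg
  npl <- design$n_probe_per_location

  # probe trials are drawn first so that the realized detection profile can
  # drive this participant's timing reports
  p_loc <- detection_probability(field, locs, obs)
  det <- if (deterministic_probes) {
    # exact expected counts, deterministically ordered within location
    unlist(lapply(p_loc, function(p) {
      k <- round(npl * p)
      c(rep(1L, k), rep(0L, npl - k))
    }))
  } else {
    stats::rbinom(npl * length(locs), 1, rep(p_loc, each = npl))
  }
  probe <- tibble::tibble(
    trial_type = "probe",
    probe_location_deg = rep(locs, each = npl),
    detected = as.integer(det),
    actual_event_angle_deg = stats::runif(npl * length(locs), 0, 360),
    reported_angle_deg = NA_real_
  )

  # expected reported time (ms relative to the judged event)
  mu <- if (report_generator == "attention") {
    rates <- if (report_basis == "realized") {
      tapply(probe$detected, probe$probe_location_deg, mean)[as.character(locs)]
    } else {
      field_value(field, locs)
    }
    model_timing_report(as.numeric(rates),
                        report_times = design_report_times(design))$report_ms
  } else {
    unname(shift_ms[cond])
  }

  n_tim <- design$n_timing
  noise <- if (deterministic_probes || obs$report_noise_sd == 0) {
    rep(0, n_tim)
  } else {
    stats::rnorm(n_tim, 0, obs$report_noise_sd)
  }
  actual_tim <- stats::runif(n_tim, 0, 360)
  reported <- (actual_tim + time_to_angle(mu + noise, design$clock)) %% 360

  timing <- tibble::tibble(
    trial_type = "timing",
    probe_location_deg = NA_real_,
    detected = NA_integer_,
    actual_event_angle_deg = actual_tim,
    reported_angle_deg = reported
  )

  n_cat <- design$n_catch
  det_cat <- if (deterministic_probes) {
    k <- round(n_cat * obs$false_alarm)
    c(rep(1L, k), rep(0L, n_cat - k))
  } else {
    stats::rbinom(n_cat, 1, obs$false_alarm)
  }
  catch <- tibble::tibble(
    trial_type = "catch",
    probe_location_deg = NA_real_,
    detected = as.integer(det_cat),
    actual_event_angle_deg = stats::runif(n_cat, 0, 360),
    reported_angle_deg = NA_real_
  )

  out <- dplyr::bind_rows(timing, probe, catch)
  out <- out[sample.int(nrow(out)), ]
  dplyr::mutate(out,
    participant_id = participant_id,
    experiment_id = design$experiment_id,
    condition = cond,
    keypress_to_sound_ms = if (cond %in% c("AS", "VS")) design$event_delay_ms
                           else NA_real_,
    .before = 1
  )
}

#' Write / read the trial-table CSV
#'
#' The on-disk schema mirrors the simulator output: one header row, one row
#' per trial, empty strings for missing values, `detected` coded 0/1.
#'
#' @param trials A trial tibble as produced by [simulate_experiment()].
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the trial tibble with the canonical column types.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      experiment_id = readr::col_character(),
      condition = readr::col_character(),
      trial_type = readr::col_character(),
      probe_location_deg = readr::col_double(),
      detected = readr::col_integer(),
      actual_event_angle_deg = readr::col_double(),
      reported_angle_deg = readr::col_double(),
      keypress_to_sound_ms = readr::col_double()
    )
  )
}

#' Adjust a pair of attention fields to plant a target binding effect
#'
#' Numerically retunes the first field's peak location so that the
#' attention-weighted model's prediction differs between the two fields by
#' exactly `target_binding_ms` on the design's probe grid (binding =
#' model(first) - model(second)). Used to give the simulator a known ground
#' truth for parameter-recovery tests.
#'
#' @param fields Named list of two [attention_field()]s; the first is the
#'   condition whose report is minuend in the binding difference (e.g. SO in
#'   outcome binding SO - AS).
#' @param target_binding_ms Target modeled binding, milliseconds.
#' @param design An [experiment_design()] supplying the probe grid and
#'   report-time grid.
#' @param tol Acceptable absolute deviation from the target, ms (default 1).
#' @return A named list of two fields with the first retuned. Errors if the
#'   target exceeds what any profile on this grid can represent, or if no
#'   peak position reaches it.
#' @examples
#' flds <- default_fields("outcome")[c("SO", "AS")]
#' planted <- plant_binding(flds, 100, design_preset("exp1"))
#' @export
plant_binding <- function(fields, target_binding_ms, design, tol = 1) {
  stopifnot(is.list(fields), length(fields) == 2,
            inherits(design, "experiment_design"))
  tk <- design_report_times(design)
  locs <- design$probe_locations_deg
  model_of <- function(f) {
    model_timing_report(field_value(f, locs), report_times = tk)$report_ms
  }
  if (abs(target_binding_ms) > diff(range(tk))) {
    stop("Target binding of ", target_binding_ms,
         " ms exceeds the representable range (", -diff(range(tk)), ", ",
         diff(range(tk)), ") ms on this grid.", call. = FALSE)
  }
  current <- model_of(fields[[1]]) - model_of(fields[[2]])
  if (abs(current - target_binding_ms) <= tol) return(fields)

  f1 <- fields[[1]]
  gap <- function(peak) {
    g <- attention_field(f1$baseline, f1$amplitude, peak,
                         f1$rise_slope, f1$fall_slope)
    model_of(g) - model_of(fields[[2]]) - target_binding_ms
  }
  lo <- min(locs) - 4 * f1$rise_slope
  hi <- max(locs) + 4 * f1$fall_slope
  if (gap(lo) * gap(hi) > 0) {
    stop("Target binding of ", target_binding_ms,
         " ms is not reachable by moving the first field's peak on this grid.",
         call. = FALSE)
  }
  peak <- stats::uniroot(gap, c(lo, hi), tol = 1e-4)$root
  fields[[1]] <- attention_field(f1$baseline, f1$amplitude, peak,
                                 f1$rise_slope, f1$fall_slope)
  achieved <- model_of(fields[[1]]) - model_of(fields[[2]])
  if (abs(achieved - target_binding_ms) > tol) {
    stop("Planting failed: achieved ", round(achieved, 2), " ms vs target ",
         target_binding_ms, " ms.", call. = FALSE)
  }
  fields
}
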