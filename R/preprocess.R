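#' Per-participant false-alarm rates
#'
#' The false-alarm rate is the fraction of catch trials (no probe shown) on
#' which a probe was nonetheless reported, pooled over conditions. It is the
#' first participant-screening statistic: observers reporting probes on most
#' catch trials provide no usable detection data.
#'
#' @param trials Trial tibble (see [simulate_experiment()] for the schema).
#' @return A tibble with `participant_id`, `n_catch`, `false_alarm_rate`.
#'   Errors if any participant in `trials` has no catch trials.
#' @export
false_alarm_rates <- function(trials) {
  check_trials(trials)
  no_catch <- setdiff(unique(trials$participant_id),
                      unique(trials$participant_id[trials$trial_type == "catch"]))
  if (length(no_catch) > 0) {
    stop("No catch trials for participant(s): ",
         paste(no_catch, collapse = ", "), call. = FALSE)
  }
  trials |>
    dplyr::filter(.data$trial_type == "catch") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_catch = dplyr::n(),
                     false_alarm_rate = mean(.data$detected),
                     .groups = "drop")
}

#' Probe detection-rate profiles (the attention measure)
#'
#' For every participant and condition, the detection rate at each design
#' probe location: the fraction of probe trials at that location on which
#' the probe was reported. These per-location rates \eqn{D_k} are the
#' study's operational measure of visuospatial attention, and each location
#' is annotated with the report time \eqn{T_k} it corresponds to on the
#' clock (see [design_report_times()]).
#'
#' @param trials Trial tibble.
#' @param design The [experiment_design()] the trials follow; supplies the
#'   probe grid and the report-time grid.
#' @return A tibble with `participant_id`, `condition`,
#'   `probe_location_deg`, `report_time_ms`, `n_trials`, `rate`, ordered by
#'   location within participant and condition. Errors if any participant x
#'   condition lacks trials at a design location.
#' @export
detection_profiles <- function(trials, design) {
  check_trials(trials)
  stopifnot(inherits(design, "experiment_design"))
  tk <- tibble::tibble(probe_location_deg = design$probe_locations_deg,
                       report_time_ms = design_report_times(design))
  probes <- dplyr::filter(trials, .data$trial_type == "probe")
  prof <- probes |>
    dplyr::group_by(.data$participant_id, .data$condition,
                    .data$probe_location_deg) |>
    dplyr::summarise(n_trials = dplyr::n(), rate = mean(.data$detected),
                     .groups = "drop")
  full <- tidyr::expand_grid(
    participant_id = unique(trials$participant_id),
    condition = design$conditions,
    probe_location_deg = design$probe_locations_deg
  )
  missing <- dplyr::anti_join(
    full, prof,
    by = c("participant_id", "condition", "probe_location_deg")
  )
  if (nrow(missing) > 0) {
    stop("No probe trials at design location(s): ",
         paste(utils::head(sprintf("%s/%s/%g deg", missing$participant_id,
                                   missing$condition,
                                   missing$probe_location_deg), 5),
               collapse = "; "),
         if (nrow(missing) > 5) " ..." else "", call. = FALSE)
  }
  prof |>
    dplyr::inner_join(tk, by = "probe_location_deg") |>
    dplyr::arrange(.data$participant_id, .data$condition,
                   .data$probe_location_deg) |>
    dplyr::select("participant_id", "condition", "probe_location_deg",
                  "report_time_ms", "n_trials", "rate")
}

#' Trial-level timing-report errors
#'
#' Converts each timing trial's reported vs actual clock-hand position into
#' a signed temporal judgment error via [report_error()].
#'
#' @param trials Trial tibble.
#' @param cfg A [clock_config()].
#' @return The timing-trial rows of `trials` with `error_deg` and
#'   `error_ms` columns appended. Errors if a timing trial has no reported
#'   angle, naming the offending rows.
#' @export
timing_errors <- function(trials, cfg = clock_config()) {
  check_trials(trials)
  tim <- dplyr::filter(trials, .data$trial_type == "timing")
  if (nrow(tim) == 0) stop("No timing trials present.", call. = FALSE)
  bad <- which(is.na(tim$reported_angle_deg))
  if (length(bad) > 0) {
    stop("Missing reported angle on timing trial row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  err <- report_error(tim$reported_angle_deg, tim$actual_event_angle_deg, cfg)
  dplyr::bind_cols(tim, err)
}

#' MAD-median outlier flags
#'
#' Flags value `p` of sample `P` as an outlier when
#' `|p - median(P)| * 0.6745 > 3 * MAD`, where `MAD = median(|P -
#' median(P)|)` is the unscaled median absolute deviation from the median.
#' The inequality is applied literally in this form (constant 0.6745
#' multiplying the deviation, threshold 3). With a constant sample the MAD
#' is 0 and the strict inequality never holds, so nothing is flagged.
#'
#' @param values Numeric vector, length >= 3.
#' @return Logical vector of flags, same length as `values`.
#' @examples
#' mad_median_flags(c(1, 2, 3, 4, 100)) # flags only 100
#' @export
mad_median_flags <- function(values) {
  if (!is.numeric(values) || length(values) < 3 || any(!is.finite(values))) {
    stop("`values` must be >= 3 finite numbers.", call. = FALSE)
  }
  dev <- abs(values - stats::median(values))
  mad_unscaled <- stats::median(dev)
  dev * 0.6745 > 3 * mad_unscaled
}

#' Per-participant condition summaries
#'
#' The screening statistics used for participant exclusion: the pooled
#' false-alarm rate, and the median and standard deviation of the
#' timing-report error in each condition.
#'
#' @param trials Trial tibble.
#' @param cfg A [clock_config()].
#' @return A tibble with one row per participant x condition:
#'   `participant_id`, `condition`, `false_alarm_rate`, `n_timing`,
#'   `median_report_ms`, `sd_report_ms`.
#' @export
participant_summaries <- function(trials, cfg = clock_config()) {
  fa <- false_alarm_rates(trials)
  timing_errors(trials, cfg) |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(n_timing = dplyr::n(),
                     median_report_ms = stats::median(.data$error_ms),
                     sd_report_ms = stats::sd(.data$error_ms),
                     .groups = "drop") |>
    dplyr::left_join(dplyr::select(fa, "participant_id", "false_alarm_rate"),
                     by = "participant_id") |>
    dplyr::select("participant_id", "condition", "false_alarm_rate",
                  "n_timing", "median_report_ms", "sd_report_ms")
}

#' Two-stage participant exclusion
#'
#' Stage 1 removes participants whose pooled false-alarm rate exceeds
#' `fa_threshold` (default 0.5: the rule separates catastrophic responders,
#' with rates above 0.6, from typical retained rates below 0.1 with a wide
#' margin). Stage 2 applies the MAD-median rule ([mad_median_flags()])
#' across the remaining participants, separately to each condition's median
#' and SD of the timing-report error; a participant flagged on any of those
#' statistics is excluded. The MAD-median reference statistics are computed
#' once on the post-stage-1 cohort; pass them back via `reference` to
#' re-apply the identical rule to a subset (exclusion is then idempotent).
#'
#' @param summaries Output of [participant_summaries()].
#' @param fa_threshold Stage-1 false-alarm cutoff, default 0.5.
#' @param reference Optional reference statistics from a previous run (the
#'   `"reference"` attribute of the previous result).
#' @return One row per participant: `participant_id`, `false_alarm_rate`,
#'   `fa_excluded`, `mad_excluded`, `excluded`, `reason`. The MAD reference
#'   (per condition x statistic: centre and MAD) is attached as attribute
#'   `"reference"`. Errors if nobody survives.
#' @export
apply_exclusions <- function(summaries, fa_threshold = 0.5, reference = NULL) {
  needed <- c("participant_id", "condition", "false_alarm_rate",
              "median_report_ms", "sd_report_ms")
  if (!all(needed %in% names(summaries))) {
    stop("`summaries` must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  by_p <- summaries |>
    dplyr::distinct(.data$participant_id, .data$false_alarm_rate) |>
    dplyr::mutate(fa_excluded = .data$false_alarm_rate > fa_threshold)

  survivors <- by_p$participant_id[!by_p$fa_excluded]
  long <- summaries |>
    dplyr::filter(.data$participant_id %in% survivors) |>
    tidyr::pivot_longer(c("median_report_ms", "sd_report_ms"),
                        names_to = "statistic", values_to = "value")

  if (is.null(reference)) {
    reference <- long |>
      dplyr::group_by(.data$condition, .data$statistic) |>
      dplyr::summarise(
        centre = stats::median(.data$value),
        mad_unscaled = stats::median(abs(.data$value - stats::median(.data$value))),
        .groups = "drop"
      )
  }
  flags <- long |>
    dplyr::inner_join(reference, by = c("condition", "statistic")) |>
    dplyr::mutate(flag = abs(.data$value - .data$centre) * 0.6745 >
                    3 * .data$mad_unscaled) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(mad_excluded = any(.data$flag), .groups = "drop")

  out <- by_p |>
    dplyr::left_join(flags, by = "participant_id") |>
    dplyr::mutate(
      mad_excluded = dplyr::coalesce(.data$mad_excluded, FALSE),
      excluded = .data$fa_excluded | .data$mad_excluded,
      reason = dplyr::case_when(
        fa_excluded ~ "false-alarm rate",
        mad_excluded ~ "MAD-median report statistics",
        TRUE ~ NA_character_
      )
    )
  if (all(out$excluded)) {
    stop("All participants excluded; check the data or the thresholds.",
         call. = FALSE)
  }
  attr(out, "reference") <- reference
  out
}

#' Per-participant binding effects
#'
#' The binding effect is the difference of condition medians of the
#' timing-report error, per participant, with the field's sign conventions:
#' outcome binding is SO - AS (or VS - AS), action binding is AS - AO, so a
#' positive value always corresponds to the classic binding direction.
#'
#' @param summaries Output of [participant_summaries()] (post-exclusion
#'   rows, typically).
#' @param pair Character length-2: the minuend and subtrahend conditions,
#'   e.g. `c("SO", "AS")` for outcome binding or `c("AS", "AO")` for action
#'   binding.
#' @return A tibble with `participant_id` and `binding_ms`; the group-level
#'   effect is the mean of `binding_ms`.
#' @examples
#' \dontrun{
#' binding_effects(summaries, c("SO", "AS")) |>
#'   dplyr::summarise(group_binding = mean(binding_ms))
#' }
#' @export
binding_effects <- function(summaries, pair) {
  stopifnot(is.character(pair), length(pair) == 2)
  missing <- setdiff(pair, unique(summaries$condition))
  if (length(missing) > 0) {
    stop("Condition(s) not summarised: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wide <- summaries |>
    dplyr::filter(.data$condition %in% pair) |>
    dplyr::select("participant_id", "condition", "median_report_ms") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "median_report_ms")
  incomplete <- wide$participant_id[is.na(wide[[pair[1]]]) |
                                      is.na(wide[[pair[2]]])]
  if (length(incomplete) > 0) {
    stop("Participant(s) missing a condition median: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(participant_id = wide$participant_id,
                 binding_ms = wide[[pair[1]]] - wide[[pair[2]]])
}

check_trials <- function(trials) {
  needed <- c("participant_id", "condition", "trial_type",
              "probe_location_deg", "detected", "actual_event_angle_deg",
              "reported_angle_deg")
  if (!is.data.frame(trials) || !all(needed %in% names(trials))) {
    stop("`trials` must be a trial table with columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) == 0) stop("`trials` is empty.", call. = FALSE)
  bad <- setdiff(unique(trials$trial_type), c("timing", "probe", "catch"))
  if (length(bad) > 0) {
    stop("Unknown trial_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(trials)
}
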