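#' Report-time grids for the two modeling tasks
#'
#' The attention model weights a fixed grid of candidate report times, one
#' per probe location. For the outcome task (sound-time report) the grid is
#' `-250, -150, -50, 50, 150, 250` ms with the sound at 0 ms; for the
#' action task (keypress-time report) it is `0, 50, ..., 500` ms with the
#' keypress at 0 ms.
#'
#' @param task `"outcome"` or `"action"`.
#' @return Strictly increasing numeric vector of report times (ms).
#' @export
model_grid <- function(task = c("outcome", "action")) {
  task <- match.arg(task)
  if (task == "outcome") c(-250, -150, -50, 50, 150, 250) else seq(0, 500, 50)
}

#' Min-corrected detection rates
#'
#' Subtracts the minimum detection rate from every location's rate,
#' `D'_k = D_k - min(D)`, so that the least-attended location contributes
#' zero weight to the modeled report. Order is preserved and the minimum
#' (and any rate tied with it) maps exactly to 0.
#'
#' @param rates Numeric detection rates in `[0, 1]`.
#' @return Corrected rates `D'`, same length.
#' @examples
#' correct_rates(c(0.2, 0.3, 0.5, 0.9, 0.6, 0.4))
#' @export
correct_rates <- function(rates) {
  if (!is.numeric(rates) || length(rates) == 0 || any(!is.finite(rates))) {
    stop("`rates` must be a non-empty finite numeric vector.", call. = FALSE)
  }
  if (any(rates < 0 | rates > 1)) {
    stop("Detection rates must lie in [0, 1].", call. = FALSE)
  }
  rates - min(rates)
}

#' Attention-weighted modeled timing report
#'
#' The model's prediction of a participant's timing report from the
#' attention measure alone: the report-time grid averaged with weights
#' proportional to the min-corrected detection rates,
#' \deqn{\hat{R} = \sum_k T_k \, D'_k / \sum_k D'_k .}
#' A perfectly flat profile leaves all corrected rates at zero; the
#' fallback then uses uniform weights (the limit of adding the same small
#' mass everywhere) and the result is flagged.
#'
#' @param rates Detection rates `D_k`, one per grid point.
#' @param task `"outcome"` or `"action"`; selects the default grid.
#' @param report_times Optional explicit report-time grid (ms), overriding
#'   `task`; must be strictly increasing and match `rates` in length.
#' @return A list of class `model_report`: `report_ms`, `fallback_used`,
#'   `weights` (summing to 1).
#' @examples
#' model_timing_report(c(0.2, 0.3, 0.5, 0.9, 0.6, 0.4), "outcome")$report_ms
#' @export
model_timing_report <- function(rates, task = c("outcome", "action"),
                                report_times = NULL) {
  if (is.null(report_times)) report_times <- model_grid(match.arg(task))
  if (!is.numeric(report_times) ||
      is.unsorted(report_times, strictly = TRUE)) {
    stop("`report_times` must be strictly increasing.", call. = FALSE)
  }
  if (length(rates) != length(report_times)) {
    stop("`rates` (", length(rates), ") and the report-time grid (",
         length(report_times), ") differ in length.", call. = FALSE)
  }
  d <- correct_rates(rates)
  total <- sum(d)
  fallback <- total == 0
  w <- if (fallback) rep(1 / length(d), length(d)) else d / total
  structure(
    list(report_ms = sum(report_times * w), fallback_used = fallback,
         weights = w),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> ", round(x$report_ms, 2), " ms",
      if (x$fallback_used) " (flat profile: uniform-weight fallback)", "\n",
      sep = "")
  invisible(x)
}

#' Modeled timing reports for every participant and condition
#'
#' Applies [model_timing_report()] to each participant x condition profile
#' in a [detection_profiles()] table, using each profile's own
#' `report_time_ms` grid.
#'
#' @param profiles Output of [detection_profiles()].
#' @return A tibble with `participant_id`, `condition`,
#'   `modeled_report_ms`, `fallback_used`.
#' @export
model_reports <- function(profiles) {
  needed <- c("participant_id", "condition", "report_time_ms", "rate")
  if (!all(needed %in% names(profiles))) {
    stop("`profiles` must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  profiles |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::arrange(.data$report_time_ms, .by_group = TRUE) |>
    dplyr::summarise(
      res = list(model_timing_report(.data$rate,
                                     report_times = .data$report_time_ms)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      modeled_report_ms = purrr::map_dbl(.data$res, "report_ms"),
      fallback_used = purrr::map_lgl(.data$res, "fallback_used")
    ) |>
    dplyr::select(-"res")
}

#' Modeled binding effects
#'
#' Differences the modeled timing reports of two conditions per
#' participant, with the same sign conventions as [binding_effects()]
#' (outcome: SO - AS or VS - AS; action: AS - AO).
#'
#' @param results Output of [model_reports()].
#' @param pair Character length-2: minuend and subtrahend conditions.
#' @return A tibble with `participant_id` and `modeled_binding_ms`.
#' @export
modeled_bindings <- function(results, pair) {
  stopifnot(is.character(pair), length(pair) == 2)
  missing <- setdiff(pair, unique(results$condition))
  if (length(missing) > 0) {
    stop("Condition(s) not modeled: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wide <- results |>
    dplyr::filter(.data$condition %in% pair) |>
    dplyr::select("participant_id", "condition", "modeled_report_ms") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "modeled_report_ms")
  incomplete <- wide$participant_id[is.na(wide[[pair[1]]]) |
                                      is.na(wide[[pair[2]]])]
  if (length(incomplete) > 0) {
    stop("Participant(s) missing a modeled condition: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(participant_id = wide$participant_id,
                 modeled_binding_ms = wide[[pair[1]]] - wide[[pair[2]]])
}
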