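#' Clock configuration
#'
#' Describes the rotating clock used for timing reports. The hand sweeps a
#' full revolution in `revolution_ms` milliseconds, so one degree of arc
#' corresponds to `revolution_ms / 360` ms (5 ms/degree at the 1800 ms
#' default). Angles are measured clockwise, and 0 degrees is defined
#' per trial as the hand position at the judged event, so the analysis never
#' needs an absolute screen orientation.
#'
#' @param revolution_ms Duration of one clock-hand revolution in
#'   milliseconds. Must be a single positive finite number.
#' @return An object of class `clock_config` with elements `revolution_ms`
#'   and `ms_per_deg`.
#' @examples
#' cfg <- clock_config()
#' cfg$ms_per_deg # 5
#' @export
clock_config <- function(revolution_ms = 1800) {
  if (!is.numeric(revolution_ms) || length(revolution_ms) != 1 ||
      !is.finite(revolution_ms) || revolution_ms <= 0) {
    stop("`revolution_ms` must be a single positive finite number.",
         call. = FALSE)
  }
  structure(
    list(revolution_ms = revolution_ms, ms_per_deg = revolution_ms / 360),
    class = "clock_config"
  )
}

#' @export
print.clock_config <- function(x, ...) {
  cat("<clock_config> ", x$revolution_ms, " ms/revolution (",
      format(x$ms_per_deg, digits = 4), " ms/degree)\n", sep = "")
  invisible(x)
}

check_clock_config <- function(cfg) {
  if (!inherits(cfg, "clock_config")) {
    stop("`cfg` must be a `clock_config` object; see `clock_config()`.",
         call. = FALSE)
  }
  cfg
}

#' Convert a clock-hand angle to a report time
#'
#' A signed angular offset on the clock face maps linearly to a signed time:
#' `angle * revolution_ms / 360`. At the default 1800 ms revolution, 50
#' degrees corresponds to 250 ms and -30 degrees to -150 ms.
#'
#' @param angle Angular offset in degrees (vectorised; may be signed).
#' @param cfg A [clock_config()].
#' @return Time in milliseconds, same length as `angle`.
#' @seealso [time_to_angle()] for the exact inverse.
#' @examples
#' angle_to_time(50)  # 250
#' angle_to_time(-30) # -150
#' @export
angle_to_time <- function(angle, cfg = clock_config()) {
  check_clock_config(cfg)
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite numeric degrees.", call. = FALSE)
  }
  angle * cfg$ms_per_deg
}

#' Convert a report time to a clock-hand angle
#'
#' Exact inverse of [angle_to_time()]: `t * 360 / revolution_ms`.
#'
#' @param t Time in milliseconds (vectorised; may be signed).
#' @param cfg A [clock_config()].
#' @return Angle in degrees, same length as `t`.
#' @examples
#' time_to_angle(250) # 50
#' @export
time_to_angle <- function(t, cfg = clock_config()) {
  check_clock_config(cfg)
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric milliseconds.", call. = FALSE)
  }
  t / cfg$ms_per_deg
}

#' Signed timing-report error from two clock-hand positions
#'
#' The raw difference `reported - actual` is wrapped into the half-open
#' interval (-180, 180] degrees -- the minimal-magnitude reading of the
#' discrepancy, with an exactly antipodal report signed positive -- and then
#' converted to milliseconds. Positive errors mean the event was reported
#' later than it occurred. At the default clock speed the error always lies
#' in (-900, 900] ms.
#'
#' @param reported_angle Reported hand position, degrees in `[0, 360)`
#'   (vectorised).
#' @param actual_angle Actual hand position at the event, degrees in
#'   `[0, 360)` (vectorised, recycled against `reported_angle`).
#' @param cfg A [clock_config()].
#' @return A tibble with columns `error_deg` and `error_ms`.
#' @examples
#' report_error(10, 0)   # +50 ms: reported one probe-step late
#' report_error(350, 10) # -100 ms: wrapped across the top of the clock
#' @export
report_error <- function(reported_angle, actual_angle, cfg = clock_config()) {
  check_clock_config(cfg)
  ok <- function(a) is.numeric(a) && all(is.finite(a)) && all(a >= 0 & a < 360)
  if (!ok(reported_angle) || !ok(actual_angle)) {
    stop("Angles must be finite degrees in [0, 360).", call. = FALSE)
  }
  d <- wrap_degrees(reported_angle - actual_angle)
  tibble::tibble(error_deg = d, error_ms = d * cfg$ms_per_deg)
}

# Wrap a signed angular difference into (-180, 180]; +180 kept positive.
wrap_degrees <- function(d) {
  w <- d %% 360
  ifelse(w > 180, w - 360, w)
}
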