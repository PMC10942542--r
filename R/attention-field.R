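#' Attention field over clock positions
#'
#' A smooth detection-rate profile A(x) over probe location x (degrees on the
#' clock rim, equivalently time given the hand speed). The shape is a
#' difference-of-logistics ramp: a rising logistic multiplied by a falling
#' logistic, max-normalised, scaled by `amplitude` and lifted by `baseline`,
#' then clamped to `[0, 1]`. `peak_deg` is (up to the max-normalisation) the
#' location of the maximum; `rise_slope` and `fall_slope` control how fast
#' attention accumulates before the peak and decays after it, in degrees.
#'
#' @param baseline Detection-rate floor far from the peak, in `[0, 1]`.
#' @param amplitude Height of the peak above the baseline; `baseline +
#'   amplitude` must not exceed 1.
#' @param peak_deg Location of peak attention, degrees.
#' @param rise_slope Logistic scale of the rising edge, degrees (> 0).
#'   Larger values mean a more gradual build-up.
#' @param fall_slope Logistic scale of the falling edge, degrees (> 0).
#' @return An object of class `attention_field`; call it like a function or
#'   use [field_value()] to evaluate it.
#' @examples
#' f <- attention_field(baseline = 0.2, amplitude = 0.55, peak_deg = -10,
#'                      rise_slope = 25, fall_slope = 12)
#' field_value(f, c(-50, -10, 50))
#' @export
attention_field <- function(baseline = 0.1, amplitude = 0.6, peak_deg = 0,
                            rise_slope = 15, fall_slope = 15) {
  stopifnot(
    is.numeric(baseline), baseline >= 0, baseline <= 1,
    is.numeric(amplitude), amplitude >= 0, baseline + amplitude <= 1 + 1e-12,
    is.numeric(peak_deg), is.finite(peak_deg),
    rise_slope > 0, fall_slope > 0
  )
  f <- structure(
    list(baseline = baseline, amplitude = amplitude, peak_deg = peak_deg,
         rise_slope = rise_slope, fall_slope = fall_slope),
    class = "attention_field"
  )
  # max of the logistic product on a fine grid spanning the working range,
  # so that A(peak) = baseline + amplitude holds to grid precision
  grid <- seq(peak_deg - 720, peak_deg + 720, by = 0.25)
  f$shape_max <- max(field_shape(f, grid))
  f
}

# unnormalised logistic-product ramp
field_shape <- function(f, x) {
  stats::plogis((x - f$peak_deg) / f$rise_slope + 2) *
    stats::plogis((f$peak_deg - x) / f$fall_slope + 2)
}

#' Evaluate an attention field
#'
#' @param field An [attention_field()].
#' @param x Probe locations in degrees (vectorised).
#' @return Detection-rate values in `[0, 1]`.
#' @export
field_value <- function(field, x) {
  stopifnot(inherits(field, "attention_field"), is.numeric(x),
            all(is.finite(x)))
  a <- field$baseline + field$amplitude * field_shape(field, x) / field$shape_max
  pmin(pmax(a, 0), 1)
}

#' @export
print.attention_field <- function(x, ...) {
  cat("<attention_field> baseline ", x$baseline, ", peak ",
      round(x$baseline + x$amplitude, 3), " at ", x$peak_deg,
      " deg (rise ", x$rise_slope, ", fall ", x$fall_slope, ")\n", sep = "")
  invisible(x)
}

#' Default attention fields for the four experimental conditions
#'
#' Qualitative shapes of the per-condition probe-detection profiles:
#' \describe{
#'   \item{SO (sound only)}{Attention accumulates towards the clock rim only
#'     after the unpredictable sound: low before 0 degrees, high after.}
#'   \item{AS, outcome task}{The keypress directs attention to the rim ahead
#'     of the sound: already elevated at the keypress position (-50 deg),
#'     peaking just before 0 deg, falling sharply after the sound.}
#'   \item{VS (vibration sound)}{The vibrotactile cue plays the attentional
#'     role of the keypress, so the field matches the AS shape.}
#'   \item{AS / AO, action task}{When the keypress time itself is judged,
#'     attention peaks right after the keypress (-50 deg = 0 ms) and decays;
#'     the sound at 0 deg (250 ms) in AS slows the decay relative to AO.}
#' }
#'
#' @param task `"outcome"` (sound-time report) or `"action"` (keypress-time
#'   report); the two tasks probe different windows of the clock face.
#' @return A named list of [attention_field()] objects keyed by condition.
#' @export
default_fields <- function(task = c("outcome", "action")) {
  task <- match.arg(task)
  if (task == "outcome") {
    list(
      AS = attention_field(baseline = 0.20, amplitude = 0.55, peak_deg = -10,
                           rise_slope = 30, fall_slope = 10),
      SO = attention_field(baseline = 0.15, amplitude = 0.60, peak_deg = 35,
                           rise_slope = 10, fall_slope = 60),
      VS = attention_field(baseline = 0.20, amplitude = 0.55, peak_deg = -10,
                           rise_slope = 30, fall_slope = 10)
    )
  } else {
    list(
      AS = attention_field(baseline = 0.10, amplitude = 0.75, peak_deg = -40,
                           rise_slope = 6, fall_slope = 30),
      AO = attention_field(baseline = 0.10, amplitude = 0.75, peak_deg = -40,
                           rise_slope = 6, fall_slope = 18)
    )
  }
}

#' Observer parameters for the probe-detection simulator
#'
#' @param false_alarm Probability of reporting a probe on a catch trial,
#'   in `[0, 1)`.
#' @param lapse Miss floor: probability mass never converted to a detection
#'   however strong the probe, in `[0, 1)`. `false_alarm + lapse` must be
#'   below 1.
#' @param report_noise_sd SD of the Gaussian noise added to the generated
#'   timing report, milliseconds (>= 0).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(false_alarm = 0.04, lapse = 0.02,
                            report_noise_sd = 60) {
  stopifnot(
    false_alarm >= 0, false_alarm < 1, lapse >= 0, lapse < 1,
    false_alarm + lapse < 1, report_noise_sd >= 0
  )
  structure(
    list(false_alarm = false_alarm, lapse = lapse,
         report_noise_sd = report_noise_sd),
    class = "observer_params"
  )
}

#' Probe-detection probability at a clock location
#'
#' Combines the attention field with the observer's false-alarm and lapse
#' floors: `false_alarm + (1 - false_alarm - lapse) * A(x)`. The result is
#' always within `[false_alarm, 1 - lapse]`.
#'
#' @param field An [attention_field()].
#' @param location Probe location(s), degrees.
#' @param obs An [observer_params()].
#' @return Detection probabilities, same length as `location`.
#' @examples
#' f <- attention_field()
#' detection_probability(f, 0, observer_params(false_alarm = 0.04, lapse = 0.1))
#' @export
detection_probability <- function(field, location, obs = observer_params()) {
  stopifnot(inherits(obs, "observer_params"))
  a <- field_value(field, location)
  obs$false_alarm + (1 - obs$false_alarm - obs$lapse) * a
}
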