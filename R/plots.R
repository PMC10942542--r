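#' Plot group attention profiles
#'
#' Mean probe detection rate by probe location and condition, with
#' standard-error bars -- the study's attention-distribution figure.
#'
#' @param profiles Output of [detection_profiles()].
#' @return A ggplot.
#' @export
plot_attention_profiles <- function(profiles) {
  grp <- profiles |>
    dplyr::group_by(.data$condition, .data$probe_location_deg) |>
    dplyr::summarise(mean_rate = mean(.data$rate),
                     se = stats::sd(.data$rate) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(grp, ggplot2::aes(x = .data$probe_location_deg,
                                    y = .data$mean_rate,
                                    colour = .data$condition,
                                    group = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_rate - .data$se,
                                          ymax = .data$mean_rate + .data$se)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "probe location (deg, 0 = judged event)",
                  y = "detection rate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot modeled against actual binding
#'
#' Per-participant scatter of the attention-model prediction against the
#' measured binding effect, with the identity line for reference.
#'
#' @param binding The `binding` tibble of a `clockbind_run` (columns
#'   `binding_ms`, `modeled_binding_ms`).
#' @return A ggplot.
#' @export
plot_binding <- function(binding) {
  ggplot2::ggplot(binding, ggplot2::aes(x = .data$modeled_binding_ms,
                                        y = .data$binding_ms)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "modeled binding (ms)", y = "actual binding (ms)") +
    ggplot2::theme_minimal()
}

#' Autoplot for a binding-analysis run
#'
#' @param object A `clockbind_run`.
#' @param type `"profiles"` (attention distributions) or `"binding"`
#'   (modeled vs actual scatter).
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @method autoplot clockbind_run
#' @export
autoplot.clockbind_run <- function(object, type = c("profiles", "binding"),
                                   ...) {
  type <- match.arg(type)
  switch(type,
         profiles = plot_attention_profiles(object$profiles),
         binding = plot_binding(object$binding))
}

#' @export
ggplot2::autoplot
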