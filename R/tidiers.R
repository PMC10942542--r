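#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a binding-analysis run
#'
#' One row per statistical result computed by [run_analysis()]: the
#' group-level binding t tests, the modeled-vs-actual correlations, and the
#' detection-rate ANOVA effects.
#'
#' @param x A `clockbind_run`.
#' @param ... Unused.
#' @return A tibble with `test`, `statistic`, `df`, `p_value`,
#'   `effect_size`, `bf10` where applicable.
#' @method tidy clockbind_run
#' @export
tidy.clockbind_run <- function(x, ...) {
  dplyr::bind_rows(
    x$tests |>
      dplyr::transmute(test = .data$test, kind = "t",
                       statistic = .data$statistic, df = .data$df,
                       p_value = .data$p_value,
                       effect_size = .data$effect_size, bf10 = .data$bf10),
    x$correlations |>
      dplyr::transmute(
        test = paste0(.data$comparison,
                      ifelse(.data$outliers_removed > 0,
                             paste0(" (", .data$outliers_removed,
                                    " outlier(s) removed)"), "")),
        kind = "spearman", statistic = .data$rho,
        df = .data$n - 2, p_value = .data$p_value
      ),
    x$anova |>
      dplyr::transmute(test = paste0("detection rate ANOVA: ", .data$effect),
                       kind = "F", statistic = .data$statistic,
                       df = .data$df1, df2 = .data$df2,
                       p_value = .data$p_value,
                       effect_size = .data$partial_eta_sq)
  )
}

#' Glance at a binding-analysis run
#'
#' @param x A `clockbind_run`.
#' @param ... Unused.
#' @return A one-row tibble: cohort sizes, group-level actual and modeled
#'   binding (ms), and the p values of their tests against zero.
#' @method glance clockbind_run
#' @export
glance.clockbind_run <- function(x, ...) {
  tibble::tibble(
    experiment_id = x$design$experiment_id,
    n_participants = x$n_participants,
    n_included = x$n_included,
    binding_pair = paste(x$config$binding_pair, collapse = " - "),
    actual_binding_ms = mean(x$binding$binding_ms),
    modeled_binding_ms = mean(x$binding$modeled_binding_ms),
    p_actual = x$tests$p_value[x$tests$test == "actual binding vs 0"],
    p_modeled = x$tests$p_value[x$tests$test == "modeled binding vs 0"]
  )
}
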