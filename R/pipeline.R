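#' Run the full binding analysis on a trial table
#'
#' Orchestrates the whole chain on one experiment's trials: participant
#' summaries and two-stage exclusions, probe detection profiles, the
#' attention-weighted modeled timing reports, actual and modeled binding
#' effects with their group-level t tests (frequentist and JZS Bayes
#' factor), Spearman correlations between modeled and actual quantities
#' (reported both with and without box-plot-rule outlier removal), and the
#' condition-by-location detection-rate ANOVA.
#'
#' @param trials Trial tibble (see [simulate_experiment()]) or a path to a
#'   trial CSV in the same schema.
#' @param design The [experiment_design()] the trials follow.
#' @param binding_pair Character length-2 giving the minuend and subtrahend
#'   conditions of the binding effect. Defaults to the design's non-AS
#'   condition minus AS for a sound-time task (outcome binding) and AS
#'   minus AO for a keypress-time task (action binding).
#' @param binding_tail Tail of the group-level binding t tests: `"greater"`
#'   (classic binding predicted, default) or `"two"` (used when the
#'   direction is not predicted, as in an attention-matched control).
#' @param fa_threshold Stage-1 false-alarm exclusion cutoff
#'   (see [apply_exclusions()]).
#' @param output_dir Optional directory; when given, writes
#'   `participant_summary.csv`, `attention_profiles.csv`,
#'   `model_results.csv`, `stats_report.json` and `run_report.json`.
#' @param seed Integer recorded in the report's provenance (the analysis
#'   itself is deterministic; the seed documents the simulation that
#'   produced the input, if any).
#' @return An object of class `clockbind_run`; see [tidy.clockbind_run()]
#'   and [glance.clockbind_run()].
#' @examples
#' design <- design_preset("exp3")
#' trials <- simulate_experiment(design, default_fields("outcome")[c("AS", "VS")],
#'                               n_participants = 8, seed = 7)
#' run <- run_analysis(trials, design, binding_tail = "two")
#' glance(run)
#' @export
run_analysis <- function(trials, design,
                         binding_pair = NULL,
                         binding_tail = c("greater", "two"),
                         fa_threshold = 0.5,
                         output_dir = NULL,
                         seed = NA_integer_) {
  binding_tail <- match.arg(binding_tail)
  stopifnot(inherits(design, "experiment_design"))
  if (is.character(trials) && length(trials) == 1) trials <- read_trials(trials)
  check_trials(trials)
  extra <- setdiff(unique(trials$condition), design$conditions)
  if (length(extra) > 0) {
    stop("Trials contain condition(s) absent from the design: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (is.null(binding_pair)) binding_pair <- default_binding_pair(design)

  summaries <- participant_summaries(trials, design$clock)
  exclusions <- apply_exclusions(summaries, fa_threshold = fa_threshold)
  included <- exclusions$participant_id[!exclusions$excluded]
  kept <- dplyr::filter(trials, .data$participant_id %in% included)
  kept_summaries <- dplyr::filter(summaries,
                                  .data$participant_id %in% included)

  profiles <- detection_profiles(kept, design)
  model_results <- model_reports(profiles)

  actual <- binding_effects(kept_summaries, binding_pair)
  modeled <- modeled_bindings(model_results, binding_pair)
  binding <- dplyr::inner_join(actual, modeled, by = "participant_id")

  t_tail <- if (binding_tail == "greater") "greater" else "two"
  bf_tail <- if (binding_tail == "greater") "positive" else "two"
  # a zero-variance contrast (e.g. modeled and actual identical in a
  # noise-free simulation) is reported as undefined, not raised
  group_test <- function(x, y, label, tt, bt) {
    ht <- tryCatch(paired_t(x, y, tail = tt), error = function(e) NULL)
    if (is.null(ht)) {
      return(tibble::tibble(test = label, method = "paired t",
                            statistic = NA_real_, df = length(x) - 1,
                            p_value = NA_real_, tail = tt,
                            n = length(x), mean_diff = mean(x - y),
                            bf10 = NA_real_,
                            note = "undefined: zero variance"))
    }
    bf <- jzs_bf_t(ht$statistic, n = ht$n, tail = bt)
    dplyr::mutate(ht, bf10 = bf$bf10, note = NA_character_,
                  test = label, .before = 1)
  }
  zero <- rep(0, nrow(binding))
  tests <- dplyr::bind_rows(
    group_test(binding$binding_ms, zero, "actual binding vs 0",
               t_tail, bf_tail),
    group_test(binding$modeled_binding_ms, zero, "modeled binding vs 0",
               t_tail, bf_tail),
    group_test(binding$binding_ms, binding$modeled_binding_ms,
               "actual vs modeled binding", "two", "two")
  )

  # modeled vs actual reports per condition, and modeled vs actual binding,
  # each with and without box-plot-rule outlier removal
  report_pairs <- kept_summaries |>
    dplyr::select("participant_id", "condition", "median_report_ms") |>
    dplyr::inner_join(model_results, by = c("participant_id", "condition"))
  correlations <- dplyr::bind_rows(
    purrr::map_dfr(design$conditions, function(cond) {
      cc <- dplyr::filter(report_pairs, .data$condition == cond)
      cor_both_ways(cc$modeled_report_ms, cc$median_report_ms,
                    paste0("modeled vs actual report, ", cond))
    }),
    cor_both_ways(binding$modeled_binding_ms, binding$binding_ms,
                  "modeled vs actual binding")
  )

  anova <- rm_anova_2way(profiles, dv = "rate",
                         factors = c("condition", "probe_location_deg"))

  run <- structure(
    list(
      design = design,
      config = list(binding_pair = binding_pair,
                    binding_tail = binding_tail,
                    fa_threshold = fa_threshold, seed = seed),
      n_participants = length(unique(trials$participant_id)),
      n_included = length(included),
      summaries = summaries,
      exclusions = exclusions,
      profiles = profiles,
      model_results = model_results,
      binding = binding,
      tests = tests,
      correlations = correlations,
      anova = anova
    ),
    class = "clockbind_run"
  )
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

default_binding_pair <- function(design) {
  if (design$report_task == "keypress-time") {
    if (!all(c("AS", "AO") %in% design$conditions)) {
      stop("Action-binding designs need AS and AO conditions; supply ",
           "`binding_pair` explicitly otherwise.", call. = FALSE)
    }
    c("AS", "AO")
  } else {
    other <- setdiff(design$conditions, "AS")
    if (!("AS" %in% design$conditions) || length(other) != 1) {
      stop("Cannot infer the binding pair from conditions ",
           paste(design$conditions, collapse = "/"),
           "; supply `binding_pair` explicitly.", call. = FALSE)
    }
    c(other, "AS")
  }
}

# a correlation reported with and without outlier removal; a zero-variance
# input is reported as undefined rather than as a correlation of 1
cor_both_ways <- function(mod, act, label) {
  one <- function(m, a, removed, note) {
    res <- tryCatch(spearman_one_tailed(m, a, direction = "positive"),
                    error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(comparison = label, outliers_removed = removed,
                     rho = NA_real_, n = length(m), p_value = NA_real_,
                     note = "undefined: zero variance")
    } else {
      tibble::tibble(comparison = label, outliers_removed = removed,
                     rho = res$statistic, n = res$n, p_value = res$p_value,
                     note = note)
    }
  }
  keep <- tryCatch(!boxplot_bivariate_outliers(mod, act),
                   error = function(e) rep(TRUE, length(mod)))
  dplyr::bind_rows(
    one(mod, act, 0L, NA_character_),
    if (all(keep)) {
      dplyr::mutate(one(mod, act, 0L, "no outliers detected"),
                    outliers_removed = 0L)
    } else {
      one(mod[keep], act[keep], sum(!keep), NA_character_)
    }
  )
}

#' Compare binding effects between two analysis runs
#'
#' Unpaired t test (pooled variance, as the degrees of freedom convention
#' `n1 + n2 - 2` implies) on the per-participant actual binding vectors of
#' two runs -- e.g. an attention-matched cohort against a standard cohort,
#' where a smaller effect is predicted in the matched cohort.
#'
#' @param run_a,run_b `clockbind_run` objects with disjoint participants.
#' @param tail `"two"`, `"greater"` (H1: binding larger in `run_a`) or
#'   `"less"`.
#' @param what `"actual"` or `"modeled"`: which binding vector to compare.
#' @return The one-row tibble of [unpaired_t()].
#' @export
compare_experiments <- function(run_a, run_b,
                                tail = c("two", "greater", "less"),
                                what = c("actual", "modeled")) {
  tail <- match.arg(tail)
  what <- match.arg(what)
  stopifnot(inherits(run_a, "clockbind_run"), inherits(run_b, "clockbind_run"))
  overlap <- intersect(run_a$binding$participant_id,
                       run_b$binding$participant_id)
  if (length(overlap) > 0) {
    stop("Runs share participant id(s): ", paste(overlap, collapse = ", "),
         "; an unpaired comparison needs disjoint cohorts.", call. = FALSE)
  }
  col <- if (what == "actual") "binding_ms" else "modeled_binding_ms"
  unpaired_t(run_a$binding[[col]], run_b$binding[[col]], tail = tail)
}

write_run <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$summaries |>
                     dplyr::left_join(dplyr::select(run$exclusions,
                                                    "participant_id",
                                                    "fa_excluded",
                                                    "mad_excluded",
                                                    "excluded"),
                                      by = "participant_id"),
                   file.path(output_dir, "participant_summary.csv"), na = "")
  readr::write_csv(run$profiles,
                   file.path(output_dir, "attention_profiles.csv"), na = "")
  readr::write_csv(run$model_results,
                   file.path(output_dir, "model_results.csv"), na = "")
  jsonlite::write_json(
    list(tests = run$tests, correlations = run$correlations,
         anova = run$anova),
    file.path(output_dir, "stats_report.json"),
    dataframe = "rows", na = "null", digits = NA, auto_unbox = TRUE
  )
  jsonlite::write_json(
    list(
      experiment_id = run$design$experiment_id,
      config = run$config,
      n_participants = run$n_participants,
      n_included = run$n_included,
      group_binding_ms = mean(run$binding$binding_ms),
      group_modeled_binding_ms = mean(run$binding$modeled_binding_ms),
      binding = run$binding
    ),
    file.path(output_dir, "run_report.json"),
    dataframe = "rows", na = "null", digits = NA, auto_unbox = TRUE
  )
  invisible(output_dir)
}

#' @export
print.clockbind_run <- function(x, ...) {
  cat("<clockbind_run> ", x$design$experiment_id, ": ",
      x$n_included, "/", x$n_participants, " participants included\n",
      sep = "")
  cat("  binding (", paste(x$config$binding_pair, collapse = " - "),
      "): actual ", round(mean(x$binding$binding_ms), 1),
      " ms, modeled ", round(mean(x$binding$modeled_binding_ms), 1),
      " ms\n", sep = "")
  invisible(x)
}
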