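#' Two-way within-participants ANOVA with partial eta squared
#'
#' The design used to compare probe detection rates across conditions and
#' probe locations: both factors vary within participants, so each effect
#' is tested against its own participant-by-effect interaction stratum
#' (fitted via [stats::aov()] with an `Error(participant/(A*B))` term).
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)` with the
#' error sum of squares taken from the effect's own stratum. An optional
#' Greenhouse-Geisser correction estimates the sphericity parameter epsilon
#' from orthonormal contrasts of the per-participant cell means and
#' multiplies both degrees of freedom by it.
#'
#' @param data Long tibble with one row per participant x factor-A level x
#'   factor-B level (a complete, balanced table; replicate rows within a
#'   cell are averaged first).
#' @param dv Name of the response column (e.g. `"rate"`).
#' @param participant Name of the participant identifier column.
#' @param factors Character length-2: the two within-participant factor
#'   columns.
#' @param sphericity `"none"` (default, uncorrected F) or
#'   `"greenhouse-geisser"`.
#' @return A tibble with one row per effect (`factor1`, `factor2`,
#'   `factor1:factor2`): `effect`, `df1`, `df2`, `statistic` (F),
#'   `p_value`, `partial_eta_sq`, plus `epsilon` and `p_gg` when the
#'   correction is requested.
#' @examples
#' \dontrun{
#' rm_anova_2way(profiles, dv = "rate",
#'               factors = c("condition", "probe_location_deg"))
#' }
#' @export
rm_anova_2way <- function(data, dv = "rate", participant = "participant_id",
                          factors = c("condition", "probe_location_deg"),
                          sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  stopifnot(is.data.frame(data), length(factors) == 2)
  cols <- c(participant, factors, dv)
  if (!all(cols %in% names(data))) {
    stop("`data` must have columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(participant, factors)))) |>
    dplyr::summarise(.y = mean(.data[[dv]]), .groups = "drop") |>
    dplyr::rename(.p = dplyr::all_of(participant),
                  .a = dplyr::all_of(factors[1]),
                  .b = dplyr::all_of(factors[2])) |>
    dplyr::mutate(.p = factor(.data$.p), .a = factor(.data$.a),
                  .b = factor(.data$.b))

  cells <- table(d$.p, d$.a, d$.b)
  if (any(cells != 1)) {
    stop("Design is incomplete or unbalanced: every participant needs ",
         "exactly one value per factor combination.", call. = FALSE)
  }

  fit <- stats::aov(.y ~ .a * .b + Error(.p / (.a * .b)), data = d)
  strata <- summary(fit)
  pull_effect <- function(stratum, term) {
    tab <- strata[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    j <- match("Residuals", rn)
    ss_e <- tab[i, "Sum Sq"]; ss_r <- tab[j, "Sum Sq"]
    tibble::tibble(
      df1 = tab[i, "Df"], df2 = tab[j, "Df"],
      statistic = tab[i, "F value"], p_value = tab[i, "Pr(>F)"],
      partial_eta_sq = ss_e / (ss_e + ss_r)
    )
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(pull_effect("Error: .p:.a", ".a"),
                  effect = factors[1], .before = 1),
    dplyr::mutate(pull_effect("Error: .p:.b", ".b"),
                  effect = factors[2], .before = 1),
    dplyr::mutate(pull_effect("Error: .p:.a:.b", ".a:.b"),
                  effect = paste(factors, collapse = ":"), .before = 1)
  )

  if (sphericity == "greenhouse-geisser") {
    eps <- c(gg_epsilon_main(d, ".a"), gg_epsilon_main(d, ".b"),
             gg_epsilon_interaction(d))
    out$epsilon <- eps
    out$p_gg <- stats::pf(out$statistic, eps * out$df1, eps * out$df2,
                          lower.tail = FALSE)
  }
  out
}

# Greenhouse-Geisser epsilon from orthonormal contrasts of a participant x
# cell matrix: eps = tr(M)^2 / ((k-1) tr(M^2)), M = C' S C.
gg_eps_from_matrix <- function(Y, C) {
  S <- stats::cov(Y)
  M <- t(C) %*% S %*% C
  sum(diag(M))^2 / (ncol(C) * sum(M^2))
}

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

gg_epsilon_main <- function(d, fac) {
  # collapse over the other factor, then pivot participants x levels
  m <- d |>
    dplyr::group_by(.data$.p, .data[[fac]]) |>
    dplyr::summarise(v = mean(.data$.y), .groups = "drop") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(fac), values_from = "v")
  Y <- as.matrix(m[, -1])
  gg_eps_from_matrix(Y, orthonormal_contrasts(ncol(Y)))
}

gg_epsilon_interaction <- function(d) {
  m <- d |>
    dplyr::arrange(.data$.p, .data$.a, .data$.b) |>
    tidyr::pivot_wider(id_cols = ".p", names_from = c(".a", ".b"),
                       values_from = ".y")
  Y <- as.matrix(m[, -1])
  a <- nlevels(d$.a); b <- nlevels(d$.b)
  C <- kronecker(orthonormal_contrasts(a), orthonormal_contrasts(b))
  gg_eps_from_matrix(Y, C)
}
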