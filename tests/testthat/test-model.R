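# independent brute-force oracle: explicit min-subtraction and weighted sum
oracle_report <- function(rates, tk) {
  d <- rates - min(rates)
  if (sum(d) == 0) return(mean(tk))
  s <- 0
  for (k in seq_along(tk)) s <- s + tk[k] * d[k] / sum(d)
  s
}

test_that("min-correction zeroes the least-attended location and keeps order", {
  expect_equal(correct_rates(c(0.2, 0.3, 0.5, 0.9, 0.6, 0.4)),
               c(0, 0.1, 0.3, 0.7, 0.4, 0.2))
  expect_equal(correct_rates(rep(0.37, 6)), rep(0, 6))
  set.seed(3)
  for (i in 1:20) {
    r <- stats::runif(6)
    cr <- correct_rates(r)
    expect_equal(which.min(r), which.min(cr))
    expect_equal(min(cr), 0)
    expect_equal(order(r), order(cr))
  }
  expect_error(correct_rates(numeric(0)), "non-empty")
  expect_error(correct_rates(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the modeled report is the corrected-rate weighted mean of T_k", {
  res <- model_timing_report(c(0.2, 0.3, 0.5, 0.9, 0.6, 0.4), "outcome")
  expect_equal(res$report_ms, 67.64706, tolerance = 1e-5)
  expect_equal(res$report_ms,
               oracle_report(c(0.2, 0.3, 0.5, 0.9, 0.6, 0.4),
                             model_grid("outcome")),
               tolerance = 1e-12)
  expect_false(res$fallback_used)
  expect_equal(sum(res$weights), 1)
  # a delta profile lands exactly on its grid point
  delta <- c(0, 0, 0, 1, 0, 0)
  expect_equal(model_timing_report(delta, "outcome")$report_ms, 50)
  # flat profile: uniform fallback, flagged; symmetric grid gives 0
  flat <- model_timing_report(rep(0.4, 6), "outcome")
  expect_true(flat$fallback_used)
  expect_equal(flat$report_ms, 0)
  expect_error(model_timing_report(rep(0.5, 5), "outcome"), "length")
})

test_that("the model matches the brute-force oracle on exhaustive small grids", {
  tk <- model_grid("outcome")
  lv <- c(0, 0.5, 1)
  grids <- as.matrix(expand.grid(lv, lv, lv, lv, lv, lv))
  for (i in seq_len(nrow(grids))) {
    r <- unname(grids[i, ])
    expect_equal(model_timing_report(r, "outcome")$report_ms,
                 oracle_report(r, tk), tolerance = 1e-12)
  }
  # random grids on the 0.1-step lattice, both tasks
  set.seed(12)
  for (i in 1:500) {
    r6 <- sample(seq(0, 1, 0.1), 6, replace = TRUE)
    expect_equal(model_timing_report(r6, "outcome")$report_ms,
                 oracle_report(r6, tk), tolerance = 1e-12)
    r11 <- sample(seq(0, 1, 0.1), 11, replace = TRUE)
    expect_equal(model_timing_report(r11, "action")$report_ms,
                 oracle_report(r11, model_grid("action")), tolerance = 1e-12)
  }
})

test_that("the model is invariant to affine maps of the rates", {
  set.seed(4)
  for (i in 1:50) {
    r <- stats::runif(6, 0.05, 0.6)
    base <- model_timing_report(r, "outcome")$report_ms
    a <- stats::runif(1, 0.2, 1.5)
    b <- stats::runif(1, 0, 0.2)
    ab <- a * r + b
    if (all(ab >= 0 & ab <= 1)) {
      expect_equal(model_timing_report(ab, "outcome")$report_ms, base,
                   tolerance = 1e-9)
    }
  }
})

test_that("the modeled report is bounded by the grid and monotone in mass shifts", {
  tk <- model_grid("action")
  set.seed(5)
  for (i in 1:100) {
    r <- stats::runif(11)
    m <- model_timing_report(r, "action")$report_ms
    expect_gte(m, min(tk))
    expect_lte(m, max(tk))
  }
  # moving detection mass towards a later T_k never decreases the report
  r <- c(0.1, 0.5, 0.3, 0.4, 0.2, 0.3)
  m0 <- model_timing_report(r, "outcome")$report_ms
  shifted <- r
  shifted[2] <- shifted[2] - 0.2 # move mass from T = -150 ...
  shifted[5] <- shifted[5] + 0.2 # ... to T = +150
  expect_gt(model_timing_report(shifted, "outcome")$report_ms, m0)
})

test_that("antisymmetric profiles on the symmetric grid mirror their reports", {
  r <- c(0.1, 0.2, 0.3, 0.5, 0.6, 0.7)
  fwd <- model_timing_report(r, "outcome")$report_ms
  rev <- model_timing_report(rev(r), "outcome")$report_ms
  expect_equal(rev, -fwd, tolerance = 1e-10)
  # so two such conditions produce a binding of twice the report magnitude
  expect_equal(fwd - rev, 2 * abs(fwd))
})

test_that("table-level modeling reproduces the per-profile computation", {
  tr <- tiny_trials(3)
  prof <- detection_profiles(tr, tiny_design())
  res <- model_reports(prof)
  expect_equal(nrow(res), 6) # 3 participants x 2 conditions
  one <- dplyr::filter(prof, participant_id == "P002", condition == "SO") |>
    dplyr::arrange(report_time_ms)
  expect_equal(
    res$modeled_report_ms[res$participant_id == "P002" &
                            res$condition == "SO"],
    oracle_report(one$rate, one$report_time_ms)
  )
  b <- modeled_bindings(res, c("SO", "AS"))
  wide <- tidyr::pivot_wider(res[, 1:3], names_from = condition,
                             values_from = modeled_report_ms)
  expect_equal(b$modeled_binding_ms, wide$SO - wide$AS)
  expect_error(modeled_bindings(res, c("VS", "AS")), "VS")
})
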