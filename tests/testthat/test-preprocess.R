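test_that("false-alarm rates are exact catch-trial ratios", {
  rows <- c(
    lapply(1:50, function(i) list(trial_type = "catch", detected = 0L)),
    lapply(1:2, function(i) list(trial_type = "timing",
                                 reported_angle_deg = 10)),
    lapply(1:100, function(i) {
      list(participant_id = "P2", trial_type = "catch",
           detected = as.integer(i <= 63))
    }),
    lapply(1:2, function(i) list(participant_id = "P2",
                                 trial_type = "timing",
                                 reported_angle_deg = 10))
  )
  tr <- manual_trials(rows)
  fa <- false_alarm_rates(tr)
  expect_equal(fa$false_alarm_rate[fa$participant_id == "P1"], 0)
  expect_equal(fa$false_alarm_rate[fa$participant_id == "P2"], 0.63)
  # pooled across conditions, and matching a brute-force row scan
  tr2 <- tiny_trials(3)
  fa2 <- false_alarm_rates(tr2)
  brute <- vapply(fa2$participant_id, function(p) {
    rows <- tr2[tr2$participant_id == p & tr2$trial_type == "catch", ]
    sum(rows$detected) / nrow(rows)
  }, numeric(1))
  expect_equal(fa2$false_alarm_rate, unname(brute))
  # a participant without catch trials is an explicit error
  no_catch <- manual_trials(list(list(trial_type = "timing",
                                      reported_angle_deg = 5)))
  expect_error(false_alarm_rates(no_catch), "catch")
})

test_that("detection profiles are exact per-location ratios with T_k attached", {
  d <- tiny_design(n_probe = 4)
  tr <- tiny_trials(2)
  prof <- detection_profiles(tr, tiny_design())
  # rates times trial counts are integer detection counts
  expect_equal(prof$rate * prof$n_trials,
               round(prof$rate * prof$n_trials))
  brute <- tr |>
    dplyr::filter(trial_type == "probe") |>
    dplyr::group_by(participant_id, condition, probe_location_deg) |>
    dplyr::summarise(rate = mean(detected), .groups = "drop")
  joined <- dplyr::inner_join(
    prof, brute, by = c("participant_id", "condition", "probe_location_deg")
  )
  expect_equal(joined$rate.x, joined$rate.y)
  # T_k grid: sound-time task maps location directly to time
  expect_equal(unique(prof$report_time_ms[prof$probe_location_deg == -50]),
               -250)
  # keypress-time task shifts by the event delay
  d4 <- design_preset("exp4")
  expect_equal(design_report_times(d4), seq(0, 500, 50))
  # a missing design location errors with its name
  expect_error(detection_profiles(dplyr::filter(tr, probe_location_deg != 30 |
                                                  is.na(probe_location_deg)),
                                  tiny_design()),
               "30")
})

test_that("timing errors match the per-row geometry oracle", {
  tr <- tiny_trials(2)
  err <- timing_errors(tr)
  tim <- dplyr::filter(tr, trial_type == "timing")
  oracle <- mapply(function(r, a) {
    d <- (r - a) %% 360
    if (d > 180) d <- d - 360
    d * 5
  }, tim$reported_angle_deg, tim$actual_event_angle_deg)
  expect_equal(err$error_ms, unname(oracle))
  # identity reports give zero error
  same <- manual_trials(list(list(trial_type = "timing",
                                  actual_event_angle_deg = 123,
                                  reported_angle_deg = 123)))
  expect_equal(timing_errors(same)$error_ms, 0)
  # a timing trial with no report is a row-level error
  bad <- manual_trials(list(list(trial_type = "timing",
                                 reported_angle_deg = NA_real_)))
  expect_error(timing_errors(bad), "row")
})

test_that("the MAD-median rule flags exactly the printed inequality", {
  expect_equal(mad_median_flags(c(3, 3, 3, 3, 3)), rep(FALSE, 5))
  expect_equal(mad_median_flags(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(mad_median_flags(c(1, 2, 3, 4, 5)), rep(FALSE, 5))
  expect_error(mad_median_flags(c(1, 2)), ">= 3")
  # direct-evaluation oracle on random samples
  set.seed(8)
  for (i in 1:20) {
    v <- stats::rt(11, df = 2) * 10
    oracle <- abs(v - stats::median(v)) * 0.6745 >
      3 * stats::median(abs(v - stats::median(v)))
    expect_equal(mad_median_flags(v), oracle)
  }
})

test_that("MAD-median flags are translation- and scale-equivariant", {
  set.seed(9)
  v <- stats::rnorm(15, 50, 20)
  f0 <- mad_median_flags(v)
  for (a in c(-2.5, 0.1, 7)) {
    for (b in c(-100, 0, 3.7)) {
      expect_equal(mad_median_flags(a * v + b), f0)
    }
  }
})

test_that("exclusions run false-alarm first, then the MAD rule, and are idempotent", {
  tr <- tiny_trials(8, seed = 21)
  summaries <- participant_summaries(tr)
  # plant one catastrophic false-alarm participant and one extreme median
  summaries$false_alarm_rate[summaries$participant_id == "P001"] <- 0.98
  summaries$median_report_ms[summaries$participant_id == "P002" &
                               summaries$condition == "AS"] <- 5000
  excl <- apply_exclusions(summaries)
  expect_true(excl$fa_excluded[excl$participant_id == "P001"])
  expect_false(excl$mad_excluded[excl$participant_id == "P001"])
  expect_true(excl$mad_excluded[excl$participant_id == "P002"])
  expect_equal(excl$reason[excl$participant_id == "P002"],
               "MAD-median report statistics")
  expect_equal(sum(excl$excluded), 2)
  # the FA participant's extreme value never enters the MAD reference
  ref <- attr(excl, "reference")
  expect_true(all(is.finite(ref$centre)))
  # idempotent on the surviving cohort with the stored reference
  kept <- dplyr::filter(summaries,
                        participant_id %in%
                          excl$participant_id[!excl$excluded])
  again <- apply_exclusions(kept, reference = ref)
  expect_equal(sum(again$excluded), 0)
  # a homogeneous cohort loses nobody
  homo <- tidyr::expand_grid(participant_id = paste0("H", 1:10),
                             condition = c("AS", "SO")) |>
    dplyr::mutate(false_alarm_rate = 0.04,
                  n_timing = 50,
                  median_report_ms = rep(seq(-20, 25, 5), 2),
                  sd_report_ms = rep(seq(60, 78, 2), 2))
  clean <- apply_exclusions(homo)
  expect_equal(sum(clean$excluded), 0)
})

test_that("binding effects difference condition medians with the stated signs", {
  summaries <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = 2),
    condition = rep(c("SO", "AS"), 2),
    false_alarm_rate = 0,
    n_timing = 10,
    median_report_ms = c(50, -50, 20, 20),
    sd_report_ms = 10
  )
  b <- binding_effects(summaries, c("SO", "AS"))
  expect_equal(b$binding_ms[b$participant_id == "A"], 100)
  expect_equal(b$binding_ms[b$participant_id == "B"], 0)
  expect_equal(mean(b$binding_ms), 50)
  expect_error(binding_effects(summaries, c("VS", "AS")), "VS")
})
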