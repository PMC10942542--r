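test_that("paired t reproduces the textbook formula and dz = t/sqrt(n)", {
  set.seed(10)
  x <- stats::rnorm(12, 0.4); y <- stats::rnorm(12)
  res <- paired_t(x, y, tail = "greater")
  d <- x - y
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(12))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(res$df, 11)
  expect_equal(res$p_value, stats::pt(t_oracle, 11, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$effect_size, t_oracle / sqrt(12), tolerance = 1e-10)
  # agreement with stats::t.test as an independent route
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "greater")
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  # printed-precision identities from reported statistics
  expect_lt(abs(9.78 / sqrt(18) - 2.30), 0.01)
  expect_error(paired_t(1:5, 1:5 + 2), "zero variance")
})

test_that("all-zero differences give t = 0 and two-tailed p = 1", {
  x <- c(1, 2, 3, 4)
  res <- paired_t(x, x + c(0.5, -0.5, 0.5, -0.5))
  expect_equal(res$p_value, 2 * stats::pt(abs(res$statistic), 3,
                                          lower.tail = FALSE))
  res0 <- paired_t(c(1, 2, 3), c(0, 2, 4)) # differences 1, 0, -1: mean 0
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("unpaired t uses pooled variance by default and ds = t*sqrt(1/n1+1/n2)", {
  set.seed(11)
  x <- stats::rnorm(9, 1); y <- stats::rnorm(14)
  res <- unpaired_t(x, y)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$df, 21)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(res$effect_size, res$statistic * sqrt(1 / 9 + 1 / 14),
               tolerance = 1e-10)
  expect_equal(round(-2.99 * sqrt(1 / 32 + 1 / 39), 2), -0.71)
  expect_equal(unpaired_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  w <- unpaired_t(x, y, variance = "welch")
  tw <- stats::t.test(x, y)
  expect_equal(w$statistic, unname(tw$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(tw$parameter), tolerance = 1e-8)
})

test_that("noncentral-t power reproduces the study's design values", {
  expect_equal(round(power_paired_t(0.89, 18), 2), 0.98)
  expect_equal(round(power_paired_t(0.89, 14), 2), 0.93)
  expect_equal(round(power_paired_t(0.70, 23), 2), 0.95)
  expect_gte(power_paired_t(0.89, 39), 0.99)
  # null effect: power equals alpha, both tails
  expect_equal(power_paired_t(0, 18), 0.05, tolerance = 1e-10)
  expect_equal(power_paired_t(0, 7, alpha = 0.10, tail = "two"), 0.10,
               tolerance = 1e-9)
  expect_error(power_paired_t(0.5, 10, alpha = 1.2), "alpha")
})

test_that("power increases strictly with effect size and sample size", {
  dz <- seq(0.1, 1.2, by = 0.1)
  expect_true(all(diff(vapply(dz, power_paired_t, numeric(1), n = 15)) > 0))
  ns <- seq(5, 60, by = 5)
  expect_true(all(diff(vapply(ns, function(n) power_paired_t(0.5, n),
                              numeric(1))) > 0))
})

test_that("Spearman correlation handles monotone, tied and directional cases", {
  x <- 1:8
  expect_equal(spearman_one_tailed(x, x^2)$statistic, 1)
  expect_equal(spearman_one_tailed(x, -x^3)$statistic, -1)
  # midranks: agreement with stats::cor's tie handling
  set.seed(13)
  xt <- c(1, 2, 2, 3, 5, 5, 7, 9)
  yt <- c(2, 1, 4, 4, 6, 8, 8, 9)
  expect_equal(spearman_one_tailed(xt, yt)$statistic,
               stats::cor(xt, yt, method = "spearman"))
  expect_error(spearman_one_tailed(rep(1, 6), 1:6), "Constant")
  # the two directions partition the permutation space
  res_p <- spearman_one_tailed(xt, yt, "positive")
  res_n <- spearman_one_tailed(xt, yt, "negative")
  expect_gte(res_p$p_value + res_n$p_value, 1) # overlap at ties only
})

test_that("the exact permutation p matches an independent enumeration oracle", {
  # oracle: recurse over orderings, score each with stats::cor
  enumerate_p <- function(x, y, direction) {
    rho_obs <- stats::cor(rank(x), rank(y))
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      unlist(lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }), recursive = FALSE)
    }
    rhos <- vapply(perms(rank(y)), function(p) stats::cor(rank(x), p),
                   numeric(1))
    if (direction == "positive") mean(rhos >= rho_obs - 1e-12)
    else mean(rhos <= rho_obs + 1e-12)
  }
  set.seed(14)
  x8 <- stats::rnorm(8); y8 <- 0.6 * x8 + stats::rnorm(8)
  res <- spearman_one_tailed(x8, y8, "positive")
  expect_true(res$exact)
  expect_equal(res$p_value, enumerate_p(x8, y8, "positive"), tolerance = 1e-12)
  # small-n negative direction, with ties
  x6 <- c(1, 2, 2, 4, 5, 6); y6 <- c(5, 6, 3, 3, 2, 1)
  expect_equal(spearman_one_tailed(x6, y6, "negative")$p_value,
               enumerate_p(x6, y6, "negative"), tolerance = 1e-12)
  # beyond the cutoff the t approximation takes over
  expect_false(spearman_one_tailed(stats::rnorm(12), stats::rnorm(12))$exact)
})

test_that("box-plot-rule outliers match brute-force Tukey fences", {
  set.seed(15)
  x <- stats::rnorm(23); y <- stats::rnorm(23)
  expect_equal(sum(boxplot_bivariate_outliers(x, y)), 0)
  # plant one extreme point: exactly that point flagged, df drop 21 -> 20
  x[7] <- 9
  flags <- boxplot_bivariate_outliers(x, y)
  expect_equal(which(flags), 7L)
  expect_equal(sum(!flags) - 2, 20)
  brute <- function(v) {
    q1 <- stats::quantile(v, 0.25, names = FALSE)
    q3 <- stats::quantile(v, 0.75, names = FALSE)
    v < q1 - 1.5 * (q3 - q1) | v > q3 + 1.5 * (q3 - q1)
  }
  expect_equal(flags, brute(x) | brute(y))
})

test_that("BH adjustment follows the step-up arithmetic", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.02, 6)), rep(0.02, 6))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)), rep(0.06, 6))
  set.seed(16)
  p <- stats::runif(9)
  adj <- bh_fdr(p)
  # independent step-up oracle: p * m / rank, then a cumulative minimum
  # from the largest p downwards, capped at 1
  o <- order(p)
  stepup <- rev(cummin(rev(p[o] * length(p) / seq_along(p))))
  oracle <- pmin(stepup, 1)[order(o)]
  expect_equal(adj, oracle)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
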