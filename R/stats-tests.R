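#' Paired-samples t test with the dz effect size
#'
#' Student's t on the pairwise differences `x - y`, with the standardized
#' effect size `dz = mean(d) / sd(d) = t / sqrt(n)` and a directional p
#' value when a one-tailed alternative is requested.
#'
#' @param x,y Paired numeric samples of equal length (>= 2).
#' @param tail `"two"`, `"greater"` (H1: mean(x - y) > 0) or `"less"`.
#' @return A one-row tibble: `method`, `statistic` (t), `df`, `p_value`,
#'   `tail`, `effect_size` (dz), `n`, `mean_diff`.
#' @examples
#' paired_t(rnorm(10, 1), rnorm(10), tail = "greater")
#' @export
paired_t <- function(x, y, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2, all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) {
    stop("Differences have zero variance; the t statistic is undefined.",
         call. = FALSE)
  }
  n <- length(d)
  t_stat <- mean(d) / (s / sqrt(n))
  tibble::tibble(
    method = "paired t",
    statistic = t_stat,
    df = n - 1,
    p_value = t_tail_p(t_stat, n - 1, tail),
    tail = tail,
    effect_size = t_stat / sqrt(n),
    effect_size_type = "dz",
    n = n,
    mean_diff = mean(d)
  )
}

#' Unpaired t test with the ds effect size
#'
#' Defaults to the Student (pooled-variance) test with `df = n1 + n2 - 2`,
#' and reports `ds = t * sqrt(1/n1 + 1/n2)`, the pooled-SD standardized
#' mean difference. Welch's unequal-variance test is available via
#' `variance`.
#'
#' @param x,y Independent numeric samples (each n >= 2).
#' @param tail `"two"`, `"greater"` (H1: mean(x) > mean(y)) or `"less"`.
#' @param variance `"pooled"` (Student, default) or `"welch"`.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`,
#'   `tail`, `effect_size` (ds), `n1`, `n2`.
#' @export
unpaired_t <- function(x, y, tail = c("two", "greater", "less"),
                       variance = c("pooled", "welch")) {
  tail <- match.arg(tail)
  variance <- match.arg(variance)
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2, length(y) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (variance == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 == 0) stop("Zero pooled variance.", call. = FALSE)
    t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) stop("Zero variance in both samples.", call. = FALSE)
    t_stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tibble::tibble(
    method = paste0("unpaired t (", variance, ")"),
    statistic = t_stat,
    df = df,
    p_value = t_tail_p(t_stat, df, tail),
    tail = tail,
    effect_size = t_stat * sqrt(1 / n1 + 1 / n2),
    effect_size_type = "ds",
    n1 = n1,
    n2 = n2
  )
}

t_tail_p <- function(t_stat, df, tail) {
  switch(tail,
         two = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
         greater = stats::pt(t_stat, df, lower.tail = FALSE),
         less = stats::pt(t_stat, df))
}

#' Power of the paired t test (noncentral t)
#'
#' Exact power under the noncentral t distribution with noncentrality
#' `dz * sqrt(n)` and `n - 1` degrees of freedom. For a two-tailed test
#' both rejection regions are counted.
#'
#' @param dz Standardized paired effect size.
#' @param n Number of pairs (>= 2).
#' @param alpha Significance level in (0, 1).
#' @param tail `"one"` or `"two"`.
#' @return Power as a single probability.
#' @examples
#' power_paired_t(dz = 0.89, n = 18) # 0.98
#' @export
power_paired_t <- function(dz, n, alpha = 0.05, tail = c("one", "two")) {
  tail <- match.arg(tail)
  stopifnot(is.numeric(dz), length(dz) == 1, is.finite(dz), n >= 2)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1).", call. = FALSE)
  }
  df <- n - 1
  ncp <- dz * sqrt(n)
  if (tail == "one") {
    stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  }
}

#' One-tailed Spearman rank correlation
#'
#' Spearman's rho on midranks (tie-corrected), with a directional p value:
#' an exact permutation p for small samples (`n <= exact_max`, full
#' enumeration of the `n!` rank orderings) and the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), neither constant.
#' @param direction `"positive"` (H1: rho > 0) or `"negative"`.
#' @param exact_max Largest n for which the exact permutation null is
#'   enumerated (default 9, about 3.6e5 orderings; beyond that the t
#'   approximation is used).
#' @return A one-row tibble: `method`, `statistic` (rho), `n`, `p_value`,
#'   `direction`, `exact`.
#' @export
spearman_one_tailed <- function(x, y, direction = c("positive", "negative"),
                                exact_max = 9) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 4, all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Constant input vector: rank correlation is undefined.",
         call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  exact <- n <= exact_max
  if (exact) {
    pm <- permutation_matrix(n)
    # rho for every permutation of y's ranks against x's ranks
    sums <- as.vector(matrix(ry[pm], nrow(pm)) %*% rx)
    rho_null <- (sums - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- if (direction == "positive") {
      mean(rho_null >= rho - 1e-12)
    } else {
      mean(rho_null <= rho + 1e-12)
    }
  } else {
    if (abs(rho) >= 1) {
      p <- if ((rho > 0) == (direction == "positive")) 0 else 1
    } else {
      t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- if (direction == "positive") {
        stats::pt(t_stat, n - 2, lower.tail = FALSE)
      } else {
        stats::pt(t_stat, n - 2)
      }
    }
  }
  tibble::tibble(method = "Spearman rank correlation",
                 statistic = rho, n = n, p_value = p,
                 direction = direction, exact = exact)
}

# all n! permutations of 1:n as a matrix (rows = permutations)
permutation_matrix <- function(n) {
  if (n == 1) return(matrix(1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    p <- permutation_matrix(n - 1)
    cbind(i, matrix(seq_len(n)[-i][p], nrow(p)))
  }))
}

#' Box-plot-rule bivariate outlier flags
#'
#' Flags a point when either coordinate falls outside its Tukey fences
#' (lower quartile minus `k` times the interquartile range, upper quartile
#' plus the same), the screening applied before correlation analyses so
#' that the degrees of freedom shrink by the number of removed points.
#'
#' @param x,y Numeric vectors of equal length (n >= 5).
#' @param k Fence multiplier (default 1.5).
#' @return Logical vector: `TRUE` marks an outlier.
#' @export
boxplot_bivariate_outliers <- function(x, y, k = 1.5) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 5, all(is.finite(x)), all(is.finite(y)), k > 0)
  outside <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    v < q[1] - k * iqr | v > q[2] + k * iqr
  }
  outside(x) | outside(y)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment across a family of comparisons.
#' A thin validating wrapper around [stats::p.adjust()].
#'
#' @param p Numeric p values in `[0, 1]`.
#' @return Adjusted p values, same length, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("`p` must be probabilities in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
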