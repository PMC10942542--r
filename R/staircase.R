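#' Simulate a 2-down-1-up staircase threshold procedure
#'
#' Two interleaved staircase lines titrate probe luminance against a
#' simulated observer: intensity is lowered after two consecutive
#' detections and raised after any miss, which converges on the 70.7%%
#' detection point. One line starts at the background luminance (128, an
#' increase line), the other above it (200, a decrease line); each trial
#' randomly picks a line that has not yet finished, and a line finishes
#' after `n_reversals` direction changes. The step starts at `step` and is
#' halved after each of a line's first three reversals (floor
#' `step_floor`); intensities are clamped to `clamp`.
#'
#' @param psychometric Function mapping luminance (8-bit units) to detection
#'   probability; must be monotone nondecreasing (checked on a coarse grid,
#'   violation raises a warning, not an error).
#' @param start Numeric length-2: starting intensities of the two lines.
#' @param step Initial step size, luminance units.
#' @param step_floor Smallest step after halving.
#' @param n_reversals Reversals per line before the line stops.
#' @param k_last Number of final reversal intensities per line averaged into
#'   the threshold.
#' @param clamp Length-2 intensity bounds.
#' @param max_trials Safety cap on total trials (degenerate observers may
#'   never reverse; the run then stops with a warning).
#' @param seed Integer seed.
#' @return A list of class `staircase_result`: `threshold` (mean of the last
#'   `k_last` reversal intensities of each line), `reversals` (tibble:
#'   `line`, `reversal`, `intensity`), and `trials` (tibble: `line`,
#'   `intensity`, `detected`).
#' @examples
#' obs <- function(l) plogis((l - 165) / 6)
#' simulate_staircase(obs, seed = 1)$threshold
#' @export
simulate_staircase <- function(psychometric,
                               start = c(128, 200),
                               step = 8, step_floor = 2,
                               n_reversals = 15, k_last = 10,
                               clamp = c(128, 255),
                               max_trials = 2000, seed = 1) {
  stopifnot(is.function(psychometric), length(start) == 2,
            step > 0, step_floor > 0, n_reversals >= 1, k_last >= 1)
  grid <- seq(clamp[1], clamp[2], length.out = 24)
  pg <- vapply(grid, psychometric, numeric(1))
  if (any(diff(pg) < -1e-8)) {
    warning("`psychometric` is not monotone nondecreasing on [",
            clamp[1], ", ", clamp[2], "].", call. = FALSE)
  }
  set.seed(seed)

  new_line <- function(s) {
    list(intensity = s, step = step, hits = 0L, direction = NA_character_,
         reversals = numeric(0), history = list())
  }
  lines <- lapply(start, new_line)
  total <- 0L

  while (any(vapply(lines, function(l) length(l$reversals), 0L) < n_reversals)
         && total < max_trials) {
    open <- which(vapply(lines, function(l) length(l$reversals), 0L) < n_reversals)
    i <- if (length(open) == 1) open else sample(open, 1)
    l <- lines[[i]]
    detected <- stats::runif(1) < psychometric(l$intensity)
    l$history[[length(l$history) + 1]] <- c(l$intensity, as.numeric(detected))

    move <- NULL
    if (detected) {
      l$hits <- l$hits + 1L
      if (l$hits == 2L) { move <- "down"; l$hits <- 0L }
    } else {
      move <- "up"
      l$hits <- 0L
    }
    if (!is.null(move)) {
      if (!is.na(l$direction) && move != l$direction) {
        l$reversals <- c(l$reversals, l$intensity)
        if (length(l$reversals) <= 3) {
          l$step <- max(l$step / 2, step_floor)
        }
      }
      l$direction <- move
      delta <- if (move == "down") -l$step else l$step
      l$intensity <- min(max(l$intensity + delta, clamp[1]), clamp[2])
    }
    lines[[i]] <- l
    total <- total + 1L
  }
  if (total >= max_trials) {
    warning("Staircase stopped after ", max_trials,
            " trials before completing all reversals.", call. = FALSE)
  }

  rev_tbl <- purrr::map_dfr(seq_along(lines), function(i) {
    r <- lines[[i]]$reversals
    tibble::tibble(line = i, reversal = seq_along(r), intensity = r)
  })
  trial_tbl <- purrr::map_dfr(seq_along(lines), function(i) {
    h <- lines[[i]]$history
    tibble::tibble(line = i,
                   intensity = vapply(h, `[`, numeric(1), 1),
                   detected = vapply(h, `[`, numeric(1), 2) == 1)
  })
  last_k <- rev_tbl |>
    dplyr::group_by(.data$line) |>
    dplyr::slice_tail(n = k_last) |>
    dplyr::ungroup()
  threshold <- if (nrow(last_k) > 0) mean(last_k$intensity) else NA_real_

  structure(list(threshold = threshold, reversals = rev_tbl,
                 trials = trial_tbl),
            class = "staircase_result")
}

#' @export
print.staircase_result <- function(x, ...) {
  cat("<staircase_result> threshold ", round(x$threshold, 1), " (",
      nrow(x$trials), " trials, ",
      paste(table(x$reversals$line), collapse = "+"), " reversals)\n",
      sep = "")
  invisible(x)
}
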