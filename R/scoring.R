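# Sleep/wake scoring of worn minutes.
#
# The scorer is a configurable windowed linear classifier in the Sadeh
# tradition: features are computed over a symmetric minute window around each
# epoch and combined linearly; non-negative scores classify as SLEEP. The
# published infant coefficient set is not reproduced here; the engine accepts
# any coefficient set via `scorer_config()`, and the defaults are chosen so
# the score is monotone non-increasing in activity (zero activity scores
# asleep, large activity scores awake). A refinement pass splits minutes
# into high/low activity at `mean(activity) * 0.72` and demotes high-activity
# sleep minutes, and ordered run-length smoothing rules then reconcile the
# series with diary-scale behaviour.

#' Scorer configuration
#'
#' @param intercept linear intercept (default 1).
#' @param w_mean weight on the window mean count (default -0.008).
#' @param w_above weight on the number of window epochs with counts above
#'   `above_level` (default -0.05).
#' @param w_sd weight on the window count standard deviation. Default 0:
#'   a non-zero value breaks the monotonicity guarantee (raising one
#'   minute's count can lower the window SD) and is opt-in.
#' @param w_log weight on `log10(1 + count)` of the epoch itself
#'   (default -0.3).
#' @param above_level count level for the `w_above` feature (default 80).
#' @param window_radius half-width of the feature window in minutes
#'   (default 5); edge windows are truncated, not padded.
#' @param refine_threshold_factor high/low activity split as a fraction of
#'   mean activity (default 0.72).
#' @param smoothing_rules ordered list of run-length rules, each
#'   `list(action = "fill_wake"|"drop_sleep", max_len = <minutes>)`; islands
#'   strictly shorter than `max_len` and flanked by the opposite state are
#'   rewritten. Defaults are placeholders standing in for the unavailable
#'   published 6-step rule set and are fully configurable.
#' @return an object of class `scorer_config`.
#' @export
scorer_config <- function(intercept = 1, w_mean = -0.008, w_above = -0.05,
                          w_sd = 0, w_log = -0.3, above_level = 80,
                          window_radius = 5L, refine_threshold_factor = 0.72,
                          smoothing_rules = list(
                            list(action = "drop_sleep", max_len = 5L),
                            list(action = "fill_wake", max_len = 5L))) {
  stopifnot(window_radius >= 1L,
            refine_threshold_factor > 0, refine_threshold_factor <= 1)
  structure(list(intercept = intercept, w_mean = w_mean, w_above = w_above,
                 w_sd = w_sd, w_log = w_log, above_level = above_level,
                 window_radius = as.integer(window_radius),
                 refine_threshold_factor = refine_threshold_factor,
                 smoothing_rules = smoothing_rules),
            class = "scorer_config")
}

roll_sum <- function(x, radius) {
  # truncated-window rolling sum, NA treated as absent
  n <- length(x)
  x0 <- ifelse(is.na(x), 0, x)
  cs <- c(0, cumsum(x0))
  hi <- pmin(seq_len(n) + radius, n)
  lo <- pmax(seq_len(n) - radius, 1L)
  cs[hi + 1L] - cs[lo]
}

#' Linear sleep score per minute
#'
#' @param counts per-minute activity counts; `NA` propagates to an `NA`
#'   score.
#' @param cfg a [scorer_config()].
#' @return numeric score vector; the minute classifies SLEEP when the score
#'   is `>= 0` (ties sleep).
#' @export
score_probability <- function(counts, cfg = scorer_config()) {
  n <- length(counts)
  r <- cfg$window_radius
  n_valid <- roll_sum(!is.na(counts), r)
  win_mean <- roll_sum(counts, r) / pmax(n_valid, 1)
  n_above <- roll_sum(!is.na(counts) & counts > cfg$above_level, r)
  if (cfg$w_sd != 0) {
    win_sq <- roll_sum(counts^2, r)
    win_var <- pmax(win_sq / pmax(n_valid, 1) - win_mean^2, 0)
    sd_term <- cfg$w_sd * sqrt(win_var)
  } else {
    sd_term <- 0
  }
  score <- cfg$intercept + cfg$w_mean * win_mean + cfg$w_above * n_above +
    sd_term + cfg$w_log * log10(1 + counts)
  score[is.na(counts)] <- NA_real_
  score
}

#' Split minutes into high/low activity at a fraction of mean activity
#'
#' @param counts per-minute counts over worn minutes (`NA` allowed).
#' @param factor threshold fraction of the mean (default 0.72).
#' @return list with `threshold` and logical `high` (`counts >= threshold`;
#'   `NA` where counts are missing).
#' @export
refine_high_low <- function(counts, factor = 0.72) {
  if (all(is.na(counts))) stop("cannot compute activity threshold: all minutes missing")
  threshold <- mean(counts, na.rm = TRUE) * factor
  list(threshold = threshold, high = counts >= threshold)
}

#' Apply ordered run-length smoothing rules
#'
#' Each rule rewrites state "islands" strictly shorter than its `max_len`
#' that are flanked on both sides by the opposite state: `"fill_wake"` turns
#' short wake islands inside sleep into sleep; `"drop_sleep"` removes short
#' sleep islands inside wake. MISSING minutes are never altered and break
#' runs (an island bordered by MISSING is left untouched). The operation is
#' idempotent.
#'
#' @param states integer vector (1 sleep, 0 wake, NA missing).
#' @param rules ordered rule list (see [scorer_config()]).
#' @return smoothed state vector.
#' @export
apply_smoothing <- function(states, rules) {
  for (rule in rules) {
    target <- switch(rule$action, fill_wake = 0L, drop_sleep = 1L,
                     stop("unknown smoothing action: ", rule$action))
    opposite <- 1L - target
    repeat {
      runs <- state_runs(states)
      k <- nrow(runs)
      if (k == 0L) break
      left_ok <- c(FALSE, !is.na(runs$value[-k]) & runs$value[-k] == opposite)
      right_ok <- c(!is.na(runs$value[-1]) & runs$value[-1] == opposite, FALSE)
      hit <- which(!is.na(runs$value) & runs$value == target &
                     runs$length < rule$max_len & left_ok & right_ok)
      if (length(hit) == 0L) break
      for (i in hit) states[runs$start[i]:runs$end[i]] <- opposite
    }
  }
  states
}

#' Full scorer: linear rule, high/low refinement, smoothing
#'
#' @param counts per-minute counts (`NA` = missing/non-wear).
#' @param cfg a [scorer_config()].
#' @return integer state vector (1 sleep, 0 wake, NA missing).
#' @export
score_sleep <- function(counts, cfg = scorer_config()) {
  score <- score_probability(counts, cfg)
  states <- ifelse(is.na(score), NA_integer_, as.integer(score >= 0))
  hl <- refine_high_low(counts, cfg$refine_threshold_factor)
  demote <- !is.na(hl$high) & hl$high & !is.na(counts) & counts > 0 &
    !is.na(states) & states == 1L
  states[demote] <- 0L
  apply_smoothing(states, cfg$smoothing_rules)
}
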