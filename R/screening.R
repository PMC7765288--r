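# Per-day validity and per-assessment inclusion rules.
#
# A recording day can fail independently per variable family: device removal
# is tolerated up to 1 h for partial-day variables, 3 h for entire-day
# variables and 5 min for movement-count variables; clock-time variables
# fail when any removal intersects a 30-min window centred on the
# parent-reported sleep on-/offset. Sick days and days with poor
# actigraphy/diary agreement fail wholesale.

#' Default removal-tolerance thresholds (minutes)
#' @return named list with `partial_day`, `entire_day`, `movement_count`,
#'   and `clock_window` (half-width of the on-/offset window).
#' @export
screening_thresholds <- function() {
  list(partial_day = 60, entire_day = 180, movement_count = 5,
       clock_window = 15)
}

#' Screen one recording day
#'
#' @param wear logical wear flag per minute of the recording (FALSE =
#'   removed / missing).
#' @param idx_night,idx_day,idx_cal 1-based minute indices of the night
#'   window, the daytime window (previous sleep offset to sleep onset) and
#'   the calendar day. `idx_day` may be `NULL` when no flanking night exists.
#' @param reported_onset_idx,reported_offset_idx minute indices of the
#'   parent-reported sleep on-/offset (NA when unreported; the clock-time
#'   check then falls back to valid).
#' @param sick TRUE when the infant was sick that day (beyond a common
#'   cold): invalidates all families.
#' @param fit_ratio actigraphy/diary agreement from [diary_fit()]; `NA`
#'   keeps the day (with the ratio unrecorded).
#' @param fit_cutoff minimum acceptable agreement (default 0.80; the
#'   published appendix criterion is not available, so this cutoff is a
#'   documented stand-in).
#' @param thresholds see [screening_thresholds()].
#' @return list with `valid_by_family` (named logical over the four
#'   screening families), `removal_minutes` (named), `sick`, `fit_ratio`.
#' @export
screen_day <- function(wear, idx_night, idx_day = NULL, idx_cal = NULL,
                       reported_onset_idx = NA, reported_offset_idx = NA,
                       sick = FALSE, fit_ratio = NA_real_, fit_cutoff = 0.80,
                       thresholds = screening_thresholds()) {
  n <- length(wear)
  clip <- function(idx) idx[idx >= 1L & idx <= n]
  removal <- !wear
  rm_in <- function(idx) if (length(idx) == 0L) 0L else sum(removal[clip(idx)])

  rm_partial <- rm_in(c(idx_night, idx_day))
  rm_entire <- if (is.null(idx_cal)) rm_in(c(idx_night, idx_day)) else rm_in(idx_cal)
  rm_move <- rm_in(idx_night)

  w <- thresholds$clock_window
  clock_hit <- FALSE
  for (ref in c(reported_onset_idx, reported_offset_idx)) {
    if (!is.na(ref)) {
      win <- clip(seq.int(ref - w, ref + w))
      if (length(win) && any(removal[win])) clock_hit <- TRUE
    }
  }

  valid <- c(
    partial_day   = rm_partial <= thresholds$partial_day,
    entire_day    = rm_entire <= thresholds$entire_day,
    movement_count = rm_move <= thresholds$movement_count,
    clock_time    = !clock_hit
  )
  if (isTRUE(sick) || (!is.na(fit_ratio) && fit_ratio < fit_cutoff)) {
    valid[] <- FALSE
  }
  list(valid_by_family = valid,
       removal_minutes = c(partial_day = rm_partial, entire_day = rm_entire,
                           movement_count = rm_move),
       sick = isTRUE(sick), fit_ratio = fit_ratio)
}

#' Actigraphy/diary agreement ratio
#'
#' Fraction of minutes where the scored state matches the diary state,
#' over minutes where both are informative.
#'
#' @param states scored states (1/0/NA).
#' @param diary_state diary states (1/0/NA).
#' @return agreement in `[0, 1]`, or `NA` (with a warning) when no minute is
#'   informative in both sources.
#' @export
diary_fit <- function(states, diary_state) {
  both <- !is.na(states) & !is.na(diary_state)
  if (!any(both)) {
    warning("no diary coverage: agreement ratio undefined, day kept")
    return(NA_real_)
  }
  mean(states[both] == diary_state[both])
}

#' Assessment-level inclusion decision
#'
#' @param n_valid_days valid recording days for base variables.
#' @param n_valid_days_variability valid days countable for variability
#'   variables (variability slots are NA below `min_days_variability`, but
#'   this alone does not exclude the assessment).
#' @param timezone_change TRUE when a >1 h time-zone change occurred less
#'   than a week before recording.
#' @param sleep_medication,medical_problem,psych_trauma metadata flags.
#' @param min_days,min_days_variability minimum valid days (defaults 3 / 5).
#' @return list with `included`, `reason` (NA when included; exactly one
#'   primary code otherwise), `variability_ok`.
#' @export
assessment_inclusion <- function(n_valid_days, n_valid_days_variability,
                                 timezone_change = FALSE,
                                 sleep_medication = FALSE,
                                 medical_problem = FALSE,
                                 psych_trauma = FALSE,
                                 min_days = 3L, min_days_variability = 5L) {
  reason <- NA_character_
  if (isTRUE(timezone_change)) reason <- "timezone_change"
  else if (isTRUE(sleep_medication)) reason <- "sleep_medication"
  else if (isTRUE(medical_problem)) reason <- "medical_problem"
  else if (isTRUE(psych_trauma)) reason <- "psych_trauma"
  else if (n_valid_days < min_days) reason <- "too_few_valid_days"
  list(included = is.na(reason), reason = reason,
       variability_ok = n_valid_days_variability >= min_days_variability)
}
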