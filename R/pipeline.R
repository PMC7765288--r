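# Assessment-level pipeline: scored minutes + night anchors -> per-day
# variables -> 48-slot assessment summary.

#' Per-day variables and validity for one assessment
#'
#' @param states full-recording scored states (1/0/NA) on the absolute
#'   minute grid (minute m, 0-based, lives on calendar day `m %/% 1440 + 1`).
#' @param activity per-minute activity counts (NA where not worn).
#' @param wear logical wear flags.
#' @param diary_state per-minute diary states (1/0/NA).
#' @param anchors data.frame with one row per night: `night_id`,
#'   `bedtime_abs`, `getup_abs` (absolute minutes), `bedtime_ext` (extended
#'   evening clock), `bedtime_reported`, `getup_reported`.
#' @param sick_nights night ids flagged sick (all families invalid).
#' @param fit_cutoff minimum actigraphy/diary agreement per day
#'   (default 0.80).
#' @param min_run,wake_follow_min,nap_min calculator rules, see
#'   [night_variables()] and [day_variables()].
#' @param wake_freq_follow_rule see [night_variables()].
#' @return list with `daily` (data.frame, one row per night: variable
#'   columns `v1`..`v44` for the per-day ids plus validity flags) and
#'   `onsets`/`offsets` (absolute minutes).
#' @export
daily_variables <- function(states, activity, wear, diary_state, anchors,
                            sick_nights = integer(), fit_cutoff = 0.80,
                            min_run = 10L, wake_follow_min = 15L,
                            nap_min = 20L, wake_freq_follow_rule = FALSE) {
  K <- nrow(anchors)
  n <- length(states)
  per_day_ids <- c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19, 21, 23, 25, 27, 28,
                   30, 32, 34, 36, 38, 40, 42, 44)
  vals <- matrix(NA_real_, nrow = K, ncol = length(per_day_ids),
                 dimnames = list(NULL, paste0("v", per_day_ids)))
  valid <- matrix(FALSE, nrow = K, ncol = 4,
                  dimnames = list(NULL, c("partial_day", "entire_day",
                                          "movement_count", "clock_time")))
  onsets <- offsets <- rep(NA_real_, K)
  fit <- rep(NA_real_, K)

  for (d in seq_len(K)) {
    a <- anchors[d, ]
    onsets[d] <- find_onset(states, a$bedtime_abs, a$getup_abs, min_run)
    offsets[d] <- find_offset(states, a$bedtime_abs, a$getup_abs, min_run)
  }

  clip <- function(idx) idx[idx >= 1L & idx <= n]
  for (d in seq_len(K)) {
    a <- anchors[d, ]
    idx_night <- if (!is.na(onsets[d]) && !is.na(offsets[d]) &&
                     offsets[d] >= onsets[d])
      (onsets[d] + 1L):(offsets[d] + 1L) else integer(0)
    idx_dayw <- if (d > 1L && !is.na(offsets[d - 1L]) && !is.na(onsets[d]) &&
                    onsets[d] > offsets[d - 1L] + 1L)
      (offsets[d - 1L] + 2L):onsets[d] else integer(0)
    day0 <- (d - 1L) * 1440L
    idx_cal <- clip((day0 + 420L + 1L):(day0 + 1860L))  # 07:00-anchored 24 h

    # diary-reported on-/offset for the clock-time removal window
    rep_on <- rep_off <- NA
    ds <- diary_state
    cand_on <- which(!is.na(ds) & ds == 1L)
    cand_on <- cand_on[cand_on >= a$bedtime_abs + 1L & cand_on <= a$getup_abs + 1L]
    if (length(cand_on)) {
      rep_on <- cand_on[1]
      rep_off <- cand_on[length(cand_on)]
    }

    fit[d] <- if (length(c(idx_night, idx_dayw)))
      suppressWarnings(diary_fit(states[clip(c(idx_dayw, idx_night))],
                                 diary_state[clip(c(idx_dayw, idx_night))]))
      else NA_real_

    sc <- screen_day(wear, clip(idx_night), clip(idx_dayw), idx_cal,
                     reported_onset_idx = rep_on, reported_offset_idx = rep_off,
                     sick = d %in% sick_nights, fit_ratio = fit[d],
                     fit_cutoff = fit_cutoff)
    valid[d, ] <- sc$valid_by_family[colnames(valid)]

    nv <- night_variables(states, activity, d, a$bedtime_abs, a$getup_abs,
                          min_run, wake_follow_min, wake_freq_follow_rule)
    dv <- day_variables(states,
                        if (d > 1L) offsets[d - 1L] else NA_real_,
                        onsets[d], nap_min)
    cv <- clock_window_variables(states, d)
    row <- c(nv, dv, cv)
    vals[d, paste0("v", names(row))] <- row
  }

  # apply family validity
  fam <- screening_family()
  for (j in seq_along(per_day_ids)) {
    f <- fam[per_day_ids[j]]
    vals[!valid[, f], j] <- NA_real_
  }

  list(daily = data.frame(night_id = seq_len(K), vals, valid,
                          diary_fit = fit, check.names = FALSE),
       onsets = onsets, offsets = offsets)
}

#' Aggregate daily variables into a 48-slot assessment summary
#'
#' Base variables are means across their valid days; variability variables
#' are sample SDs across the base variable's valid days (requiring at least
#' `min_days_variability` of them); the three Sleep Regularity Indices are
#' computed across the calendar days valid for the entire-day family.
#'
#' @param daily result of [daily_variables()].
#' @param states full-recording state vector (for the regularity indices).
#' @param min_days,min_days_variability assessment-level day minima
#'   (defaults 3 and 5).
#' @return list with `values` (named numeric vector, names "1".."48"),
#'   `n_valid_days`, `n_valid_days_variability`.
#' @export
aggregate_assessment <- function(daily, states, min_days = 3L,
                                 min_days_variability = 5L) {
  reg <- variable_registry()
  fam <- screening_family()
  d <- daily$daily
  values <- stats::setNames(rep(NA_real_, 48L), as.character(1:48))
  n_valid <- sum(d$partial_day)

  for (id in reg$id[!reg$is_variability & !grepl("Regularity", reg$name)]) {
    col <- paste0("v", id)
    x <- d[[col]][d[[fam[id]]]]
    x <- x[!is.na(x)]
    if (length(x) >= min_days) values[as.character(id)] <- mean(x)
  }
  for (id in reg$id[reg$is_variability]) {
    base <- reg$base_id[reg$id == id]
    col <- paste0("v", base)
    x <- d[[col]][d[[fam[base]]]]
    values[as.character(id)] <- variability_across_days(x, min_days_variability)
  }
  ed_days <- d$night_id[d$entire_day]
  if (length(ed_days) >= min_days) {
    values["46"] <- sleep_regularity_index(states, "whole", days = ed_days)
    values["47"] <- sleep_regularity_index(states, "day", days = ed_days)
    values["48"] <- sleep_regularity_index(states, "night", days = ed_days)
  }
  n_var <- {
    x <- d$v1[d[[fam[1L]]]]
    sum(!is.na(x))
  }
  list(values = values, n_valid_days = n_valid,
       n_valid_days_variability = n_var)
}

#' Process one assessment end to end
#'
#' Convenience wrapper: [daily_variables()] then [aggregate_assessment()].
#'
#' @inheritParams daily_variables
#' @inheritParams aggregate_assessment
#' @param ... passed to [daily_variables()].
#' @return list with `summary` (48-slot named vector), `daily`,
#'   `n_valid_days`, `n_valid_days_variability`.
#' @export
process_assessment <- function(states, activity, wear, diary_state, anchors,
                               sick_nights = integer(), min_days = 3L,
                               min_days_variability = 5L, ...) {
  dv <- daily_variables(states, activity, wear, diary_state, anchors,
                        sick_nights = sick_nights, ...)
  ag <- aggregate_assessment(dv, states, min_days, min_days_variability)
  list(summary = ag$values, daily = dv$daily,
       n_valid_days = ag$n_valid_days,
       n_valid_days_variability = ag$n_valid_days_variability,
       onsets = dv$onsets, offsets = dv$offsets)
}
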