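# Per-day sleep variable calculators.
#
# Time conventions: a recording is laid out on an absolute minute grid where
# minute m (0-based) belongs to calendar day `m %/% 1440 + 1` at clock
# minute `m %% 1440`. The minute grid is half-open: "a minute asleep" is an
# epoch whose scored state is SLEEP. Night d runs from the reported bedtime
# on day d's evening to the reported get-up time on day d+1's morning; the
# daytime window of day d runs from the sleep offset of night d-1 to the
# sleep onset of night d. Fixed-clock ("entire-day") variables use a
# 24-h span anchored at 07:00, split into 7 am-7 pm and 7 pm-7 am halves,
# so that day + night sleep durations add up to the 24-h duration exactly.
#
# Counting convention: sleep period and sleep opportunity are inclusive
# epoch counts (last - first + 1), so Total Sleep Time + Wake after Sleep
# Onset equals the Sleep Period length minute-for-minute.

#' Find sleep onset for one night
#'
#' The first minute of the first sleep run of at least `min_run` consecutive
#' minutes at or after bedtime; if the infant is already asleep at bedtime,
#' the first minute of that ongoing run (before bedtime) is returned.
#'
#' @param states full-recording state vector (1/0/NA), 1-based index
#'   `m + 1` for absolute minute `m`.
#' @param bedtime_abs,getup_abs absolute minutes (0-based) of bedtime and
#'   get-up.
#' @param min_run minimum qualifying sleep-run length (default 10).
#' @return absolute minute of onset, or `NA` when no qualifying run exists
#'   before get-up.
#' @export
find_onset <- function(states, bedtime_abs, getup_abs, min_run = 10L) {
  bed_i <- bedtime_abs + 1L
  getup_i <- getup_abs + 1L
  if (bed_i < 1L || bed_i > length(states)) return(NA_real_)
  # runs never span a full day; a window around the night suffices
  lo <- max(1L, bed_i - 1440L)
  hi <- min(length(states), getup_i + 1440L)
  runs <- state_runs(states[lo:hi])
  runs$start <- runs$start + lo - 1L
  runs$end <- runs$end + lo - 1L
  if (!is.na(states[bed_i]) && states[bed_i] == 1L) {
    r <- runs[runs$start <= bed_i & runs$end >= bed_i, ]
    return(r$start[1] - 1L)
  }
  cand <- runs[!is.na(runs$value) & runs$value == 1L &
                 runs$length >= min_run &
                 runs$start >= bed_i & runs$start <= getup_i, ]
  if (nrow(cand) == 0L) return(NA_real_)
  cand$start[1] - 1L
}

#' Find sleep offset for one night
#'
#' Mirror of [find_onset()]: the last minute of the last sleep run of at
#' least `min_run` consecutive minutes ending at or before get-up time; if
#' asleep at get-up, the last minute of that ongoing run (after get-up).
#'
#' @inheritParams find_onset
#' @return absolute minute of offset, or `NA`.
#' @export
find_offset <- function(states, bedtime_abs, getup_abs, min_run = 10L) {
  bed_i <- bedtime_abs + 1L
  getup_i <- getup_abs + 1L
  if (getup_i < 1L || getup_i > length(states)) return(NA_real_)
  lo <- max(1L, bed_i - 1440L)
  hi <- min(length(states), getup_i + 1440L)
  runs <- state_runs(states[lo:hi])
  runs$start <- runs$start + lo - 1L
  runs$end <- runs$end + lo - 1L
  if (!is.na(states[getup_i]) && states[getup_i] == 1L) {
    r <- runs[runs$start <= getup_i & runs$end >= getup_i, ]
    return(r$end[1] - 1L)
  }
  cand <- runs[!is.na(runs$value) & runs$value == 1L &
                 runs$length >= min_run &
                 runs$end <= getup_i & runs$end >= bed_i, ]
  if (nrow(cand) == 0L) return(NA_real_)
  cand$end[nrow(cand)] - 1L
}

#' Night variables for one night
#'
#' Computes variable ids 1, 3, 5, 7, 9, 11, 13, 15, 17, 19, 21, 23, 25, 27,
#' 28, 30 from the scored states and activity counts of one night.
#'
#' @param states,activity full-recording vectors.
#' @param night_id night number d (1-based; night d starts on calendar
#'   day d).
#' @param bedtime_abs,getup_abs absolute minutes of the (possibly
#'   fallen-back) reported bedtime / get-up time.
#' @param min_run onset/offset sleep-run rule (default 10).
#' @param wake_follow_min a nocturnal wake run only counts for *Longest
#'   Nocturnal Wake* when followed by at least this many minutes of
#'   consecutive sleep (default 15).
#' @param wake_freq_follow_rule when TRUE, variable 25 counts only wake
#'   periods satisfying the follow rule as well; default FALSE (any maximal
#'   wake run in the sleep period counts).
#' @return named numeric vector over the computed ids (names "1","3",...);
#'   all NA when no onset/offset can be determined.
#' @export
night_variables <- function(states, activity, night_id, bedtime_abs,
                            getup_abs, min_run = 10L, wake_follow_min = 15L,
                            wake_freq_follow_rule = FALSE) {
  ids <- c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19, 21, 23, 25, 27, 28, 30)
  out <- stats::setNames(rep(NA_real_, length(ids)), as.character(ids))
  onset <- find_onset(states, bedtime_abs, getup_abs, min_run)
  offset <- find_offset(states, bedtime_abs, getup_abs, min_run)
  day0 <- (night_id - 1L) * 1440L
  out["1"] <- bedtime_abs - day0                   # extended evening clock
  out["3"] <- getup_abs %% 1440                    # morning clock
  if (is.na(onset) || is.na(offset) || offset < onset) return(out)

  onset_ext <- onset - day0
  offset_ext <- offset - day0
  out["5"] <- onset_ext
  out["7"] <- max(0, onset - bedtime_abs)
  out["9"] <- offset %% 1440
  # midpoint on the extended clock, expressed as minutes after midnight
  # (slightly negative for rare pre-midnight midsleeps; reduced modulo 1440
  # only when formatting as a clock string)
  out["11"] <- (onset_ext + offset_ext) / 2 - 1440

  asleep_at <- function(abs_min) {
    i <- abs_min + 1L
    i >= 1L && i <= length(states) && !is.na(states[i]) && states[i] == 1L
  }
  opp_start <- if (asleep_at(bedtime_abs)) onset else bedtime_abs
  opp_end <- if (asleep_at(getup_abs)) offset else getup_abs
  out["13"] <- opp_end - opp_start + 1

  per_idx <- (onset + 1L):(offset + 1L)
  per <- states[per_idx]
  out["15"] <- length(per)
  out["17"] <- sum(per == 1L, na.rm = TRUE)
  out["19"] <- out["17"] / out["13"] * 100
  out["21"] <- sum(per == 0L, na.rm = TRUE)

  runs <- state_runs(per)
  wake_rows <- which(!is.na(runs$value) & runs$value == 0L)
  followed <- vapply(wake_rows, function(i) {
    i < nrow(runs) && !is.na(runs$value[i + 1]) && runs$value[i + 1] == 1L &&
      runs$length[i + 1] >= wake_follow_min
  }, logical(1))
  qual <- wake_rows[followed]
  out["23"] <- if (length(qual)) max(runs$length[qual]) else 0
  n_wake <- if (wake_freq_follow_rule) length(qual) else length(wake_rows)
  out["25"] <- n_wake / (out["15"] / 60)

  act <- activity[per_idx]
  out["27"] <- if (sum(!is.na(act)) >= 2L) stats::sd(act, na.rm = TRUE) else NA_real_
  out["28"] <- if (any(!is.na(act))) mean(act > 0, na.rm = TRUE) else NA_real_
  out["30"] <- longest_run(per, 1L)
  out
}

#' Daytime variables for one analysis day
#'
#' Variable ids 32 (*Longest Wake*), 34 (*Nap Counter*: daytime sleep runs
#' strictly exceeding `nap_min` minutes) and 36 (*Sleep after Wake Onset*)
#' over the window from the previous night's sleep offset to this night's
#' sleep onset (both exclusive).
#'
#' @param states full-recording state vector.
#' @param offset_prev_abs,onset_abs absolute minutes of the flanking sleep
#'   offset/onset.
#' @param nap_min naps must strictly exceed this run length (default 20).
#' @return named numeric vector ids 32, 34, 36 (NA when a flanking anchor is
#'   missing).
#' @export
day_variables <- function(states, offset_prev_abs, onset_abs, nap_min = 20L) {
  out <- stats::setNames(rep(NA_real_, 3L), c("32", "34", "36"))
  if (is.na(offset_prev_abs) || is.na(onset_abs)) return(out)
  lo <- offset_prev_abs + 2L   # first minute after the offset epoch (1-based)
  hi <- onset_abs              # last minute before the onset epoch (1-based)
  if (hi < lo) return(out)
  win <- states[lo:hi]
  runs <- state_runs(win)
  sleep_runs <- runs[!is.na(runs$value) & runs$value == 1L, ]
  out["32"] <- longest_run(win, 0L)
  out["34"] <- sum(sleep_runs$length > nap_min)
  out["36"] <- sum(win == 1L, na.rm = TRUE)
  out
}

#' Fixed-clock window variables for one 24-h span
#'
#' Variable ids 38, 40, 42, 44 over the 24-h span anchored at 07:00 of
#' calendar day d: *Sleep Duration Day* counts sleep between 7 am and 7 pm,
#' *Sleep Duration Night* between 7 pm and 7 am of the next day, and
#' *Sleep Duration 24 h* is their sum, so day + night = 24 h by
#' construction.
#'
#' @param states full-recording state vector.
#' @param day calendar day d (1-based).
#' @return named numeric vector ids 38, 40, 42, 44.
#' @export
clock_window_variables <- function(states, day) {
  day0 <- (day - 1L) * 1440L
  idx_day <- (day0 + 420L + 1L):(day0 + 1140L)        # [07:00, 19:00)
  idx_night <- (day0 + 1140L + 1L):(day0 + 1860L)     # [19:00, 07:00 next)
  clip <- function(idx) idx[idx >= 1L & idx <= length(states)]
  sleep_in <- function(idx) {
    idx <- clip(idx)
    if (length(idx) == 0L) return(NA_real_)
    sum(states[idx] == 1L, na.rm = TRUE)
  }
  d <- sleep_in(idx_day)
  n <- sleep_in(idx_night)
  tot <- d + n
  c("38" = tot, "40" = d, "42" = n,
    "44" = if (!is.na(tot) && tot > 0) n / tot else NA_real_)
}

#' Sleep Regularity Index
#'
#' Probability of being in the same state (sleep or wake) at the same clock
#' minute on consecutive days: for each day pair, the agreement indicator is
#' averaged over the window's clock minutes (ignoring minutes missing on
#' either day), then averaged across day pairs.
#'
#' @param states full-recording state vector covering `n_days * 1440`
#'   minutes (padded with NA as needed).
#' @param window `"whole"` (all 1440 min), `"day"` (7 am-7 pm) or
#'   `"night"` (7 pm-7 am).
#' @param days optional integer vector of calendar days to use (consecutive
#'   pairs are formed among them only when adjacent); default all full days.
#' @return ratio in `[0, 1]`, or `NA` with fewer than 2 usable days.
#' @export
sleep_regularity_index <- function(states, window = c("whole", "day", "night"),
                                   days = NULL) {
  window <- match.arg(window)
  n_days <- length(states) %/% 1440L
  if (n_days < 2L) return(NA_real_)
  m <- matrix(states[seq_len(n_days * 1440L)], nrow = 1440L)
  if (is.null(days)) days <- seq_len(n_days)
  rows <- switch(window,
                 whole = seq_len(1440L),
                 day = (420L + 1L):1140L,
                 night = c((1140L + 1L):1440L, seq_len(420L)))
  pair_vals <- c()
  for (d in days[-length(days)]) {
    if (!((d + 1L) %in% days)) next
    a <- m[rows, d]
    b <- m[rows, d + 1L]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) pair_vals <- c(pair_vals, mean(a[ok] == b[ok]))
  }
  if (length(pair_vals) == 0L) return(NA_real_)
  mean(pair_vals)
}

#' Cross-day variability (sample SD) of base variables
#'
#' @param x daily values of one base variable (NA = invalid day).
#' @param min_days minimum valid days required (default 5).
#' @return sample SD (n-1 denominator), or NA below `min_days`.
#' @export
variability_across_days <- function(x, min_days = 5L) {
  x <- x[!is.na(x)]
  if (length(x) < min_days) return(NA_real_)
  stats::sd(x)
}
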