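#' Extended-clock conventions
#'
#' Nightly events (bedtime, sleep onset, midsleep, ...) are reported on a
#' 24-h clock but must be monotone within a night: an 00:30 bedtime follows a
#' 23:30 bedtime. Evening events falling after midnight are therefore mapped
#' onto an "extended clock" by adding 1440 min. The evening/morning cutoff is
#' 04:00 (240 min): no infant bedtime or sleep onset in this cohort design
#' plausibly falls between 04:00 and noon, so any clock time before 04:00
#' occurring as an evening event is treated as "past midnight".
#'
#' @param clock_min integer vector, minutes since midnight in `[0, 1440)`.
#' @param cutoff evening/morning cutoff in minutes since midnight; clock
#'   times strictly below it get `+1440`. Default 240 (= 04:00).
#' @return numeric vector of extended minutes.
#' @examples
#' clock_to_extended(c(1274, 79, 0))  # 21:14, 01:19, 00:00
#' @export
clock_to_extended <- function(clock_min, cutoff = 240) {
  stopifnot(all(is.na(clock_min) | (clock_min >= 0 & clock_min < 1440)))
  ifelse(clock_min < cutoff, clock_min + 1440, clock_min)
}

#' Reduce an extended-clock value back to `[0, 1440)`
#' @param ext_min numeric vector of extended minutes.
#' @return minutes since midnight.
#' @export
extended_to_clock <- function(ext_min) {
  ext_min %% 1440
}

#' Format minutes-since-midnight as HH:MM
#' @param min_of_day numeric vector (extended values are reduced modulo 1440).
#' @return character vector.
#' @export
minutes_to_hhmm <- function(min_of_day) {
  m <- round(min_of_day) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

#' Parse HH:MM to minutes since midnight
#' @param x character vector like "21:14".
#' @return integer minutes in `[0, 1440)`.
#' @export
hhmm_to_minutes <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) < 2L || anyNA(suppressWarnings(as.integer(p[1:2])))) return(NA_integer_)
    as.integer(p[1]) * 60L + as.integer(p[2])
  }, integer(1))
}
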