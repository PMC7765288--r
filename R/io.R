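# Delimited-text interfaces. All tables are plain CSV; writers and readers
# round-trip exactly.
#
# Dialects:
#  * epoch file: `timestamp` (ISO-8601, minute resolution) plus either an
#    `activity` column (pre-computed counts) or `x`,`y`,`z` acceleration;
#  * diary intervals: `day` (1-based recording day), `interval_start`
#    (HH:MM, 15-min grid), `state` (S/W), `external_movement` (0/1);
#  * diary nights: `night_id`, `bedtime` / `getup` (HH:MM, empty when
#    unreported);
#  * metadata / ASQ: free-form rectangular tables keyed by participant and
#    timepoint.

iso_from_minute <- function(minute_abs, origin = "2020-01-01") {
  t0 <- as.POSIXct(paste(origin, "00:00:00"), tz = "UTC")
  format(t0 + minute_abs * 60, "%Y-%m-%dT%H:%M:%S")
}

minute_from_iso <- function(ts, origin = "2020-01-01") {
  t0 <- as.POSIXct(paste(origin, "00:00:00"), tz = "UTC")
  as.integer(round(as.numeric(difftime(
    as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"), t0,
    units = "mins"))))
}

#' Write / read a per-minute epoch file
#'
#' @param activity per-minute counts (NA allowed); minute m (0-based) is
#'   stamped `origin + m` minutes.
#' @param path output file.
#' @param origin calendar date of recording day 1.
#' @return (read) list with `activity` and `minute_abs`.
#' @export
write_epochs <- function(activity, path, origin = "2020-01-01") {
  df <- data.frame(timestamp = iso_from_minute(seq_along(activity) - 1L, origin),
                   activity = activity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path, origin = "2020-01-01") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("timestamp" %in% names(df))
  act <- if ("activity" %in% names(df)) df$activity else NULL
  list(minute_abs = minute_from_iso(df$timestamp, origin),
       activity = as.numeric(act),
       xyz = if (all(c("x", "y", "z") %in% names(df)))
         as.matrix(df[, c("x", "y", "z")]) else NULL)
}

#' Write / read the 15-min diary interval table
#'
#' @param diary_state per-minute diary state (1/0/NA).
#' @param external_movement optional per-minute logical.
#' @param path output file.
#' @return (read) list with per-minute `diary_state` and
#'   `external_movement` broadcast back to the minute grid.
#' @export
write_diary <- function(diary_state, path, external_movement = NULL) {
  n <- length(diary_state)
  nb <- n %/% 15L
  if (is.null(external_movement)) external_movement <- rep(FALSE, n)
  blk <- diary_state[seq(1L, by = 15L, length.out = nb)]
  ext <- external_movement[seq(1L, by = 15L, length.out = nb)]
  start_min <- (seq_len(nb) - 1L) * 15L
  df <- data.frame(day = start_min %/% 1440L + 1L,
                   interval_start = minutes_to_hhmm(start_min %% 1440L),
                   state = ifelse(is.na(blk), "", ifelse(blk == 1L, "S", "W")),
                   external_movement = as.integer(ext))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_diary
#' @export
read_diary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(state = "character"))
  start_min <- (df$day - 1L) * 1440L + hhmm_to_minutes(df$interval_start)
  n <- max(start_min) + 15L
  ds <- rep(NA_integer_, n)
  ext <- rep(FALSE, n)
  for (i in seq_len(nrow(df))) {
    idx <- (start_min[i] + 1L):(start_min[i] + 15L)
    ds[idx] <- if (identical(df$state[i], "S")) 1L
      else if (identical(df$state[i], "W")) 0L else NA_integer_
    ext[idx] <- df$external_movement[i] == 1L
  }
  list(diary_state = ds, external_movement = ext)
}

#' Write / read reported nightly bedtimes and get-up times
#'
#' @param anchors anchors data.frame (see [realize_days()]); unreported
#'   times are written empty.
#' @param path output file.
#' @return (read) data.frame `night_id`, `bedtime_ext` (extended minutes,
#'   NA when unreported), `getup_min`, `bedtime_abs`, `getup_abs`.
#' @export
write_nights <- function(anchors, path) {
  df <- data.frame(
    night_id = anchors$night_id,
    bedtime = ifelse(anchors$bedtime_reported,
                     minutes_to_hhmm(anchors$bedtime_ext), ""),
    getup = ifelse(anchors$getup_reported,
                   minutes_to_hhmm(anchors$getup_min), ""))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nights
#' @export
read_nights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(bedtime = "character",
                                       getup = "character"))
  bt_clock <- hhmm_to_minutes(df$bedtime)
  gu_clock <- hhmm_to_minutes(df$getup)
  bt_ext <- clock_to_extended(bt_clock)
  d0 <- (df$night_id - 1L) * 1440L
  data.frame(night_id = df$night_id,
             bedtime_ext = bt_ext,
             getup_min = gu_clock,
             bedtime_abs = d0 + bt_ext,
             getup_abs = df$night_id * 1440L + gu_clock,
             bedtime_reported = !is.na(bt_ext),
             getup_reported = !is.na(gu_clock))
}

#' Build night anchors from reported nights with diary fallback
#'
#' Unreported bedtimes fall back to the first minute of diary-reported sleep
#' of that night (and get-up times to the last), flagged via
#' `bedtime_reported` / `getup_reported`.
#'
#' @param nights data.frame from [read_nights()].
#' @param diary_state per-minute diary state vector.
#' @return anchors data.frame as consumed by [daily_variables()].
#' @export
anchors_from_nights <- function(nights, diary_state) {
  out <- nights
  sleep_min <- which(!is.na(diary_state) & diary_state == 1L) - 1L
  for (i in seq_len(nrow(out))) {
    d0 <- (out$night_id[i] - 1L) * 1440L
    lo <- d0 + 1080L            # 18:00 on night i's evening
    hi <- out$night_id[i] * 1440L + 720L
    cand <- sleep_min[sleep_min >= lo & sleep_min <= hi]
    if (is.na(out$bedtime_abs[i])) {
      if (length(cand) == 0L) next
      out$bedtime_abs[i] <- cand[1]
      out$bedtime_ext[i] <- cand[1] - d0
      out$bedtime_reported[i] <- FALSE
    }
    if (is.na(out$getup_abs[i])) {
      if (length(cand) == 0L) next
      out$getup_abs[i] <- cand[length(cand)]
      out$getup_min[i] <- cand[length(cand)] %% 1440L
      out$getup_reported[i] <- FALSE
    }
  }
  out[!is.na(out$bedtime_abs) & !is.na(out$getup_abs), , drop = FALSE]
}

#' Write / read a rectangular metadata or questionnaire table
#' @param df data.frame.
#' @param path file path.
#' @return (read) the data.frame.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export one synthetic assessment to its file dialects
#'
#' Writes `epochs.csv`, `diary.csv`, `nights.csv` (and `truth.csv` with the
#' latent factors) for a [realize_days()] record, in exactly the dialects
#' the readers accept.
#'
#' @param rec record from [realize_days()] (optionally after
#'   [inject_missingness()]).
#' @param dir output directory (created).
#' @return invisibly, the file paths.
#' @export
export_assessment <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(epochs = file.path(dir, "epochs.csv"),
             diary = file.path(dir, "diary.csv"),
             nights = file.path(dir, "nights.csv"),
             truth = file.path(dir, "truth.csv"))
  write_epochs(rec$activity, paths["epochs"])
  write_diary(rec$diary_state, paths["diary"])
  write_nights(rec$anchors, paths["nights"])
  write_table(data.frame(factor = names(rec$truth$factors),
                         value = as.numeric(rec$truth$factors)),
              paths["truth"])
  invisible(paths)
}
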