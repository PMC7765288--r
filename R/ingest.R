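# Raw tri-axial acceleration -> per-minute activity counts -> minute records.
#
# Count pipeline: per-axis 3-11 Hz band-pass (4th-order Butterworth applied
# forward-backward), rectification, compression to 15-s bins (sum of
# absolute filtered values per axis by default), axis fusion by sum of
# squares per bin, and summation of the four bins into one count per minute.

#' Convert tri-axial acceleration to per-minute activity counts
#'
#' @param ax,ay,az acceleration per axis in g at the device sampling rate.
#'   `NA` samples mark recording gaps; every minute touching a gap is
#'   returned as `NA` (missing), never as zero.
#' @param rate sampling rate in Hz; must exceed twice the upper band edge.
#' @param low,high band-pass edges in Hz (defaults 3 and 11).
#' @param bin_seconds compression bin width in seconds (default 15).
#' @param bin_stat per-axis statistic over each bin of absolute filtered
#'   values: `"sum"` (default), `"mean"` or `"max"`.
#' @param order Butterworth prototype order (default 4).
#' @return numeric vector of per-minute counts (length `floor(n/(60*rate))`),
#'   `NA` for minutes with incomplete data.
#' @export
accel_to_counts <- function(ax, ay, az, rate = 30,
                            low = 3, high = 11,
                            bin_seconds = 15, bin_stat = c("sum", "mean", "max"),
                            order = 4L) {
  bin_stat <- match.arg(bin_stat)
  stopifnot(length(ax) == length(ay), length(ay) == length(az),
            rate > 2 * high, 60 %% bin_seconds == 0)
  spb <- as.integer(round(rate * bin_seconds))  # samples per bin
  bins_per_min <- 60L %/% as.integer(bin_seconds)
  n_min <- length(ax) %/% (spb * bins_per_min)
  if (n_min == 0L) return(numeric(0))
  n_use <- n_min * spb * bins_per_min
  coef <- butter_bandpass(low, high, rate, order)

  filt_axis <- function(x) {
    x <- x[seq_len(n_use)]
    out <- rep(NA_real_, n_use)
    ok <- !is.na(x)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    pad <- 3L * (length(coef$a) - 1L)
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      seg <- starts[i]:ends[i]
      if (length(seg) > pad) {
        out[seg] <- abs(filtfilt_zero_phase(coef$b, coef$a, x[seg]))
      }  # too-short segments stay NA (unfilterable)
    }
    out
  }

  bin_reduce <- function(v) {
    m <- matrix(v, nrow = spb)
    switch(bin_stat,
           sum  = colSums(m),
           mean = colMeans(m),
           max  = suppressWarnings(apply(m, 2, max)))
  }

  sx <- bin_reduce(filt_axis(ax))
  sy <- bin_reduce(filt_axis(ay))
  sz <- bin_reduce(filt_axis(az))
  bins <- sx^2 + sy^2 + sz^2        # axis fusion per 15-s bin
  counts <- colSums(matrix(bins, nrow = bins_per_min))
  as.numeric(counts)
}

#' Detect non-wear minutes
#'
#' A minute is non-wear when the diary reports device removal, or when it
#' lies in a zero-activity run at least `zero_run_min` minutes long (the
#' automated stand-in for visual inspection of abrupt no-activity periods).
#'
#' @param counts per-minute activity counts (`NA` = missing).
#' @param removal logical per-minute vector of diary-reported removals
#'   (recycled `FALSE` when `NULL`).
#' @param zero_run_min minimum zero-run length flagged as non-wear
#'   (default 60).
#' @return logical vector, `TRUE` = worn.
#' @export
detect_nonwear <- function(counts, removal = NULL, zero_run_min = 60) {
  n <- length(counts)
  if (is.null(removal)) removal <- rep(FALSE, n)
  stopifnot(length(removal) == n)
  wear <- rep(TRUE, n)
  wear[removal] <- FALSE
  zero <- !is.na(counts) & counts == 0
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long0 <- which(r$values & r$lengths >= zero_run_min)
  for (i in long0) wear[starts[i]:ends[i]] <- FALSE
  wear[is.na(counts)] <- FALSE
  wear
}

#' Fuse activity counts with diary information into minute records
#'
#' Worn, sensor-informed minutes keep their counts and an undetermined state
#' (to be filled by the sleep scorer); non-wear minutes take the diary state
#' when one exists; minutes informed by neither source are MISSING.
#'
#' @param counts per-minute counts.
#' @param wear logical per-minute wear flags.
#' @param diary_state per-minute diary state: 1 sleep, 0 wake, `NA` unknown
#'   (each 15-min diary interval broadcast to its minutes upstream).
#' @param external_movement optional logical per-minute flag.
#' @return data.frame with columns `minute_index`, `activity`, `wear`,
#'   `diary_state`, `state` (NA where the scorer must decide or no source
#'   informs the minute), `missing` (TRUE when neither source informs).
#' @export
fuse_diary <- function(counts, wear, diary_state,
                       external_movement = NULL) {
  n <- length(counts)
  stopifnot(length(wear) == n, length(diary_state) == n)
  if (is.null(external_movement)) external_movement <- rep(FALSE, n)
  state <- rep(NA_integer_, n)
  use_diary <- !wear & !is.na(diary_state)
  state[use_diary] <- as.integer(diary_state[use_diary])
  data.frame(
    minute_index = seq_len(n) - 1L,
    activity = ifelse(wear, counts, NA_real_),
    wear = wear,
    diary_state = as.integer(diary_state),
    state = state,
    missing = !wear & is.na(diary_state),
    external_movement = external_movement
  )
}
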