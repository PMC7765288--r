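# Run-length utilities over minute-state vectors.
# State encoding used throughout: 1 = SLEEP, 0 = WAKE, NA = MISSING.

#' Maximal runs of a state vector
#'
#' @param states integer vector (1 = SLEEP, 0 = WAKE, NA = MISSING). Missing
#'   minutes break runs and form their own runs with value `NA`.
#' @return data.frame with columns `value`, `start`, `end`, `length`
#'   (1-based positions, inclusive).
#' @export
state_runs <- function(states) {
  if (length(states) == 0L) {
    return(structure(list(value = integer(), start = integer(),
                          end = integer(), length = integer()),
                     class = "data.frame", row.names = integer()))
  }
  enc <- as.integer(states)
  enc[is.na(enc)] <- -1L
  r <- rle(enc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  val <- r$values
  val[val == -1L] <- NA_integer_
  structure(list(value = val, start = starts, end = ends,
                 length = r$lengths),
            class = "data.frame", row.names = seq_along(val))
}

#' Length of the longest run of a given state
#' @param states state vector.
#' @param value state to look for (1 sleep, 0 wake).
#' @return integer (0 when the state never occurs).
#' @export
longest_run <- function(states, value) {
  r <- state_runs(states)
  r <- r[!is.na(r$value) & r$value == value, , drop = FALSE]
  if (nrow(r) == 0L) 0L else max(r$length)
}
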