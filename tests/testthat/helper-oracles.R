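# Brute-force oracles: naive loop/enumeration implementations of the sleep
# variable definitions, independent of the package's vectorised calculators.

oracle_runs <- function(states) {
  runs <- list()
  i <- 1L
  n <- length(states)
  while (i <= n) {
    j <- i
    same <- function(a, b) (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
    while (j < n && same(states[j + 1L], states[i])) j <- j + 1L
    runs[[length(runs) + 1L]] <- list(value = states[i], start = i, end = j,
                                      length = j - i + 1L)
    i <- j + 1L
  }
  runs
}

oracle_longest <- function(states, value) {
  best <- 0L
  for (r in oracle_runs(states)) {
    if (!is.na(r$value) && r$value == value && r$length > best) best <- r$length
  }
  best
}

# first minute (1-based) of the first sleep run >= min_run starting at or
# after bed_i; if asleep at bed_i, the start of the containing run
oracle_onset <- function(states, bed_i, getup_i, min_run = 10L) {
  if (!is.na(states[bed_i]) && states[bed_i] == 1L) {
    k <- bed_i
    while (k > 1L && !is.na(states[k - 1L]) && states[k - 1L] == 1L) k <- k - 1L
    return(k)
  }
  for (s in bed_i:getup_i) {
    if (is.na(states[s]) || states[s] != 1L) next
    if (s > 1L && !is.na(states[s - 1L]) && states[s - 1L] == 1L) next
    len <- 0L
    k <- s
    while (k <= length(states) && !is.na(states[k]) && states[k] == 1L) {
      len <- len + 1L; k <- k + 1L
    }
    if (len >= min_run) return(s)
  }
  NA_integer_
}

oracle_offset <- function(states, bed_i, getup_i, min_run = 10L) {
  if (!is.na(states[getup_i]) && states[getup_i] == 1L) {
    k <- getup_i
    while (k < length(states) && !is.na(states[k + 1L]) && states[k + 1L] == 1L) k <- k + 1L
    return(k)
  }
  for (e in getup_i:bed_i) {
    if (is.na(states[e]) || states[e] != 1L) next
    if (e < length(states) && !is.na(states[e + 1L]) && states[e + 1L] == 1L) next
    len <- 0L
    k <- e
    while (k >= 1L && !is.na(states[k]) && states[k] == 1L) {
      len <- len + 1L; k <- k - 1L
    }
    if (len >= min_run) return(e)
  }
  NA_integer_
}

# longest wake run in win followed immediately by >= follow sleep minutes
oracle_lnw <- function(win, follow = 15L) {
  best <- 0
  runs <- oracle_runs(win)
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    if (is.na(r$value) || r$value != 0L) next
    if (i == length(runs)) next
    nxt <- runs[[i + 1L]]
    if (!is.na(nxt$value) && nxt$value == 1L && nxt$length >= follow &&
        r$length > best) best <- r$length
  }
  best
}

oracle_nap_count <- function(win, nap_min = 20L) {
  cnt <- 0L
  for (r in oracle_runs(win)) {
    if (!is.na(r$value) && r$value == 1L && r$length > nap_min) cnt <- cnt + 1L
  }
  cnt
}

oracle_sri <- function(states, rows = 1:1440) {
  n_days <- length(states) %/% 1440L
  m <- matrix(states[1:(n_days * 1440L)], nrow = 1440L)
  vals <- c()
  for (d in seq_len(n_days - 1L)) {
    agree <- tot <- 0L
    for (r in rows) {
      a <- m[r, d]; b <- m[r, d + 1L]
      if (!is.na(a) && !is.na(b)) {
        tot <- tot + 1L
        if (a == b) agree <- agree + 1L
      }
    }
    if (tot > 0L) vals <- c(vals, agree / tot)
  }
  if (length(vals)) mean(vals) else NA_real_
}

# random toy state series: alternating sleep/wake bouts with optional
# missing patches, length n minutes
make_toy_states <- function(n, p_missing = 0.02) {
  states <- integer(0)
  cur <- sample(0:1, 1)
  while (length(states) < n) {
    len <- sample(1:120, 1)
    states <- c(states, rep(cur, len))
    cur <- 1L - cur
  }
  states <- states[1:n]
  miss <- runif(n) < p_missing
  states[miss] <- NA_integer_
  states
}
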