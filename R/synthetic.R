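# Synthetic longitudinal infant-sleep cohort.
#
# The generative model works at the bout level: per night it draws bedtime /
# get-up anchors, sleep onset latency, nocturnal wake bouts and daytime naps
# from distributions whose per-timepoint locations track the published
# 3/6/12-month descriptive statistics, and whose per-participant deviations
# are driven by five correlated latent factors (Sleep Activity, Sleep
# Variability, Sleep Day, Sleep Timing, Sleep Night). Day-to-day jitter is
# scaled by the Variability factor; run-length statistics (WASO, bout
# counts, nap counts) are controlled directly, because those are exactly
# what the sleep variables measure.

#' Default synthetic cohort configuration
#'
#' All numerical defaults are the stated world of the generator: cohort
#' size, timepoint age windows, recording-length distribution, per-timepoint
#' variable targets, the five-factor correlation structure, age slopes and
#' the female contrast on Sleep Activity / Sleep Variability, the ASQ effect
#' of Sleep Day on the Collective score, and the missingness rates.
#'
#' @param n_participants cohort size (default 150).
#' @param seed master seed (default 42). All draws of one cohort flow from
#'   it through per-participant substreams (sequential allocation).
#' @param factor_cor 5x5 latent correlation matrix, order Activity,
#'   Variability, Day, Timing, Night.
#' @param age_slopes per-month factor drift within a timepoint window.
#' @param sex_effects female-minus-male factor shift.
#' @param between_share share of factor variance at the participant level
#'   (drives cross-timepoint stability).
#' @param asq_b_day effect of the Day factor on the ASQ Collective score.
#' @param missing missingness rates (see the returned list).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 150L, seed = 42L,
                          factor_cor = default_factor_cor(),
                          age_slopes = c(activity = -0.15, variability = -0.08,
                                         day = -0.21, timing = -0.07,
                                         night = 0.03),
                          sex_effects = c(activity = -0.29, variability = -0.17,
                                          day = 0, timing = 0, night = 0),
                          between_share = c(activity = 0.25, variability = 0.33,
                                            day = 0.27, timing = 0.62,
                                            night = 0.50),
                          asq_b_day = -6.65,
                          missing = list(sick_day = 0.03,
                                         removal_per_day = 0.3,
                                         removal_meanlog = log(45),
                                         removal_sdlog = 0.7,
                                         diary_block_noise = 0.05,
                                         diary_block_absent = 0.02,
                                         bedtime_unreported = 0.03,
                                         dropout = c(0.013, 0.026, 0.059),
                                         asq_missing = 0.05)) {
  stopifnot(all(eigen(factor_cor, symmetric = TRUE,
                      only.values = TRUE)$values > 0))
  list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    timepoints = c("3m", "6m", "12m"),
    age_windows = rbind(`3m` = c(2.43, 3.39), `6m` = c(5.42, 6.28),
                        `12m` = c(11.47, 12.26)),
    n_days_mean = c(11.13, 10.60, 10.55),
    n_days_sd = c(1.17, 1.91, 1.93),
    factor_cor = factor_cor,
    age_slopes = age_slopes,
    sex_effects = sex_effects,
    between_share = between_share,
    targets = default_targets(),
    variability_sigma = 0.45,   # lognormal spread of the day-to-day jitter scale
    asq = list(collective = c(intercept = 203.16, b_day = asq_b_day,
                              b_age = 0.21, b_female = 9.49,
                              sd_participant = 35, sd_resid = 50),
               personal_social = c(intercept = 42.17, b_day = 0, b_age = -0.37,
                                   b_female = 1.76, sd_participant = 8,
                                   sd_resid = 12),
               gross_motor = c(intercept = 38.82, b_day = 0, b_age = 0.14,
                               b_female = 0.90, sd_participant = 9,
                               sd_resid = 13)),
    missing = missing
  )
}

#' Default latent factor correlation matrix
#'
#' Order: Activity, Variability, Day, Timing, Night. The four published
#' pairwise values (Activity-Day 0.50, Variability-Timing 0.48, Day-Night
#' -0.26, Timing-Night -0.25) anchor the matrix; the remaining pairs are
#' set to modest values of plausible sign (all composites correlate).
#'
#' @return 5x5 positive-definite correlation matrix.
#' @export
default_factor_cor <- function() {
  nm <- c("activity", "variability", "day", "timing", "night")
  M <- diag(5)
  dimnames(M) <- list(nm, nm)
  set_pair <- function(a, b, v) {
    M[a, b] <<- v; M[b, a] <<- v
  }
  set_pair("activity", "variability", 0.25)
  set_pair("activity", "day", 0.50)
  set_pair("activity", "timing", 0.15)
  set_pair("activity", "night", 0.18)
  set_pair("variability", "day", 0.20)
  set_pair("variability", "timing", 0.48)
  set_pair("variability", "night", -0.18)
  set_pair("day", "timing", 0.15)
  set_pair("day", "night", -0.26)
  set_pair("timing", "night", -0.25)
  M
}

# Per-timepoint generative targets (columns = 3m, 6m, 12m), anchored to the
# published descriptive table: anchor means, between-subject SDs, mean
# within-subject SDs, night fragmentation, naps and activity levels.
default_targets <- function() {
  list(
    bedtime_mean = c(1273.71, 1226.59, 1220.78),
    bedtime_sd_between = c(75, 69, 53),
    bedtime_sd_within = c(39.3, 29.4, 26.1),
    getup_mean = c(472.88, 443.84, 437.93),
    getup_sd_between = c(52, 49, 43),
    getup_sd_within = c(38.0, 32.8, 32.3),
    latency_mean = c(7.79, 11.29, 10.94),
    latency_sd_within = c(10.3, 11.4, 10.3),
    offset_gap_mean = c(1.5, 1.5, 1.5),
    wake_freq = c(0.34, 0.23, 0.14),        # bouts per hour of sleep period
    wake_bout_mean = c(19.4, 18.1, 14.8),   # minutes
    wake_bout_sdlog = 0.65,
    nap_count = c(4.06, 3.20, 2.07),
    nap_count_sd_between = c(0.65, 0.50, 0.47),
    nap_count_resid_between = c(0.40, 0.31, 0.29),
    nap_count_sd_within = c(1.00, 0.78, 0.68),
    nap_excess_mean = c(40, 35, 48),        # nap duration = 21 + lognormal
    nap_excess_sdlog = 0.55,
    p_active_sleep = c(0.215, 0.18, 0.20),  # non-zero-count prob per sleep min
    activity_scale_sleep = c(110, 130, 75),
    activity_sdlog_sleep = 1.0,
    activity_scale_wake = 250,
    activity_sdlog_wake = 0.7
  )
}

rmvn <- function(n, Sigma) {
  L <- chol(Sigma)
  matrix(stats::rnorm(n * ncol(Sigma)), n) %*% L
}

#' Draw participants, ages and latent factors
#'
#' Sex is Bernoulli(0.5); exact ages are uniform in the per-timepoint
#' windows; each participant x timepoint gets five correlated latent
#' factors composed of a participant-level component (share
#' `between_share`) and a timepoint-level component, both with the
#' configured correlation matrix, plus within-window age drift and the sex
#' shift.
#'
#' @param cfg a [cohort_config()].
#' @return data.frame, one row per participant x timepoint: participant_id,
#'   timepoint, tp_index, exact_age, sex, and factor columns `f_activity`,
#'   `f_variability`, `f_day`, `f_timing`, `f_night`.
#' @export
draw_cohort <- function(cfg = cohort_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_participants
  nm <- colnames(cfg$factor_cor)
  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "female", "male")
  B <- rmvn(n, cfg$factor_cor)
  rows <- list()
  for (t in seq_along(cfg$timepoints)) {
    w <- cfg$age_windows[t, ]
    age <- stats::runif(n, w[1], w[2])
    E <- rmvn(n, cfg$factor_cor)
    phi <- cfg$between_share[nm]
    Fm <- sweep(B, 2, sqrt(phi), `*`) + sweep(E, 2, sqrt(1 - phi), `*`)
    drift <- outer(age - mean(w), cfg$age_slopes[nm]) +
      outer(as.numeric(sex == "female") - 0.5, cfg$sex_effects[nm])
    Fm <- Fm + drift
    colnames(Fm) <- paste0("f_", nm)
    rows[[t]] <- data.frame(participant_id = seq_len(n),
                            timepoint = cfg$timepoints[t], tp_index = t,
                            exact_age = age, sex = sex, Fm,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Realize one assessment: anchors, minute states, activity, diary
#'
#' @param factors named numeric vector (`activity`, `variability`, `day`,
#'   `timing`, `night`) for this participant x timepoint.
#' @param tp timepoint index (1, 2, 3).
#' @param cfg a [cohort_config()].
#' @param n_nights optional fixed number of nights (default drawn from the
#'   configured recording-length distribution).
#' @param jitter_scale optional override of the day-to-day jitter
#'   multiplier (normally `exp(sigma_V * variability)` normalised to mean
#'   1); `0` yields identical anchors every day.
#' @return list with `states`, `activity`, `diary_state`, `wear` (minute
#'   vectors over `(n_nights + 1) * 1440` absolute minutes; unrecorded heads
#'   and tails are NA), `anchors` (data.frame), `n_nights`, and `truth`
#'   (true onsets/offsets and the latent factors).
#' @export
realize_days <- function(factors, tp, cfg = cohort_config(),
                         n_nights = NULL, jitter_scale = NULL) {
  tg <- cfg$targets
  fA <- factors[["activity"]]; fV <- factors[["variability"]]
  fD <- factors[["day"]]; fT <- factors[["timing"]]; fN <- factors[["night"]]
  sV <- cfg$variability_sigma
  if (is.null(jitter_scale)) jitter_scale <- exp(sV * fV - sV^2 / 2)

  if (is.null(n_nights)) {
    n_nights <- round(stats::rnorm(1, cfg$n_days_mean[tp], cfg$n_days_sd[tp]))
    n_nights <- max(6L, min(14L, n_nights))
  }
  K <- as.integer(n_nights)
  n_min <- (K + 1L) * 1440L

  # participant-level centres
  bt_c <- tg$bedtime_mean[tp] + 0.80 * tg$bedtime_sd_between[tp] * fT -
    0.57 * tg$bedtime_sd_between[tp] * fN
  gu_c <- tg$getup_mean[tp] + 0.93 * tg$getup_sd_between[tp] * fT +
    0.36 * tg$getup_sd_between[tp] * fN
  lat_c <- max(0, tg$latency_mean[tp] + 1.5 * fA)
  freq_c <- tg$wake_freq[tp] * exp(0.35 * fA - 0.35^2 / 2)
  bout_c <- tg$wake_bout_mean[tp] * exp(0.30 * fA - 0.30^2 / 2)
  nap_c <- tg$nap_count[tp] + tg$nap_count_sd_between[tp] * fD +
    tg$nap_count_resid_between[tp] * stats::rnorm(1)
  nap_ex_c <- tg$nap_excess_mean[tp] * exp(0.20 * fD - 0.20^2 / 2)
  p_act <- min(0.9, tg$p_active_sleep[tp] * exp(0.12 * fA))

  # per-night anchors
  bedtime <- round(bt_c + jitter_scale *
                     stats::rnorm(K, 0, tg$bedtime_sd_within[tp]))
  bedtime <- pmax(1085L, pmin(1519L, as.integer(bedtime)))
  getup <- round(gu_c + jitter_scale *
                   stats::rnorm(K, 0, tg$getup_sd_within[tp]))
  getup <- pmax(300L, pmin(660L, as.integer(getup)))
  latency <- pmax(0L, as.integer(round(
    stats::rnorm(K, lat_c, jitter_scale * tg$latency_sd_within[tp]))))
  gap <- pmax(0L, as.integer(round(
    stats::rnorm(K, tg$offset_gap_mean[tp], jitter_scale * 2.5))))

  d0 <- (seq_len(K) - 1L) * 1440L
  bedtime_abs <- d0 + bedtime
  getup_abs <- seq_len(K) * 1440L + getup
  onset_abs <- pmin(bedtime_abs + latency, getup_abs - 60L)
  offset_abs <- pmax(getup_abs - gap, onset_abs + 60L)

  states <- rep(0L, n_min)    # base: wake
  activity <- integer(n_min)

  place_wake_bouts <- function(on, off) {
    per_h <- (off - on + 1) / 60
    nb <- stats::rpois(1, freq_c * per_h)
    if (nb == 0L) return(NULL)
    lens <- pmax(1L, as.integer(round(stats::rlnorm(
      nb, log(bout_c) - tg$wake_bout_sdlog^2 / 2, tg$wake_bout_sdlog))))
    # one bout per equal segment, keeping 16-min sleep margins
    seg <- (off - on - 32) / nb
    if (seg < 2) return(NULL)
    starts <- on + 16 + as.integer((seq_len(nb) - 1) * seg +
                                     stats::runif(nb, 0, pmax(1, seg - lens - 16)))
    ends <- pmin(starts + lens - 1L, off - 16L)
    keep <- ends >= starts
    cbind(starts[keep], ends[keep])
  }

  for (d in seq_len(K)) {
    states[(onset_abs[d] + 1L):(offset_abs[d] + 1L)] <- 1L
    wb <- place_wake_bouts(onset_abs[d], offset_abs[d])
    if (!is.null(wb)) for (r in seq_len(nrow(wb))) {
      states[(wb[r, 1] + 1L):(wb[r, 2] + 1L)] <- 0L
    }
  }

  # daytime naps in each window between sleep offset and next sleep onset
  place_naps <- function(lo, hi, scale = 1) {
    win <- hi - lo
    if (win < 120) return(invisible(NULL))
    cnt <- max(0L, as.integer(round(
      nap_c * scale + stats::rnorm(1, 0, tg$nap_count_sd_within[tp]))))
    if (cnt == 0L) return(invisible(NULL))
    durs <- 21L + pmax(1L, as.integer(round(stats::rlnorm(
      cnt, log(nap_ex_c) - tg$nap_excess_sdlog^2 / 2, tg$nap_excess_sdlog))))
    slot <- (win - 60) / cnt
    if (slot < 40) { cnt <- max(1L, floor((win - 60) / 40)); durs <- durs[seq_len(cnt)]; slot <- (win - 60) / cnt }
    for (i in seq_len(cnt)) {
      s0 <- lo + 30 + (i - 1) * slot
      start <- as.integer(s0 + stats::runif(1, 0, max(1, slot - durs[i] - 10)))
      end <- min(start + durs[i] - 1L, hi - 15L)
      if (end >= start) states[(start + 1L):(end + 1L)] <<- 1L
    }
    invisible(NULL)
  }
  place_naps(720L, onset_abs[1], scale = (onset_abs[1] - 720) / 770)
  for (d in 2:K) place_naps(offset_abs[d - 1L] + 1L, onset_abs[d])

  # activity counts: bursty in sleep, high in wake
  asleep <- states == 1L
  n_s <- sum(asleep); n_w <- sum(!asleep)
  act_s <- ifelse(stats::runif(n_s) < p_act,
                  round(stats::rlnorm(n_s, log(tg$activity_scale_sleep[tp]),
                                      tg$activity_sdlog_sleep)), 0)
  act_w <- ifelse(stats::runif(n_w) < 0.95,
                  round(stats::rlnorm(n_w, log(tg$activity_scale_wake),
                                      tg$activity_sdlog_wake)), 0)
  activity[asleep] <- as.integer(act_s)
  activity[!asleep] <- as.integer(act_w)

  # trim to the recorded span: from noon of day 1 to the last get-up
  rec_start <- 720L
  rec_end <- getup_abs[K]
  idx_out <- c(seq_len(rec_start), (rec_end + 2L):n_min)
  states[idx_out] <- NA_integer_
  activity[idx_out] <- NA_integer_

  # diary: 15-min majority with reporting noise
  nb <- n_min %/% 15L
  block <- matrix(states[seq_len(nb * 15L)], nrow = 15L)
  dmaj <- as.integer(colMeans(block, na.rm = TRUE) >= 0.5)
  dmaj[colSums(!is.na(block)) == 0L] <- NA_integer_
  flip <- stats::runif(nb) < cfg$missing$diary_block_noise
  absent <- stats::runif(nb) < cfg$missing$diary_block_absent
  dmaj[flip & !is.na(dmaj)] <- 1L - dmaj[flip & !is.na(dmaj)]
  dmaj[absent] <- NA_integer_
  diary_state <- rep(dmaj, each = 15L)
  diary_state <- c(diary_state, rep(NA_integer_, n_min - length(diary_state)))

  # reported anchors (small reporting error; occasional fallback to the
  # first/last diary-reported sleep minute)
  rep_bt <- bedtime_abs + as.integer(round(stats::rnorm(K, 0, 4)))
  rep_gu <- getup_abs + as.integer(round(stats::rnorm(K, 0, 4)))
  bt_reported <- stats::runif(K) >= cfg$missing$bedtime_unreported
  gu_reported <- stats::runif(K) >= cfg$missing$bedtime_unreported
  for (d in seq_len(K)) {
    if (!bt_reported[d]) {
      cand <- which(!is.na(diary_state) & diary_state == 1L)
      cand <- cand[cand - 1L >= bedtime_abs[d] - 90L & cand - 1L <= getup_abs[d]]
      rep_bt[d] <- if (length(cand)) cand[1] - 1L else bedtime_abs[d]
    }
    if (!gu_reported[d]) {
      cand <- which(!is.na(diary_state) & diary_state == 1L)
      cand <- cand[cand - 1L <= getup_abs[d] + 90L & cand - 1L >= bedtime_abs[d]]
      rep_gu[d] <- if (length(cand)) cand[length(cand)] - 1L else getup_abs[d]
    }
  }
  rep_bt <- pmax(d0 + 721L, rep_bt)   # keep within the recorded span
  rep_gu <- pmin(rec_end, pmax(rep_bt + 120L, rep_gu))

  anchors <- data.frame(
    night_id = seq_len(K),
    bedtime_abs = rep_bt, getup_abs = rep_gu,
    bedtime_ext = rep_bt - d0,
    getup_min = rep_gu %% 1440L,
    bedtime_reported = bt_reported, getup_reported = gu_reported)

  list(states = states, activity = as.numeric(activity),
       diary_state = diary_state, wear = !is.na(states),
       anchors = anchors, n_nights = K,
       truth = list(factors = factors, onset_abs = onset_abs,
                    offset_abs = offset_abs, bedtime_abs = bedtime_abs,
                    getup_abs = getup_abs))
}

#' Inject missingness: sick days, device removals
#'
#' Removal episodes set wear to FALSE and activity to NA; their states fall
#' back to the diary (or MISSING where the diary is absent). Sick nights are
#' flagged for the screening stage. Ground truth is retained untouched.
#'
#' @param rec a realization from [realize_days()].
#' @param cfg a [cohort_config()].
#' @return the record with `wear`, `activity`, `states` updated and
#'   `sick_nights` attached.
#' @export
inject_missingness <- function(rec, cfg = cohort_config()) {
  K <- rec$n_nights
  ms <- cfg$missing
  sick <- which(stats::runif(K) < ms$sick_day)
  n_min <- length(rec$states)
  wear <- rec$wear
  for (d in seq_len(K)) {
    n_ep <- stats::rpois(1, ms$removal_per_day)
    if (n_ep == 0L) next
    for (e in seq_len(n_ep)) {
      dur <- max(2L, as.integer(round(stats::rlnorm(1, ms$removal_meanlog,
                                                    ms$removal_sdlog))))
      start <- (d - 1L) * 1440L + as.integer(stats::runif(1, 480, 1400))
      idx <- (start + 1L):min(start + dur, n_min)
      wear[idx] <- FALSE
    }
  }
  removed <- rec$wear & !wear
  rec$activity[removed] <- NA_real_
  rec$states[removed] <- rec$diary_state[removed]   # diary fallback / MISSING
  rec$wear <- wear
  rec$sick_nights <- sick
  rec
}

#' Simulate a full cohort and run the measurement pipeline
#'
#' Draws the cohort, realizes and degrades every assessment, runs
#' [process_assessment()] on each, and attaches ASQ scores. Assessment-level
#' dropout follows the configured per-timepoint rates.
#'
#' @param cfg a [cohort_config()].
#' @param process run the measurement pipeline (default TRUE). With FALSE
#'   only metadata, factors and ASQ are generated (fast path for analyses
#'   that operate on the latent truth).
#' @return list with `cohort` (metadata + factors + ASQ columns), `matrix`
#'   (assessments x 48 variable matrix, rownames participant_timepoint;
#'   dropped or excluded assessments are all-NA rows), `n_valid_days`,
#'   `dropped` (logical).
#' @export
simulate_cohort <- function(cfg = cohort_config(), process = TRUE) {
  cohort <- draw_cohort(cfg)
  n_row <- nrow(cohort)
  dropped <- stats::runif(n_row) < cfg$missing$dropout[cohort$tp_index]
  mat <- matrix(NA_real_, n_row, 48,
                dimnames = list(paste0(cohort$participant_id, "_",
                                       cohort$timepoint),
                                as.character(1:48)))
  n_valid <- rep(NA_integer_, n_row)
  if (process) {
    for (i in seq_len(n_row)) {
      if (dropped[i]) next
      f <- as.numeric(cohort[i, paste0("f_", colnames(cfg$factor_cor))])
      names(f) <- colnames(cfg$factor_cor)
      rec <- realize_days(f, cohort$tp_index[i], cfg)
      rec <- inject_missingness(rec, cfg)
      pa <- process_assessment(rec$states, rec$activity, rec$wear,
                               rec$diary_state, rec$anchors,
                               sick_nights = rec$sick_nights)
      mat[i, ] <- pa$summary
      n_valid[i] <- pa$n_valid_days
    }
  }
  cohort <- attach_asq(cohort, cfg)
  list(cohort = cohort, matrix = mat, n_valid_days = n_valid,
       dropped = dropped)
}

#' Attach ASQ developmental scores
#'
#' Collective score: configured intercept + Day-factor effect + age and
#' female terms + participant random intercept + residual noise. The
#' Personal-Social and Gross-Motor subscales carry no composite effect (the
#' reference analysis found none).
#'
#' @param cohort data.frame from [draw_cohort()] (uses `f_day`, `exact_age`,
#'   `sex`, `participant_id`).
#' @param cfg a [cohort_config()].
#' @return `cohort` with columns `asq_collective`, `asq_personal_social`,
#'   `asq_gross_motor` added (missing at the configured rate).
#' @export
attach_asq <- function(cohort, cfg = cohort_config()) {
  n_part <- max(cohort$participant_id)
  female <- as.numeric(cohort$sex == "female")
  age_c <- cohort$exact_age - mean(cohort$exact_age)
  gen <- function(par) {
    u <- stats::rnorm(n_part, 0, par[["sd_participant"]])
    val <- par[["intercept"]] + par[["b_day"]] * cohort$f_day +
      par[["b_age"]] * age_c + par[["b_female"]] * female +
      u[cohort$participant_id] +
      stats::rnorm(nrow(cohort), 0, par[["sd_resid"]])
    val[stats::runif(nrow(cohort)) < cfg$missing$asq_missing] <- NA_real_
    val
  }
  cohort$asq_collective <- gen(cfg$asq$collective)
  cohort$asq_personal_social <- gen(cfg$asq$personal_social)
  cohort$asq_gross_motor <- gen(cfg$asq$gross_motor)
  cohort
}
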