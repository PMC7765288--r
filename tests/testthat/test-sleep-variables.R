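# Calculators for the per-day sleep variables, checked against hand-worked
# examples; randomized oracle equivalence lives in test-acceptance.R.

blank_rec <- function(n = 2880L) rep(0L, n)
set_sleep <- function(states, from, to) {
  states[(from + 1L):(to + 1L)] <- 1L
  states
}

test_that("sleep onset follows the 10-min run rule with the walk-back clause", {
  s <- blank_rec()
  s <- set_sleep(s, 1210, 1219)                  # exactly 10 min
  expect_equal(find_onset(s, 1200, 1800), 1210)

  s2 <- set_sleep(blank_rec(), 1195, 1250)       # asleep at bedtime
  expect_equal(find_onset(s2, 1200, 1800), 1195)

  s3 <- blank_rec()
  s3 <- set_sleep(s3, 1210, 1217)                # 8 min: fails the rule
  s3 <- set_sleep(s3, 1230, 1259)                # 30 min: qualifies
  expect_equal(find_onset(s3, 1200, 1800), 1230)

  expect_true(is.na(find_onset(set_sleep(blank_rec(), 1210, 1215), 1200, 1800)))
})

test_that("sleep offset mirrors onset including the asleep-at-getup clause", {
  s <- blank_rec()
  s <- set_sleep(s, 1300, 1445)
  expect_equal(find_offset(s, 1200, 1460), 1445)

  s2 <- set_sleep(blank_rec(), 1400, 1472)       # asleep at getup 1460
  expect_equal(find_offset(s2, 1200, 1460), 1472)

  s3 <- blank_rec()
  s3 <- set_sleep(s3, 1300, 1380)                # earlier long run
  s3 <- set_sleep(s3, 1430, 1438)                # 9-min run near getup
  expect_equal(find_offset(s3, 1200, 1460), 1380)
})

test_that("night variables follow their printed definitions", {
  # sleep 1210..1749, awake at both boundaries, getup at 1799
  s <- set_sleep(blank_rec(), 1210, 1749)
  v <- night_variables(s, activity = rep(0, 2880), night_id = 1,
                       bedtime_abs = 1200, getup_abs = 1799)
  expect_equal(unname(v["13"]), 600)   # opportunity 1200..1799
  expect_equal(unname(v["15"]), 540)   # period 1210..1749
  expect_equal(unname(v["17"]), 540)
  expect_equal(unname(v["19"]), 90)    # 540 / 600 * 100
  expect_equal(unname(v["21"]), 0)
  expect_equal(unname(v["7"]), 10)     # latency
  expect_equal(unname(v["5"]), 1210)
  expect_equal(unname(v["11"]), (1210 + 1749) / 2 - 1440)

  # asleep at bedtime: onset before bedtime, latency clamped to 0
  s2 <- set_sleep(blank_rec(), 1190, 1700)
  v2 <- night_variables(s2, rep(0, 2880), 1, 1200, 1750)
  expect_equal(unname(v2["5"]), 1190)
  expect_equal(unname(v2["7"]), 0)
  # opportunity start moves to onset when asleep at bedtime
  expect_equal(unname(v2["13"]), 1750 - 1190 + 1)
})

test_that("longest nocturnal wake requires 15 min of following sleep", {
  s <- blank_rec()
  s <- set_sleep(s, 1300, 1329)    # 30 sleep
  # wake 1330..1354 (25)
  s <- set_sleep(s, 1355, 1384)    # 30 sleep
  # wake 1385..1424 (40)
  s <- set_sleep(s, 1425, 1434)    # 10 sleep -> offset
  v <- night_variables(s, rep(0, 2880), 1, 1290, 1500)
  expect_equal(unname(v["23"]), 25)        # the 40-min run is not followed by >= 15
  expect_equal(unname(v["21"]), 65)
  expect_equal(unname(v["15"]), 135)
  expect_equal(unname(v["17"]) + unname(v["21"]), unname(v["15"]))
  expect_equal(unname(v["25"]), 2 / (135 / 60))   # both maximal wake runs count
  expect_equal(unname(v["30"]), 30)
  # with the optional follow rule only the qualifying run counts
  v2 <- night_variables(s, rep(0, 2880), 1, 1290, 1500,
                        wake_freq_follow_rule = TRUE)
  expect_equal(unname(v2["25"]), 1 / (135 / 60))
})

test_that("movement-count variables use the sleep-period activity trace", {
  s <- set_sleep(blank_rec(), 1200, 1499)
  act <- rep(0, 2880)
  act[(1201:1500)[1:75]] <- 100   # 75 of 300 period minutes active
  v <- night_variables(s, act, 1, 1200, 1550)
  expect_equal(unname(v["28"]), 0.25)
  expect_equal(unname(v["27"]), stats::sd(act[1201:1500]))
})

test_that("daytime naps count only runs strictly exceeding 20 min", {
  s <- blank_rec()
  s <- set_sleep(s, 600, 624)    # 25
  s <- set_sleep(s, 700, 717)    # 18
  s <- set_sleep(s, 800, 844)    # 45
  v <- day_variables(s, 500, 1300)
  expect_equal(unname(v["34"]), 2)
  expect_equal(unname(v["36"]), 88)
  expect_equal(unname(v["32"]), 455)       # 845..1299 wake gap

  s20 <- set_sleep(blank_rec(), 600, 619)  # exactly 20 min
  expect_equal(unname(day_variables(s20, 500, 1300)["34"]), 0)

  empty <- day_variables(blank_rec(), 500, 1300)
  expect_equal(unname(empty["34"]), 0)
  expect_equal(unname(empty["32"]), 799)   # whole window awake
  expect_true(all(is.na(day_variables(blank_rec(), NA, 1300))))
})

test_that("fixed-clock windows split day and night sleep additively", {
  all_sleep <- rep(1L, 2880)
  v <- clock_window_variables(all_sleep, 1)
  expect_equal(unname(v[c("38", "40", "42", "44")]), c(1440, 720, 720, 0.5))

  s <- set_sleep(blank_rec(), 1200, 1799)   # 20:00 -> 06:00
  v2 <- clock_window_variables(s, 1)
  expect_equal(unname(v2["42"]), 600)
  expect_equal(unname(v2["40"]), 0)
  expect_equal(unname(v2["44"]), 1)
  expect_equal(unname(v2["38"]), unname(v2["40"]) + unname(v2["42"]))
})

test_that("sleep regularity index matches minute-agreement arithmetic", {
  day <- c(rep(1L, 500), rep(0L, 940))
  expect_equal(sleep_regularity_index(rep(day, 2)), 1)
  expect_equal(sleep_regularity_index(c(day, 1L - day)), 0)

  day2 <- day
  flip <- 1:360
  day2[flip] <- 1L - day2[flip]
  expect_equal(sleep_regularity_index(c(day, day2)), 1080 / 1440)
  expect_true(is.na(sleep_regularity_index(day)))  # single day
  # missing minutes drop out of numerator and denominator
  day3 <- day
  day3[1:100] <- NA_integer_
  expect_equal(sleep_regularity_index(c(day, day3)), 1)
})

test_that("cross-day variability is a sample SD gated by the day minimum", {
  expect_equal(variability_across_days(rep(1250, 5)), 0)
  expect_equal(variability_across_days(c(1200, 1210, 1220), min_days = 3), 10)
  expect_true(is.na(variability_across_days(c(1200, 1210, 1220, 1230))))  # 4 < 5
})

test_that("aggregation averages each variable over its own valid days", {
  daily <- data.frame(night_id = 1:6)
  per_day_ids <- c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19, 21, 23, 25, 27, 28,
                   30, 32, 34, 36, 38, 40, 42, 44)
  for (id in per_day_ids) daily[[paste0("v", id)]] <- NA_real_
  daily$v17 <- c(600, 660, 630, 600, 660, 630)
  daily$v1 <- c(1250, 1260, 1270, 1240, 1250, 1260)
  daily$v38 <- c(800, 810, 790, 805, 795, 800)
  daily$partial_day <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  daily$entire_day <- rep(TRUE, 6)
  daily$movement_count <- rep(FALSE, 6)
  daily$clock_time <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  dv <- list(daily = daily)
  states <- rep(c(rep(1L, 480), rep(0L, 960)), 7)
  ag <- aggregate_assessment(dv, states)
  # v17 averages only its 5 valid days
  expect_equal(unname(ag$values["17"]), mean(c(600, 660, 600, 660, 630)))
  # v1 averages its 5 clock-valid days; its variability is the sample SD
  expect_equal(unname(ag$values["1"]), mean(c(1250, 1260, 1270, 1240, 1250)))
  expect_equal(unname(ag$values["2"]), stats::sd(c(1250, 1260, 1270, 1240, 1250)))
  expect_equal(unname(ag$values["39"]), stats::sd(daily$v38))
  # movement-count family has no valid days -> NA
  expect_true(is.na(ag$values["28"]))
  # identical days: regularity indices are exactly 1
  expect_equal(unname(ag$values["46"]), 1)
  expect_equal(ag$n_valid_days, 5)
})

test_that("two-day toy pipelines keep the conservation invariants", {
  set.seed(11)
  for (i in 1:50) {
    s <- make_toy_states(2880, p_missing = 0)
    bed <- sample(1150:1300, 1)
    getup <- sample(1750:1900, 1)
    v <- night_variables(s, rep(1, 2880), 1, bed, getup)
    if (is.na(v["15"])) next
    expect_equal(unname(v["17"] + v["21"]), unname(v["15"]))
    expect_gte(unname(v["19"]), 0)
    expect_lte(unname(v["19"]), 100)
    expect_lte(unname(v["15"]), unname(v["13"]))
    cw <- clock_window_variables(s, 1)
    expect_equal(unname(cw["38"]), unname(cw["40"] + cw["42"]))
    sri <- sleep_regularity_index(s)
    expect_gte(sri, 0)
    expect_lte(sri, 1)
  }
  # appending an identical day never decreases the regularity index
  set.seed(12)
  for (i in 1:10) {
    d1 <- make_toy_states(1440, 0)
    d2 <- make_toy_states(1440, 0)
    base <- sleep_regularity_index(c(d1, d2))
    more <- sleep_regularity_index(c(d1, d2, d2))
    expect_gte(more + 1e-12, base)
  }
})
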