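test_that("cohort draws are seed-deterministic and correlation-calibrated", {
  cfg <- cohort_config(n_participants = 40, seed = 11)
  a <- draw_cohort(cfg)
  b <- draw_cohort(cfg)
  expect_identical(a, b)

  big <- draw_cohort(cohort_config(n_participants = 10000, seed = 2))
  r <- cor(big$f_activity, big$f_day)
  expect_equal(r, 0.50, tolerance = 0.05)
  # independent factors under a diagonal matrix
  cfg0 <- cohort_config(n_participants = 10000, seed = 3,
                        factor_cor = diag(5))
  dimnames(cfg0$factor_cor) <- dimnames(default_factor_cor())
  big0 <- draw_cohort(cfg0)
  expect_lt(abs(cor(big0$f_activity, big0$f_day)), 0.03)
  expect_error(cohort_config(factor_cor = matrix(1, 5, 5)))
})

test_that("ages fall in the assessment windows and sex is balanced", {
  co <- draw_cohort(cohort_config(n_participants = 500, seed = 4))
  for (tp in c("3m", "6m", "12m")) {
    w <- cohort_config()$age_windows[tp, ]
    ages <- co$exact_age[co$timepoint == tp]
    expect_true(all(ages >= w[1] & ages <= w[2]))
  }
  expect_equal(mean(co$sex == "female"), 0.5, tolerance = 0.1)
})

test_that("zero jitter scale yields identical anchors every day", {
  f <- c(activity = 0, variability = 0, day = 0, timing = 0, night = 0)
  cfg <- cohort_config(seed = 5)
  cfg$missing$bedtime_unreported <- 0
  set.seed(5)
  rec <- realize_days(f, 1, cfg, n_nights = 8, jitter_scale = 0)
  bt <- rec$anchors$bedtime_ext
  # reporting noise aside, the underlying bedtime is constant
  expect_lt(diff(range(rec$truth$bedtime_abs - (0:7) * 1440)), 1e-9)
  expect_lt(diff(range(rec$truth$getup_abs - (1:8) * 1440)), 1e-9)
})

test_that("realized cohorts hit the printed per-timepoint targets", {
  sim <- default_sim()
  m <- sim$matrix
  co <- sim$cohort
  ok <- rowSums(!is.na(m)) > 0
  i3 <- ok & co$timepoint == "3m"
  i12 <- ok & co$timepoint == "12m"
  expect_equal(mean(m[i3, "34"], na.rm = TRUE), 4.06, tolerance = 0.3 / 4.06)
  expect_equal(mean(m[i12, "44"], na.rm = TRUE), 0.78, tolerance = 0.03 / 0.78)
  expect_equal(mean(m[i3, "1"], na.rm = TRUE), 1273.71, tolerance = 0.02)
  expect_equal(mean(m[i12, "17"], na.rm = TRUE), 627.3, tolerance = 0.05)
})

test_that("missingness injection responds to its rates", {
  f <- c(activity = 0, variability = 0, day = 0, timing = 0, night = 0)
  cfg <- cohort_config(seed = 6)
  set.seed(6)
  rec <- realize_days(f, 1, cfg, n_nights = 8)
  cfg0 <- cfg
  cfg0$missing$sick_day <- 0
  cfg0$missing$removal_per_day <- 0
  set.seed(1)
  rec0 <- inject_missingness(rec, cfg0)
  expect_identical(rec0$states, rec$states)
  expect_identical(rec0$wear, rec$wear)
  expect_length(rec0$sick_nights, 0)

  cfg1 <- cfg
  cfg1$missing$removal_per_day <- 2
  set.seed(2)
  rec1 <- inject_missingness(rec, cfg1)
  expect_gt(sum(!rec1$wear & rec$wear), 0)
  expect_true(all(is.na(rec1$activity[!rec1$wear])))

  # a 70-min mid-day removal invalidates the partial-day family downstream
  rec2 <- rec
  idx <- (2 * 1440 + 601):(2 * 1440 + 670)   # day 3, 10:00-11:10
  rec2$wear[idx] <- FALSE
  rec2$activity[idx] <- NA
  rec2$states[idx] <- rec2$diary_state[idx]
  dv <- daily_variables(rec2$states, rec2$activity, rec2$wear,
                        rec2$diary_state, rec2$anchors)
  expect_false(dv$daily$partial_day[3])
})

test_that("assessment dropout tracks the configured rate", {
  cfg <- cohort_config(n_participants = 400, seed = 12)
  cfg$missing$dropout <- c(0.1, 0.1, 0.1)
  sim <- simulate_cohort(cfg, process = FALSE)
  expect_equal(mean(sim$dropped), 0.1, tolerance = 0.35)
})

test_that("ASQ generation carries the Sleep Day effect (and none when disabled)", {
  cfg <- cohort_config(n_participants = 300, seed = 13)
  co <- draw_cohort(cfg)
  set.seed(13)
  co <- attach_asq(co, cfg)
  d <- co
  for (nm in composite_names()) {
    d[[nm]] <- d[[paste0("f_", sub("sleep ", "", tolower(nm)))]]
  }
  res <- asq_models(d)
  b <- res[res$term == "Sleep Day", ]
  expect_lt(b$estimate, 0)

  cfg0 <- cohort_config(n_participants = 300, seed = 13, asq_b_day = 0)
  set.seed(13)
  co0 <- attach_asq(draw_cohort(cfg0), cfg0)
  d0 <- co0
  for (nm in composite_names()) {
    d0[[nm]] <- d0[[paste0("f_", sub("sleep ", "", tolower(nm)))]]
  }
  res0 <- asq_models(d0)
  b0 <- res0[res0$term == "Sleep Day", ]
  expect_true(abs(b0$estimate) < 3 * b0$se)
})

test_that("measured variables track the generator truth", {
  f <- c(activity = 0.5, variability = 0.2, day = -0.3, timing = 0.1,
         night = 0.4)
  cfg <- cohort_config(seed = 14)
  set.seed(14)
  rec <- realize_days(f, 2, cfg, n_nights = 10)
  pa <- process_assessment(rec$states, rec$activity, rec$wear,
                           rec$diary_state, rec$anchors)
  # measured onsets within reporting error of the true ones
  err <- abs(pa$onsets - rec$truth$onset_abs)
  expect_lt(stats::median(err, na.rm = TRUE), 16)
  err_off <- abs(pa$offsets - rec$truth$offset_abs)
  expect_lt(stats::median(err_off, na.rm = TRUE), 16)
})
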