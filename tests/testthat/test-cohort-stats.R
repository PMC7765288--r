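make_scores <- function(n = 60, seed = 1, stable = 0.9) {
  set.seed(seed)
  base <- matrix(rnorm(n * 5), n, 5)
  rows <- list()
  for (t in 1:3) {
    sc <- stable * base + sqrt(1 - stable^2) * matrix(rnorm(n * 5), n, 5)
    colnames(sc) <- composite_names()
    rows[[t]] <- data.frame(participant_id = seq_len(n),
                            timepoint = c("3m", "6m", "12m")[t], tp_index = t,
                            exact_age = c(3, 6, 12)[t] + runif(n, -0.3, 0.3),
                            sex = rep(c("female", "male"), length.out = n),
                            sc, check.names = FALSE)
  }
  do.call(rbind, rows)
}

test_that("spearman matches the rank-then-pearson oracle, including ties", {
  set.seed(2)
  for (i in 1:20) {
    x <- sample(1:8, 15, replace = TRUE)   # heavy ties
    y <- sample(1:8, 15, replace = TRUE)
    st <- spearman_test(x, y)
    expect_equal(st$rho, cor(rank(x), rank(y)))
  }
})

test_that("percentile ranks are monotone-invariant and average ties", {
  x <- c(5, 1, 9, 3, 7)
  expect_equal(percentile_rank(x), rank(x) / 6 * 100)
  expect_equal(percentile_rank(exp(x)), percentile_rank(x))
  expect_equal(percentile_rank(c(2, 2)), c(50, 50))
})

test_that("age/sex linear models recover generated slopes and signs", {
  set.seed(7)
  n <- 200
  d <- data.frame(participant_id = 1:n, exact_age = runif(n, 3, 12),
                  sex = rep(c("female", "male"), n / 2))
  for (nm in composite_names()) d[[nm]] <- rnorm(n, sd = 0.3)
  d[["Sleep Day"]] <- d[["Sleep Day"]] - 0.21 * d$exact_age
  d[["Sleep Activity"]] <- d[["Sleep Activity"]] -
    0.29 * (d$sex == "female")
  res <- age_sex_models(d)
  b_day <- res[res$composite == "Sleep Day" & res$term == "age", ]
  expect_lt(abs(b_day$estimate - (-0.21)), 0.05)
  b_sex <- res[res$composite == "Sleep Activity" & res$term == "sexfemale", ]
  expect_lt(abs(b_sex$estimate - (-0.29)), 0.12)
  # null composite: near-zero slope
  b_null <- res[res$composite == "Sleep Night" & res$term == "age", ]
  expect_lt(abs(b_null$estimate), 0.05)
})

test_that("composite correlations detect monotone dependence", {
  set.seed(3)
  a <- rnorm(300)
  sc <- data.frame(A = a, B = exp(a), C = rnorm(300))
  cc <- composite_correlations(sc)
  expect_equal(cc$rho["A", "B"], 1)
  expect_true(cc$significant["A", "B"])
  expect_lt(abs(cc$rho["A", "C"]), 0.15)
  expect_equal(cc$alpha_adjusted, 0.05 / 3)
})

test_that("stability table uses the 0.05/15 Bonferroni threshold", {
  sc <- make_scores(n = 80, stable = 0.95)
  st <- stability_table(sc)
  expect_equal(attr(st, "alpha_adjusted"), 0.05 / 15)
  expect_equal(round(attr(st, "alpha_adjusted"), 4), 0.0033)
  expect_equal(nrow(st), 15)
  expect_true(all(st$rho > 0.6))
  expect_true(all(st$significant))
  # permuted ranks: no stability
  sc2 <- make_scores(n = 80, stable = 0)
  st2 <- stability_table(sc2)
  expect_lt(mean(abs(st2$rho)), 0.2)
})

test_that("within-subject stability ranges behave at the extremes", {
  # perfectly rank-stable scores: all ranges 0
  sc <- make_scores(n = 40, stable = 1)
  ws <- within_subject_stability(sc)
  expect_true(all(abs(ws$ranges[, composite_names()]) < 1e-9))
  # i.i.d. scores across timepoints: mean range near the uniform order
  # statistic expectation of 50 (range of 3 uniform draws)
  sc2 <- make_scores(n = 400, stable = 0, seed = 5)
  ws2 <- within_subject_stability(sc2)
  expect_equal(unname(ws2$mean_range), rep(50, 5), tolerance = 0.08)
  # a hand-computed range
  d <- data.frame(participant_id = rep(1:5, 3),
                  timepoint = rep(c("3m", "6m", "12m"), each = 5))
  d$X <- c(1:5, c(2, 1, 3, 5, 4), c(3, 1, 2, 4, 5))
  ws3 <- within_subject_stability(d, composites = "X")
  # participant 4: percentiles 4/6, 5/6, 4/6 -> range 1/6 of 100
  expect_equal(ws3$ranges$X[ws3$ranges$participant_id == 4], 100 / 6,
               tolerance = 1e-9)
})

test_that("stability contrasts flag degenerate paired differences", {
  x <- c(10, 20, 30, 40)
  sc <- stability_contrast(x, x)
  expect_true(sc$degenerate)
  set.seed(6)
  a <- runif(100, 20, 80)
  b <- a + rnorm(100, 5, 10)
  sc2 <- stability_contrast(a, b)
  expect_false(sc2$degenerate)
  expect_lt(sc2$t, 0)
  expect_lt(sc2$p, 0.05)
})

test_that("outlier rule is 1.5 IQR beyond the quartiles", {
  set.seed(8)
  x <- rnorm(200)
  q <- quantile(x, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  probe <- q[2] + 1.6 * iqr
  expect_true(outlier_flags(c(x, probe))[201])
  probe2 <- q[2] + 1.4 * iqr
  expect_false(outlier_flags(c(x, probe2))[201])
})

test_that("mixed models recover a built-in Sleep Day effect on the outcome", {
  set.seed(9)
  sc <- make_scores(n = 120, stable = 0.6)
  u <- rnorm(120, 0, 10)
  sc$asq_collective <- 200 - 6.65 * sc[["Sleep Day"]] +
    u[sc$participant_id] + rnorm(nrow(sc), 0, 12)
  res <- asq_models(sc)
  b <- res[res$term == "Sleep Day", ]
  expect_lt(b$estimate, 0)
  expect_equal(b$estimate, -6.65, tolerance = 2 * b$se)
  expect_lt(b$p, 0.05)
  # null outcome: composite coefficients near zero
  sc$asq_null <- 100 + u[sc$participant_id] + rnorm(nrow(sc), 0, 12)
  res0 <- asq_models(sc, outcomes = "asq_null")
  b0 <- res0[res0$term %in% composite_names(), ]
  expect_true(all(abs(b0$estimate) < 3 * b0$se + 1e-9))
})
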